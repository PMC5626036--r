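#' Beat segmentation and downsampling scheme
#'
#' Defines the fixed beat window around each R peak and the two-rate
#' downsampling that reduces a beat to the network's input length. The default
#' window keeps 105 samples before the R peak and 165 from the R peak on
#' (270 samples, 0.75 s at 360 Hz); downsampling passes the 15 samples
#' centered on R through untouched and picks the remaining 55 at evenly
#' spaced positions, for 70 samples per beat. The alternative 251-sample
#' clustering (90 before, 161 from R on) is expressed with `pre = 90`,
#' `post = 161`.
#'
#' @param pre Samples kept before the R peak.
#' @param post Samples kept from the R peak on (R itself included), so the
#'   window is `[R - pre, R + post)` and the beat length is `pre + post`.
#' @param central_width Width of the R-centered pass-through block; odd.
#' @param target Total samples after downsampling (used by the `"linspace"`
#'   method).
#' @param method `"linspace"` (default): exactly `target` samples, the
#'   non-central ones at `round(seq())` positions over the remaining samples.
#'   `"stride"`: every `stride`-th remaining sample, in which case the output
#'   length is `central_width + ceiling((pre + post - central_width) /
#'   stride)` and `target` is ignored.
#' @param stride Stride for the `"stride"` method.
#'
#' @return Object of class `segmentation_scheme`.
#' @export
segmentation_scheme <- function(pre = 105L, post = 165L, central_width = 15L,
                                target = 70L, method = c("linspace", "stride"),
                                stride = 6L) {
  method <- match.arg(method)
  pre <- as.integer(pre); post <- as.integer(post)
  central_width <- as.integer(central_width); target <- as.integer(target)
  L <- pre + post
  if (pre < 0 || post < 1) stop("need `pre` >= 0 and `post` >= 1", call. = FALSE)
  if (central_width %% 2L == 0L || central_width > L) {
    stop("`central_width` must be odd and <= the beat length", call. = FALSE)
  }
  if (target < central_width || target > L) {
    stop("`target` must lie in [central_width, beat length]", call. = FALSE)
  }
  half <- (central_width - 1L) %/% 2L
  if (pre + 1L - half < 1L || pre + 1L + half > L) {
    stop("central block must fit inside the beat window", call. = FALSE)
  }
  structure(list(pre = pre, post = post, beat_length = L,
                 central_width = central_width, target = target,
                 method = method, stride = as.integer(stride)),
            class = "segmentation_scheme")
}

#' Retained sample positions for a downsampling scheme
#'
#' The fixed 1-based index map (within a beat window) of the samples a scheme
#' retains. Publishing the map makes compression bit-reproducible and gives
#' [upsample_beat()] its interpolation knots.
#'
#' @param scheme A [segmentation_scheme()].
#' @return Sorted integer vector of retained positions; length
#'   `scheme$target` for the `"linspace"` method.
#' @export
downsample_indices <- function(scheme) {
  L <- scheme$beat_length
  r_pos <- scheme$pre + 1L
  half <- (scheme$central_width - 1L) %/% 2L
  central <- (r_pos - half):(r_pos + half)
  remaining <- setdiff(seq_len(L), central)
  sel <- if (scheme$method == "stride") {
    remaining[seq(1L, length(remaining), by = scheme$stride)]
  } else {
    k <- scheme$target - scheme$central_width
    pos <- round(seq(1, length(remaining), length.out = k))
    if (anyDuplicated(pos)) {
      stop("scheme too dense: non-central samples collide; raise `target` spacing",
           call. = FALSE)
    }
    remaining[pos]
  }
  sort(c(central, sel))
}

#' Extract fixed-length beats around detected R peaks
#'
#' Cuts the window `[R - pre, R + post)` for every R peak; beats whose window
#' runs off either end of the record are skipped and counted.
#'
#' @param record An [ecg_record()].
#' @param r_peaks An `r_peak_list` from [detect_r_peaks()] or an integer
#'   vector of 1-based R indices.
#' @param scheme A [segmentation_scheme()].
#'
#' @return Object of class `beat_matrix`: list with `beats` (matrix, one beat
#'   per row), `r_peaks` (indices of the retained beats), `scheme`, `skipped`
#'   (number of boundary beats dropped) and `fs`.
#' @export
segment_beats <- function(record, r_peaks, scheme = segmentation_scheme()) {
  sig <- record_samples(record)
  fs <- record_fs(record)
  peaks <- peak_indices(r_peaks)
  ok <- peaks - scheme$pre >= 1L & peaks + scheme$post - 1L <= length(sig)
  kept <- peaks[ok]
  beats <- matrix(numeric(0), nrow = 0, ncol = scheme$beat_length)
  if (length(kept)) {
    beats <- t(vapply(kept, function(r) {
      sig[(r - scheme$pre):(r + scheme$post - 1L)]
    }, numeric(scheme$beat_length)))
  } else {
    warning("no beat window fits inside the record", call. = FALSE)
  }
  structure(list(beats = beats, r_peaks = kept, scheme = scheme,
                 skipped = sum(!ok), fs = fs),
            class = "beat_matrix")
}

#' @export
print.beat_matrix <- function(x, ...) {
  cat(sprintf("<beat_matrix: %d beats x %d samples (%d skipped)>\n",
              nrow(x$beats), ncol(x$beats), x$skipped))
  invisible(x)
}

#' Downsample one beat to the scheme's retained positions
#'
#' A pure gather: `beat[downsample_indices(scheme)]`. The central R block is
#' passed through unchanged; with the default scheme the output has exactly
#' 70 samples.
#'
#' @param beat Numeric vector of length `scheme$beat_length`.
#' @param scheme A [segmentation_scheme()].
#' @return Numeric vector of the retained samples.
#' @export
downsample_beat <- function(beat, scheme = segmentation_scheme()) {
  if (length(beat) != scheme$beat_length) {
    stop(sprintf("beat has %d samples but the scheme expects %d",
                 length(beat), scheme$beat_length), call. = FALSE)
  }
  beat[downsample_indices(scheme)]
}

#' Upsample a downsampled beat back to the full window length
#'
#' Places the retained samples at their original positions and fills the gaps
#' by interpolation, so retained positions are exact fixed points of the
#' downsample/upsample round trip.
#'
#' @param vec Numeric vector as produced by [downsample_beat()].
#' @param scheme A [segmentation_scheme()].
#' @param interp `"linear"` (default) or `"spline"` (cubic).
#' @return Numeric vector of length `scheme$beat_length`.
#' @export
upsample_beat <- function(vec, scheme = segmentation_scheme(),
                          interp = c("linear", "spline")) {
  interp <- match.arg(interp)
  idx <- downsample_indices(scheme)
  if (length(vec) != length(idx)) {
    stop(sprintf("input has %d samples but the scheme retains %d",
                 length(vec), length(idx)), call. = FALSE)
  }
  xout <- seq_len(scheme$beat_length)
  if (interp == "spline") {
    out <- stats::spline(idx, vec, xout = xout, method = "natural")$y
    out[idx] <- vec
    out
  } else {
    stats::approx(idx, vec, xout = xout, rule = 2)$y
  }
}

#' Per-beat min-max normalization to the unit interval
#'
#' Sigmoid hidden units need bounded inputs, so each beat is mapped to
#' \[0, 1\] by its own minimum and maximum; the pair is stored per beat so
#' [denormalize_beats()] inverts the map exactly. A constant beat maps to the
#' constant 0.5.
#'
#' @param beats Numeric matrix, one beat per row.
#' @return List with `beats` (normalized matrix), `mins`, `maxs`.
#' @export
normalize_beats <- function(beats) {
  beats <- as.matrix(beats)
  mins <- apply(beats, 1, min)
  maxs <- apply(beats, 1, max)
  rng <- maxs - mins
  norm <- (beats - mins) / ifelse(rng > 0, rng, 1)
  norm[rng == 0, ] <- 0.5
  list(beats = norm, mins = mins, maxs = maxs)
}

#' Invert the per-beat min-max normalization
#'
#' @param beats Normalized matrix (rows in \[0, 1\]).
#' @param mins,maxs Per-beat minima and maxima stored by [normalize_beats()].
#' @return Matrix on the original scale.
#' @export
denormalize_beats <- function(beats, mins, maxs) {
  beats <- as.matrix(beats)
  rng <- maxs - mins
  out <- beats * ifelse(rng > 0, rng, 0) + mins
  out[rng == 0, ] <- mins[rng == 0]
  out
}
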