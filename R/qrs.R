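#' Delay correction for the wavelet R-peak detector
#'
#' The analytic detail at level `j` trails the input by `(2^j - 1) / 2`
#' samples with the default quadratic-spline alignment, so the zero-crossing
#' between a modulus maximum-minimum pair lands that far after the true R
#' peak. The integer correction applied is `2^{j-1}` (the half-sample excess
#' rounded up): 4 samples at the detection level `j = 3`.
#'
#' @param j Decomposition level.
#' @return Integer number of samples to subtract from the crossing index.
#' @examples
#' delay_correction(3) # 4
#' @export
delay_correction <- function(j) {
  if (j < 1) stop("`j` must be >= 1", call. = FALSE)
  as.integer(2^(j - 1))
}

#' Detection configuration for the wavelet R-peak detector
#'
#' @param level Detail level `j` used for detection (default 3; the QRS
#'   energy concentrates at scales `2^3`..`2^5`).
#' @param s1_frac,s2_frac Relative thresholds: the positive threshold `s1` is
#'   `s1_frac` times the largest positive detail value over the record, the
#'   negative threshold `s2` is `s2_frac` times the most negative value.
#'   Record-relative fractions make the defaults amplitude-invariant.
#' @param refractory_ms Minimum spacing between accepted peaks (ms); within a
#'   refractory conflict the larger-modulus event wins.
#' @param pair_window_ms Maximum distance from a modulus maximum to its paired
#'   minimum (ms); bounds the QRS duration.
#' @param delay Integer delay offset subtracted from each zero-crossing;
#'   defaults to [delay_correction()] at `level`.
#' @param filters A [filter_pair()] for the analytic decomposition.
#'
#' @return Object of class `detection_config`.
#' @export
detection_config <- function(level = 3L, s1_frac = 0.3, s2_frac = 0.3,
                             refractory_ms = 200, pair_window_ms = 120,
                             delay = delay_correction(level),
                             filters = filter_pair()) {
  if (s1_frac <= 0 || s1_frac >= 1 || s2_frac <= 0 || s2_frac >= 1) {
    stop("threshold fractions must lie in (0, 1)", call. = FALSE)
  }
  if (refractory_ms <= 0) stop("`refractory_ms` must be > 0", call. = FALSE)
  structure(list(level = as.integer(level), s1_frac = s1_frac,
                 s2_frac = s2_frac, refractory_ms = refractory_ms,
                 pair_window_ms = pair_window_ms, delay = as.integer(delay),
                 filters = filters),
            class = "detection_config")
}

#' Default modulus thresholds from a detail array
#'
#' @param detail Numeric detail coefficients at the detection level.
#' @param s1_frac,s2_frac Fractions of the extreme positive / negative values.
#' @return Named numeric vector `c(s1 = , s2 = )`; both 0 for an all-zero
#'   detail, in which case detection returns no events.
#' @examples
#' default_thresholds(c(-8, 0, 10)) # c(s1 = 3, s2 = -2.4)
#' @export
default_thresholds <- function(detail, s1_frac = 0.3, s2_frac = 0.3) {
  if (!length(detail)) stop("`detail` must be non-empty", call. = FALSE)
  s1 <- s1_frac * max(c(detail, 0))
  s2 <- s2_frac * min(c(detail, 0))
  c(s1 = s1, s2 = s2)
}

#' Detect R peaks from wavelet modulus maximum-minimum zero-crossings
#'
#' Computes the analytic detail at scale `2^level`, finds local maxima above
#' `s1` and local minima below `s2`, pairs each maximum with the nearest
#' following minimum inside the pairing window, locates the zero-crossing
#' between the pair, and subtracts the level-dependent delay offset. Events
#' closer than the refractory period are resolved in favour of the larger
#' modulus (|max| + |min|).
#'
#' @param record An [ecg_record()].
#' @param config A [detection_config()].
#'
#' @return Object of class `r_peak_list`: list with `peaks` (strictly
#'   increasing 1-based sample indices; empty when nothing crosses the
#'   thresholds) and `modulus` (per-peak |max| + |min| pair amplitude).
#' @export
detect_r_peaks <- function(record, config = detection_config()) {
  fs <- record_fs(record)
  sig <- record_samples(record)
  empty <- structure(list(peaks = integer(0), modulus = numeric(0)),
                     class = "r_peak_list")
  if (!length(sig)) return(empty)
  dec <- atrous_decompose(sig, config$level, config$filters,
                          variant = "analytic")
  d <- dec$W[[config$level]]
  thr <- default_thresholds(d, config$s1_frac, config$s2_frac)
  if (thr[["s1"]] == 0 || thr[["s2"]] == 0) return(empty)

  n <- length(d)
  i <- 2:(n - 1)
  maxima <- i[d[i] > d[i - 1] & d[i] >= d[i + 1] & d[i] > thr[["s1"]]]
  minima <- i[d[i] < d[i - 1] & d[i] <= d[i + 1] & d[i] < thr[["s2"]]]
  if (!length(maxima) || !length(minima)) return(empty)

  win <- round(config$pair_window_ms * fs / 1000)
  cand_idx <- integer(0)
  cand_mod <- numeric(0)
  for (m in maxima) {
    after <- minima[minima > m & minima <= m + win]
    if (!length(after)) next
    mn <- after[1]
    # zero-crossing (+ to -) between the pair, linearly interpolated
    ks <- m:(mn - 1)
    k <- ks[d[ks] >= 0 & d[ks + 1] < 0][1]
    if (is.na(k)) next
    zc <- k + d[k] / (d[k] - d[k + 1])
    r <- round(zc) - config$delay
    if (r < 1 || r > n) next
    cand_idx <- c(cand_idx, as.integer(r))
    cand_mod <- c(cand_mod, abs(d[m]) + abs(d[mn]))
  }
  if (!length(cand_idx)) return(empty)

  # refractory suppression: accept in decreasing modulus order
  refr <- round(config$refractory_ms * fs / 1000)
  ord <- order(cand_mod, decreasing = TRUE)
  keep <- logical(length(cand_idx))
  for (o in ord) {
    if (!any(keep & abs(cand_idx - cand_idx[o]) < refr)) keep[o] <- TRUE
  }
  ord2 <- order(cand_idx[keep])
  structure(list(peaks = cand_idx[keep][ord2], modulus = cand_mod[keep][ord2]),
            class = "r_peak_list")
}

#' @export
print.r_peak_list <- function(x, ...) {
  cat(sprintf("<r_peak_list: %d peaks>\n", length(x$peaks)))
  invisible(x)
}

# Accept an r_peak_list or a bare integer vector of peak indices.
peak_indices <- function(x) {
  if (inherits(x, "r_peak_list")) x$peaks else as.integer(x)
}
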