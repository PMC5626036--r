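#' Objective weights for the multi-objective compression energy
#'
#' The three weights trade off compression ratio (via the hidden-layer size),
#' reconstruction error (PRD) and waveform correctness (CC). They must each
#' lie in (0, 1) and sum to 1. Defaults: 0.25, 0.45, 0.3.
#'
#' @param w1 Weight on the hidden-layer size term.
#' @param w2 Weight on PRD.
#' @param w3 Weight on `1 - CC`.
#' @return Object of class `objective_weights` (named numeric vector).
#' @export
objective_weights <- function(w1 = 0.25, w2 = 0.45, w3 = 0.3) {
  w <- c(w1 = w1, w2 = w2, w3 = w3)
  if (any(w <= 0) || any(w >= 1)) {
    stop("each weight must lie in (0, 1)", call. = FALSE)
  }
  if (abs(sum(w) - 1) > 1e-8) {
    stop("weights must sum to 1", call. = FALSE)
  }
  structure(w, class = "objective_weights")
}

#' Percentage root-mean-squared difference (PRD)
#'
#' Baseline-corrected relative RMS error between an original and a restored
#' waveform:
#' `sqrt( sum(((r - mean(r)) - (o - mean(o)))^2) / sum((o - mean(o))^2) )`.
#' Mean removal makes the measure insensitive to DC offset in either signal.
#' Returned as a fraction (0.12 means 12%).
#'
#' @param original Numeric vector `o` (the reference).
#' @param restored Numeric vector `r`, same length.
#' @return Nonnegative fraction.
#' @examples
#' prd(c(1, 2, 3, 4), c(1, 2, 3, 5)) # ~0.387
#' @export
prd <- function(original, restored) {
  if (length(original) != length(restored)) {
    stop("`original` and `restored` must have equal lengths", call. = FALSE)
  }
  if (length(original) < 2) stop("need at least 2 samples", call. = FALSE)
  o <- original - mean(original)
  denom <- sum(o^2)
  if (denom == 0) {
    stop("PRD is undefined for a constant original waveform", call. = FALSE)
  }
  r <- restored - mean(restored)
  sqrt(sum((r - o)^2) / denom)
}

#' Correlation coefficient (CC) between original and restored waveforms
#'
#' Pearson product-moment correlation; 1 means the restored waveform preserves
#' the original's shape exactly up to a positive affine map.
#'
#' @param original Numeric vector, not constant.
#' @param restored Numeric vector, same length, not constant.
#' @return Value in \[-1, 1\].
#' @export
cc <- function(original, restored) {
  if (length(original) != length(restored)) {
    stop("`original` and `restored` must have equal lengths", call. = FALSE)
  }
  if (length(original) < 2) stop("need at least 2 samples", call. = FALSE)
  o <- original - mean(original)
  r <- restored - mean(restored)
  no <- sqrt(sum(o^2))
  nr <- sqrt(sum(r^2))
  if (no == 0 || nr == 0) {
    stop("CC is undefined for a constant waveform", call. = FALSE)
  }
  sum(o * r) / (no * nr)
}

#' Multi-objective compression energy
#'
#' The scalarized objective `E = W1 * Nd + W2 * PRD + W3 * (1 - CC)`
#' balancing compression (small hidden layer) against distortion. PRD and
#' `1 - CC` enter as fractions: at `Nd = 14`, `PRD = 0.12`, `CC = 0.99` with
#' the default weights, `E = 0.25 * 14 + 0.45 * 0.12 + 0.3 * 0.01 = 3.557`.
#'
#' @param nd Hidden-layer size (code length per beat), >= 1.
#' @param prd PRD as a fraction, >= 0.
#' @param cc Correlation coefficient in \[-1, 1\].
#' @param weights An [objective_weights()] vector.
#' @return The energy value.
#' @examples
#' energy(14, 0.12, 0.99) # 3.557
#' @export
energy <- function(nd, prd, cc, weights = objective_weights()) {
  if (nd < 1) stop("`nd` must be >= 1", call. = FALSE)
  if (prd < 0) stop("`prd` must be >= 0", call. = FALSE)
  if (abs(cc) > 1 + 1e-12) stop("`cc` must lie in [-1, 1]", call. = FALSE)
  unname(weights[["w1"]] * nd + weights[["w2"]] * prd +
           weights[["w3"]] * (1 - cc))
}

#' Compression ratio of the beat code
#'
#' Stored samples per beat over code length, excluding container overhead:
#' 270 samples compressed to a 14-value code gives 19.3, reported "1:19".
#'
#' @param beat_length Samples per segmented beat.
#' @param nd Code length (hidden-layer size).
#' @return List with `ratio` (numeric) and `label` (`"1:n"`, n = floor(ratio)).
#' @examples
#' compression_ratio(270, 14)
#' @export
compression_ratio <- function(beat_length, nd) {
  if (beat_length < 1 || nd < 1) {
    stop("`beat_length` and `nd` must be >= 1", call. = FALSE)
  }
  ratio <- beat_length / nd
  list(ratio = ratio, label = sprintf("1:%d", floor(ratio)))
}

#' Full distortion report for a reconstruction
#'
#' @param original,restored Equal-length numeric vectors.
#' @param nd Hidden-layer size used.
#' @param beat_length Samples per beat (for the compression ratio).
#' @param weights An [objective_weights()] vector.
#' @return Object of class `metrics_report`: PRD, CC, energy, compression
#'   ratio, sample count and the two means.
#' @export
metrics_report <- function(original, restored, nd, beat_length = 270L,
                           weights = objective_weights()) {
  p <- prd(original, restored)
  r <- cc(original, restored)
  structure(list(
    prd = p, cc = r, energy = energy(nd, p, r, weights),
    compression = compression_ratio(beat_length, nd),
    n = length(original),
    mean_original = mean(original), mean_restored = mean(restored),
    weights = weights, nd = nd
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("PRD: %.2f%%   CC: %.4f   E: %.3f   ratio: %s (%.2f)   n = %d\n",
              100 * x$prd, x$cc, x$energy, x$compression$label,
              x$compression$ratio, x$n))
  invisible(x)
}
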