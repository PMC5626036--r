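#' Dynamic time warping configuration
#'
#' @param threshold Match threshold on the (normalized) distance; default 0.3.
#'   The comparison is inclusive: a distance exactly at the threshold matches.
#' @param normalize Divide the total path cost by the warping-path length
#'   (number of cells on the optimal path) so the threshold is independent of
#'   sequence length; default `TRUE`.
#' @return Object of class `dtw_config`.
#' @export
dtw_config <- function(threshold = 0.3, normalize = TRUE) {
  if (threshold <= 0) stop("`threshold` must be > 0", call. = FALSE)
  structure(list(threshold = threshold, normalize = normalize),
            class = "dtw_config")
}

#' Dynamic time warping distance between two sequences
#'
#' Classic dynamic program over the `M x N` grid with steps (1,0), (0,1),
#' (1,1), local cost `|a_i - b_j|`, and full boundary alignment. With
#' normalization on (the default) the minimal total cost is divided by the
#' length of the optimal warping path, recovered by backtracking (diagonal
#' preferred on ties).
#'
#' @param a,b Nonempty numeric vectors (frames of a beat or code vector).
#' @param config A [dtw_config()].
#' @return The (normalized) distance, with attributes `raw` (unnormalized
#'   total cost) and `path_length`.
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 3))
#' @export
dtw_distance <- function(a, b, config = dtw_config()) {
  if (!length(a) || !length(b)) {
    stop("both sequences must be nonempty", call. = FALSE)
  }
  M <- length(a); N <- length(b)
  D <- matrix(Inf, M + 1L, N + 1L)
  D[1L, 1L] <- 0
  cost <- abs(outer(a, b, `-`))
  for (i in seq_len(M)) {
    for (j in seq_len(N)) {
      D[i + 1L, j + 1L] <- cost[i, j] +
        min(D[i, j], D[i, j + 1L], D[i + 1L, j])
    }
  }
  raw <- D[M + 1L, N + 1L]
  # backtrack for the path length; prefer the diagonal on ties
  i <- M; j <- N; len <- 1L
  while (i > 1L || j > 1L) {
    moves <- c(diag = D[i, j], up = D[i, j + 1L], left = D[i + 1L, j])
    pick <- names(moves)[which.min(moves)]
    if (pick == "diag") { i <- i - 1L; j <- j - 1L }
    else if (pick == "up") i <- i - 1L
    else j <- j - 1L
    len <- len + 1L
  }
  d <- if (config$normalize) raw / len else raw
  structure(d, raw = raw, path_length = len)
}

#' Threshold match between a template and a candidate waveform
#'
#' @param template,candidate Numeric vectors.
#' @param config A [dtw_config()].
#' @return List with `match` (`TRUE` iff distance <= threshold, inclusive)
#'   and `distance`.
#' @export
dtw_match <- function(template, candidate, config = dtw_config()) {
  d <- dtw_distance(template, candidate, config)
  list(match = as.numeric(d) <= config$threshold, distance = as.numeric(d))
}
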