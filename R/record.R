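#' Construct an ECG record
#'
#' Container for a single-channel sampled ECG waveform: the sample values in
#' millivolts together with the sampling rate in Hz. All pipeline stages
#' (preprocessing, R detection, segmentation, compression) take and return
#' `ecg_record` objects.
#'
#' @param samples Numeric vector of sample values (mV). Must be finite.
#' @param fs Sampling rate in Hz; a single positive number.
#' @param id Optional record identifier (character).
#'
#' @return An object of class `ecg_record` with fields `samples`, `fs`, `id`.
#' @examples
#' rec <- ecg_record(sin(seq(0, 2 * pi, length.out = 100)), fs = 100)
#' length(rec$samples)
#' @export
ecg_record <- function(samples, fs, id = NULL) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (length(samples) && !all(is.finite(samples))) {
    stop("`samples` must all be finite", call. = FALSE)
  }
  structure(list(samples = samples, fs = fs, id = id), class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf(
    "<ecg_record%s: %d samples @ %g Hz (%.2f s)>\n",
    if (is.null(x$id)) "" else paste0(" ", x$id), length(x$samples), x$fs, dur
  ))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

# Accept either an ecg_record or a bare numeric vector.
record_samples <- function(x) {
  if (inherits(x, "ecg_record")) x$samples else as.numeric(x)
}

record_fs <- function(x, fs = NULL) {
  if (inherits(x, "ecg_record")) x$fs
  else if (!is.null(fs)) fs
  else stop("sampling rate `fs` is required", call. = FALSE)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
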