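#' Compress an ECG record with a trained network
#'
#' Runs the full coding pipeline: baseline-wander removal (and optional
#' scale-selective denoising), wavelet R-peak detection, fixed-window
#' segmentation, two-rate downsampling, per-beat min-max normalization and
#' encoding through the trained hidden layer. The container stores the
#' decoder half of the network once, plus per beat the R position, the
#' `nd`-value code and the normalization pair — everything needed to
#' reconstruct.
#'
#' @param record An [ecg_record()].
#' @param params Trained [init_params()] object.
#' @param scheme A [segmentation_scheme()].
#' @param det_config A [detection_config()].
#' @param baseline Remove baseline wander before detection; default `TRUE`.
#' @param denoise_scales `NULL` (default, no denoising) or the detail scales
#'   to keep, e.g. `3:5`.
#' @param weights An [objective_weights()] vector recorded in the header.
#'
#' @return Object of class `compressed_record`.
#' @export
compress_record <- function(record, params, scheme = segmentation_scheme(),
                            det_config = detection_config(),
                            baseline = TRUE, denoise_scales = NULL,
                            weights = objective_weights()) {
  fs <- record_fs(record)
  proc <- record
  if (baseline) proc <- remove_baseline(proc)
  if (!is.null(denoise_scales)) proc <- denoise(proc, keep = denoise_scales)
  peaks <- detect_r_peaks(proc, det_config)
  bm <- segment_beats(proc, peaks, scheme)
  if (!nrow(bm$beats)) stop("no beats detected; cannot compress", call. = FALSE)
  down <- t(apply(bm$beats, 1, downsample_beat, scheme = scheme))
  if (ncol(down) != params$n_io) {
    stop(sprintf("scheme retains %d samples per beat but the network expects %d",
                 ncol(down), params$n_io), call. = FALSE)
  }
  nb <- normalize_beats(down)
  codes <- net_forward(params, nb$beats)$code
  structure(list(
    version = "1.0", fs = fs,
    scheme = scheme, nd = params$nd,
    decoder = list(w_ho = params$w_ho, b_o = params$b_o),
    weights = as.numeric(weights),
    r_peaks = bm$r_peaks, codes = codes,
    mins = nb$mins, maxs = nb$maxs
  ), class = "compressed_record")
}

#' @export
print.compressed_record <- function(x, ...) {
  cr <- compression_ratio(x$scheme$beat_length, x$nd)
  cat(sprintf(
    "<compressed_record v%s: %d beats, code length %d, ratio %s>\n",
    x$version, length(x$r_peaks), x$nd, cr$label))
  invisible(x)
}

#' Decompress a compressed ECG record
#'
#' Decodes every stored code through the decoder layer, inverts the per-beat
#' normalization with the stored (min, max) pair, and upsamples each beat back
#' to the full window length. Beats are returned aligned to their stored R
#' positions.
#'
#' @param comp A [compress_record()] container (possibly read back from disk).
#' @return List with `beats` (matrix, one reconstructed full-length beat per
#'   row), `r_peaks`, `scheme` and `fs`.
#' @export
decompress_record <- function(comp) {
  if (!inherits(comp, "compressed_record")) {
    stop("`comp` must be a compressed_record", call. = FALSE)
  }
  codes <- as.matrix(comp$codes)
  recon70 <- sweep(codes %*% comp$decoder$w_ho, 2, comp$decoder$b_o, `+`)
  denorm <- denormalize_beats(recon70, comp$mins, comp$maxs)
  beats <- t(apply(denorm, 1, upsample_beat, scheme = comp$scheme))
  list(beats = beats, r_peaks = comp$r_peaks, scheme = comp$scheme,
       fs = comp$fs)
}

#' Assemble reconstructed beats into a waveform
#'
#' Places each reconstructed beat at its stored R position in a zero signal
#' (later beats overwrite earlier ones where windows overlap); useful for
#' whole-record distortion evaluation against the original.
#'
#' @param dec Output of [decompress_record()].
#' @param n Output length; defaults to the end of the last beat window.
#' @return An [ecg_record()].
#' @export
assemble_beats <- function(dec, n = NULL) {
  sch <- dec$scheme
  if (is.null(n)) n <- max(dec$r_peaks) + sch$post - 1L
  out <- numeric(n)
  for (i in seq_along(dec$r_peaks)) {
    r <- dec$r_peaks[i]
    idx <- (r - sch$pre):(r + sch$post - 1L)
    ok <- idx >= 1L & idx <= n
    out[idx[ok]] <- dec$beats[i, ok]
  }
  ecg_record(out, dec$fs, id = "reconstructed")
}

#' Evaluate a reconstruction against the original record
#'
#' Computes beat-wise PRD/CC between the original segmented beats and their
#' reconstructions, the pooled distortion over all matched beat windows, the
#' energy, the compression ratio, and optionally a DTW template-match rate of
#' reconstructed against original beats.
#'
#' @param record The original [ecg_record()].
#' @param comp The [compress_record()] container for that record.
#' @param dtw Also compute the DTW match rate (normalized beats); default
#'   `TRUE`.
#' @param dtw_cfg A [dtw_config()].
#' @param weights An [objective_weights()] vector for the energy.
#' @return List with `report` (a [metrics_report()] over the pooled beat
#'   windows), `per_beat` (data.frame of PRD/CC/DTW distance per beat) and
#'   `dtw_match_rate`.
#' @export
evaluate_compression <- function(record, comp, dtw = TRUE,
                                 dtw_cfg = dtw_config(),
                                 weights = objective_weights()) {
  dec <- decompress_record(comp)
  orig_bm <- segment_beats(record, comp$r_peaks, comp$scheme)
  stopifnot(nrow(orig_bm$beats) == nrow(dec$beats))
  nbeat <- nrow(dec$beats)
  per <- data.frame(prd = numeric(nbeat), cc = numeric(nbeat),
                    dtw = rep(NA_real_, nbeat))
  for (i in seq_len(nbeat)) {
    per$prd[i] <- prd(orig_bm$beats[i, ], dec$beats[i, ])
    per$cc[i] <- cc(orig_bm$beats[i, ], dec$beats[i, ])
    if (dtw) {
      no <- normalize_beats(orig_bm$beats[i, , drop = FALSE])
      nr <- (dec$beats[i, ] - no$mins) / max(no$maxs - no$mins, 1e-12)
      per$dtw[i] <- as.numeric(dtw_distance(no$beats[1, ], nr, dtw_cfg))
    }
  }
  rep <- metrics_report(as.numeric(t(orig_bm$beats)),
                        as.numeric(t(dec$beats)),
                        nd = comp$nd, beat_length = comp$scheme$beat_length,
                        weights = weights)
  list(report = rep, per_beat = per,
       dtw_match_rate = if (dtw) mean(per$dtw <= dtw_cfg$threshold) else NA)
}
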