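# Shared fixture builders: everything is generated in code, seeded.

quiet_record <- function(n_beats = 10, sd = 0, wander = 0, seed = 1L, ...) {
  generate_record(fs = 360, n_beats = n_beats,
                  noise = noise_params(sd = sd, wander_amp = wander,
                                       seed = seed, ...))
}

# Normalized 70-sample training matrix from a clean synthetic record.
training_beats <- function(n_beats = 7, seed = 1L, sd = 0.01) {
  g <- quiet_record(n_beats, sd = sd, seed = seed)
  bm <- segment_beats(g$record, g$r_peaks)
  down <- t(apply(bm$beats, 1, downsample_beat,
                  scheme = segmentation_scheme()))
  normalize_beats(down)$beats
}

# Exhaustive DTW over all monotone alignments with steps (1,0),(0,1),(1,1);
# independent of the DP implementation.
brute_dtw <- function(a, b) {
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(abs(a[1] - b[1]))
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    best + abs(a[i] - b[j])
  }
  rec(length(a), length(b))
}

# Central finite-difference gradient of the training loss for one parameter
# block, used as the oracle for the analytic backpropagation.
numeric_grad <- function(params, x, weights, field, h = 1e-6) {
  v <- params[[field]]
  g <- if (is.matrix(v)) matrix(0, nrow(v), ncol(v)) else numeric(length(v))
  for (i in seq_along(v)) {
    p1 <- params; p1[[field]][i] <- v[i] + h
    p2 <- params; p2[[field]][i] <- v[i] - h
    l1 <- ecgcomp:::net_loss_grad(p1, x, weights, grad = FALSE)$loss
    l2 <- ecgcomp:::net_loss_grad(p2, x, weights, grad = FALSE)$loss
    g[i] <- (l1 - l2) / (2 * h)
  }
  g
}
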