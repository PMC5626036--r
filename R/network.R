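#' Training configuration for the compression network
#'
#' @param alpha Learning rate for full-batch gradient descent; default 0.4.
#' @param weights An [objective_weights()] vector; default (0.25, 0.45, 0.3).
#' @param epochs Training cycles; default 10000.
#' @param seed Integer seed for weight initialization.
#' @param candidates Hidden-layer sizes tried by [select_hidden_size()];
#'   default `c(12, 14, 16)`.
#' @param train_frac Fraction of beats used for training when a held-out
#'   evaluation split is requested; default 0.67.
#' @return Object of class `train_config`.
#' @export
train_config <- function(alpha = 0.4, weights = objective_weights(),
                         epochs = 10000L, seed = 1L,
                         candidates = c(12L, 14L, 16L), train_frac = 0.67) {
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  if (epochs < 1) stop("`epochs` must be >= 1", call. = FALSE)
  if (!length(candidates)) stop("`candidates` must be non-empty", call. = FALSE)
  if (train_frac <= 0 || train_frac > 1) {
    stop("`train_frac` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(alpha = alpha, weights = weights,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 candidates = sort(as.integer(candidates)),
                 train_frac = train_frac),
            class = "train_config")
}

#' Initialize network parameters
#'
#' Weights are drawn uniformly from `(-r, r)` with
#' `r = sqrt(6 / (fan_in + fan_out))` (the usual scaling that keeps sigmoid
#' pre-activations in their responsive range); biases start at zero. Seeded
#' and reproducible.
#'
#' @param n_io Input/output width (samples per downsampled beat); default 70.
#' @param nd Hidden-layer size (code length).
#' @param seed Integer seed.
#' @return Object of class `network_params` with fields `w_ih` (`n_io x nd`),
#'   `b_h` (`nd`), `w_ho` (`nd x n_io`), `b_o` (`n_io`), `nd`, `n_io`.
#' @export
init_params <- function(n_io = 70L, nd, seed = 1L) {
  if (n_io < 1 || nd < 1) stop("layer sizes must be >= 1", call. = FALSE)
  r <- sqrt(6 / (n_io + nd))
  with_seed(seed, {
    w_ih <- matrix(stats::runif(n_io * nd, -r, r), n_io, nd)
    w_ho <- matrix(stats::runif(nd * n_io, -r, r), nd, n_io)
  })
  structure(list(w_ih = w_ih, b_h = numeric(nd), w_ho = w_ho,
                 b_o = numeric(n_io), nd = as.integer(nd),
                 n_io = as.integer(n_io), activation = "sigmoid-linear"),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("<network_params: %d-%d-%d, sigmoid hidden / linear output>\n",
              x$n_io, x$nd, x$n_io))
  invisible(x)
}

#' Forward pass: encode beats and reconstruct them
#'
#' `code = sigmoid(x W_ih + b_h)`; `reconstruction = code W_ho + b_o`. The
#' hidden activations are the stored compressed representation; the linear
#' output avoids saturation bias at the beat extremes of the \[0, 1\]
#' normalized input.
#'
#' @param params A [init_params()] object (possibly trained).
#' @param beats Numeric matrix (beats in rows, `n_io` columns) or a single
#'   beat vector of length `n_io`.
#' @return List with `code` (matrix, `nd` columns) and `recon` (matrix,
#'   `n_io` columns); single-row for vector input.
#' @export
net_forward <- function(params, beats) {
  x <- if (is.matrix(beats)) beats else matrix(beats, nrow = 1)
  if (ncol(x) != params$n_io) {
    stop(sprintf("beats have %d columns but the network expects %d",
                 ncol(x), params$n_io), call. = FALSE)
  }
  z <- sweep(x %*% params$w_ih, 2, params$b_h, `+`)
  code <- stats::plogis(z)
  recon <- sweep(code %*% params$w_ho, 2, params$b_o, `+`)
  list(code = code, recon = recon)
}

# Distortion loss over a batch and its analytic gradient.
#
# loss = mean_b [ w2 * PRD_b + w3 * (1 - CC_b) ]  — the trainable part of the
# energy (the w1 * Nd term has zero gradient in the weights and is handled by
# the discrete hidden-size search). Per beat, with centered vectors
# o~ = o - mean(o), r~ = r - mean(r) and e = r~ - o~:
#   dPRD/dr = e / (||e|| * ||o~||)
#   dCC/dr  = o~ / (||o~|| ||r~||) - CC * r~ / ||r~||^2
# (both already mean-free, so centering adds nothing). Degenerate beats
# (perfect fit or constant reconstruction) get zero gradient for the term.
net_loss_grad <- function(params, x, weights, grad = TRUE) {
  fw <- net_forward(params, x)
  code <- fw$code
  recon <- fw$recon
  B <- nrow(x)
  w2 <- weights[["w2"]]; w3 <- weights[["w3"]]
  prds <- numeric(B)
  ccs <- numeric(B)
  d_recon <- if (grad) matrix(0, B, params$n_io) else NULL
  for (b in seq_len(B)) {
    o <- x[b, ] - mean(x[b, ])
    r <- recon[b, ] - mean(recon[b, ])
    no <- sqrt(sum(o^2))
    e <- r - o
    ne <- sqrt(sum(e^2))
    nr <- sqrt(sum(r^2))
    prds[b] <- ne / no
    ccs[b] <- if (nr > 0) sum(o * r) / (no * nr) else 0
    if (grad) {
      g <- numeric(params$n_io)
      if (ne > 0) g <- g + (w2 / B) * e / (ne * no)
      if (nr > 0) {
        g <- g - (w3 / B) * (o / (no * nr) - ccs[b] * r / nr^2)
      }
      d_recon[b, ] <- g
    }
  }
  loss <- w2 * mean(prds) + w3 * (1 - mean(ccs))
  out <- list(loss = loss, prd = mean(prds), cc = mean(ccs))
  if (grad) {
    out$g_w_ho <- t(code) %*% d_recon
    out$g_b_o <- colSums(d_recon)
    d_code <- (d_recon %*% t(params$w_ho)) * code * (1 - code)
    out$g_w_ih <- t(x) %*% d_code
    out$g_b_h <- colSums(d_code)
  }
  out
}

#' Train the compression network by gradient descent on the energy
#'
#' Full-batch gradient descent on the trainable part of the multi-objective
#' energy, `w2 * PRD + w3 * (1 - CC)` averaged over the training beats; the
#' `w1 * Nd` term is constant in the weights (the hidden size is discrete)
#' and is added back when the energy history is reported, so the history is
#' the full `E` of each epoch. Training aborts with a diagnostic if the loss
#' diverges.
#'
#' @param beats A `beat_matrix` of full-length beats (they are downsampled
#'   and normalized internally), or a numeric matrix of already-normalized
#'   `n_io`-sample beats in \[0, 1\].
#' @param nd Hidden-layer size.
#' @param config A [train_config()].
#'
#' @return List with `params` (trained [init_params()] object), `history`
#'   (energy per epoch, length `epochs + 1`, first entry at initialization),
#'   `prd` and `cc` (training-set averages at the final parameters).
#' @export
train_network <- function(beats, nd, config = train_config()) {
  x <- training_matrix(beats)
  if (nrow(x) < 2) stop("need at least 2 beats to train", call. = FALSE)
  params <- init_params(ncol(x), nd, seed = config$seed)
  w <- config$weights
  const <- w[["w1"]] * nd
  history <- numeric(config$epochs + 1L)
  for (ep in seq_len(config$epochs)) {
    lg <- net_loss_grad(params, x, w)
    if (!is.finite(lg$loss) || lg$loss > 1e6) {
      stop(sprintf(
        "training diverged at epoch %d (loss = %g, alpha = %g); reduce alpha",
        ep, lg$loss, config$alpha), call. = FALSE)
    }
    history[ep] <- const + lg$loss
    params$w_ih <- params$w_ih - config$alpha * lg$g_w_ih
    params$b_h <- params$b_h - config$alpha * lg$g_b_h
    params$w_ho <- params$w_ho - config$alpha * lg$g_w_ho
    params$b_o <- params$b_o - config$alpha * lg$g_b_o
  }
  fin <- net_loss_grad(params, x, w, grad = FALSE)
  history[config$epochs + 1L] <- const + fin$loss
  list(params = params, history = history, prd = fin$prd, cc = fin$cc)
}

# Coerce training input to a normalized n_io-wide matrix.
training_matrix <- function(beats) {
  if (inherits(beats, "beat_matrix")) {
    down <- t(apply(beats$beats, 1, downsample_beat, scheme = beats$scheme))
    normalize_beats(down)$beats
  } else {
    x <- as.matrix(beats)
    if (min(x) < -1e-9 || max(x) > 1 + 1e-9) {
      stop("beat matrix must be normalized to [0, 1]; see normalize_beats()",
           call. = FALSE)
    }
    x
  }
}

#' Split beats into a studied (training) and held-out set
#'
#' Seeded random split used when held-out distortion is reported alongside
#' the training-set energy; by default 67% of the beats are studied.
#'
#' @param n_beats Number of beats.
#' @param frac Training fraction in (0, 1].
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
train_split <- function(n_beats, frac = 0.67, seed = 1L) {
  if (n_beats < 1) stop("`n_beats` must be >= 1", call. = FALSE)
  n_tr <- max(1L, round(frac * n_beats))
  idx <- with_seed(seed, sample.int(n_beats, n_tr))
  list(train = sort(idx), test = setdiff(seq_len(n_beats), sort(idx)))
}

#' Select the hidden-layer size by minimizing the energy
#'
#' Trains one network per candidate hidden size with identical data, seed and
#' epoch budget, evaluates the full energy `E = w1 * Nd + w2 * PRD +
#' w3 * (1 - CC)` on the training set, and returns the argmin (ties going to
#' the smaller, i.e. more compressive, size).
#'
#' @param beats As in [train_network()].
#' @param config A [train_config()]; `config$candidates` are the sizes tried.
#' @return List with `nd` (selected size), `energies` (named numeric, one per
#'   candidate), `results` (per-candidate training results) and `params` (the
#'   selected network).
#' @export
select_hidden_size <- function(beats, config = train_config()) {
  cands <- config$candidates
  energies <- numeric(length(cands))
  results <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    fit <- train_network(beats, cands[i], config)
    energies[i] <- energy(cands[i], fit$prd, fit$cc, config$weights)
    results[[i]] <- fit
  }
  names(energies) <- names(results) <- as.character(cands)
  best <- which.min(energies) # candidates sorted ascending: ties -> smaller
  list(nd = cands[best], energies = energies, results = results,
       params = results[[best]]$params)
}
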