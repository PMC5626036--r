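test_that("initialization is seeded, shaped by the hidden size, and scaled by fan-in/out", {
  p1 <- init_params(70, 14, seed = 3)
  p2 <- init_params(70, 14, seed = 3)
  expect_identical(p1$w_ih, p2$w_ih)
  expect_equal(dim(p1$w_ih), c(70L, 14L))
  expect_equal(dim(p1$w_ho), c(14L, 70L))
  expect_true(all(abs(p1$w_ih) < sqrt(6 / 84)))
  expect_true(all(p1$b_h == 0) && all(p1$b_o == 0))
})

test_that("the forward pass is deterministic with sigmoid codes and linear output", {
  p <- init_params(10, 3, seed = 1)
  p$w_ih[] <- 0; p$w_ho[] <- 0
  fw <- net_forward(p, runif(10))
  expect_equal(as.numeric(fw$code), rep(0.5, 3))
  expect_equal(as.numeric(fw$recon), rep(0, 10))
  x <- matrix(runif(30), 3, 10)
  p2 <- init_params(10, 4, seed = 2)
  expect_identical(net_forward(p2, x), net_forward(p2, x))
  expect_equal(ncol(net_forward(p2, x)$code), 4)
  expect_error(net_forward(p2, runif(7)), "expects")
})

test_that("backpropagation matches central finite differences", {
  set.seed(13)
  x <- matrix(stats::runif(40), 4, 10)
  p <- init_params(10, 3, seed = 5)
  w <- objective_weights()
  lg <- ecgcomp:::net_loss_grad(p, x, w)
  for (field in c("w_ih", "b_h", "w_ho", "b_o")) {
    num <- numeric_grad(p, x, w, field)
    ana <- lg[[paste0("g_", field)]]
    expect_lt(max(abs(ana - num)) / max(abs(num)), 1e-5)
  }
})

test_that("a zero learning rate leaves the parameters untouched", {
  x <- training_beats(5)
  fit <- train_network(x, 6, train_config(alpha = 0, epochs = 20, seed = 4))
  expect_identical(fit$params$w_ih, init_params(70, 6, seed = 4)$w_ih)
  expect_equal(diff(range(fit$history)), 0)
})

test_that("training is reproducible and descends the energy", {
  x <- training_beats(5)
  cfg <- train_config(alpha = 0.01, epochs = 500, seed = 3)
  f1 <- train_network(x, 14, cfg)
  f2 <- train_network(x, 14, cfg)
  expect_identical(f1$history, f2$history)
  expect_lt(f1$history[length(f1$history)], f1$history[1])
  expect_true(all(diff(f1$history) <= 1e-10))
})

test_that("more hidden units never fit worse on the same data and budget", {
  # noisy beats so the rows genuinely differ and capacity matters
  x <- training_beats(6, seed = 2, sd = 0.1)
  cfg <- train_config(alpha = 0.2, epochs = 2000, seed = 5)
  prd_small <- train_network(x, 4, cfg)$prd
  prd_large <- train_network(x, 16, cfg)$prd
  expect_lte(prd_large, prd_small)
})

test_that("hidden-size selection reports one energy per candidate and takes the argmin", {
  x <- training_beats(6, seed = 3)
  one <- select_hidden_size(x, train_config(alpha = 0.2, epochs = 50,
                                            seed = 1, candidates = 14))
  expect_equal(one$nd, 14L)
  sel <- select_hidden_size(x, train_config(alpha = 0.2, epochs = 150,
                                            seed = 1,
                                            candidates = c(12, 14, 16)))
  expect_length(sel$energies, 3)
  expect_equal(unname(sel$energies[as.character(sel$nd)]),
               min(sel$energies))
})

test_that("the 67% study split is seeded and covers all beats", {
  sp <- train_split(40, 0.67, seed = 2)
  expect_length(sp$train, round(0.67 * 40))
  expect_setequal(c(sp$train, sp$test), 1:40)
  expect_identical(sp, train_split(40, 0.67, seed = 2))
})

test_that("divergence aborts with an informative error", {
  x <- training_beats(4)
  expect_error(
    train_network(x, 4, train_config(alpha = 1e9, epochs = 50, seed = 1)),
    "diverged")
})
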