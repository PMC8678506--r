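test_that("analytic gradients match numerical differentiation for every cell", {
  for (cell in c("rnn", "lstm", "decay_rnn", "ode_rnn")) {
    expect_lt(grad_check(cell), 1e-4)
  }
})

test_that("plain RNN forward has the degenerate-weight and symmetry properties", {
  w <- toy_window(c(2, 10, 18), cbind(c(0.2, 0.5, 0.9), c(0.1, 0.4, 0.7)),
                  matrix(1L, 3, 2))
  p <- sicdic:::init_seq_params("rnn", 4, 5, 2, seed = 3)

  # zero weights: hidden state is the bias activation, independent of input
  p0 <- p
  p0$Wx[] <- 0; p0$Wh[] <- 0; p0$b[] <- 0.3
  h1 <- rnn_forward(w, p0)
  w_other <- toy_window(c(1, 12), cbind(c(0.9, 0.1), c(0.3, 0.3)), matrix(1L, 2, 2))
  expect_equal(h1, rnn_forward(w_other, p0))
  expect_equal(unname(h1), rep(tanh(0.3), 5))

  # permuting variables together with the matching input-weight rows is a no-op
  w_perm <- w
  w_perm$x <- w$x[, 2:1]; w_perm$m <- w$m[, 2:1]; w_perm$delta <- w$delta[, 2:1]
  colnames(w_perm$x) <- colnames(w$x); colnames(w_perm$m) <- colnames(w$m)
  p_perm <- p
  p_perm$Wx <- p$Wx[c(2, 1, 4, 3), ]  # grid view input is (x_1, x_2, m_1, m_2)
  expect_equal(rnn_forward(w, p), rnn_forward(w_perm, p_perm))

  # single-cell window is exactly one recurrent step
  w1 <- toy_window(c(3), matrix(c(0.4, 0.8), 1), matrix(1L, 1, 2),
                   window_end_h = 24)
  b1 <- sicdic:::build_seq_batch(list(w1), "grid", grid_h = 24)
  u <- sicdic:::batch_input(b1, 1)
  expect_equal(drop(tanh(u %*% p$Wx + p$b)),
               drop(sicdic:::seq_forward_batch(p, b1, "rnn")$h))
})

test_that("decay cell: unit gamma at zero gap reduces to the plain RNN step and shrinkage is monotone in the gap", {
  D <- 2; H <- 4
  p <- sicdic:::init_seq_params("decay_rnn", 3 * D, H, 2, seed = 8)
  p$b_gamma[] <- 0
  # single observation at the window start: gap 0 -> gamma = exp(0) = 1
  w0 <- toy_window(c(0), matrix(c(0.3, 0.6), 1), matrix(1L, 1, 2), window_end_h = 24)
  h_decay <- decay_rnn_forward(w0, p)
  b0 <- sicdic:::build_seq_batch(list(w0), "event")
  u <- sicdic:::batch_input(b0, 1)
  h_plain <- drop(tanh(u %*% p$Wx + p$b))  # plain step from h = 0
  expect_equal(h_decay, h_plain, tolerance = 1e-12)

  # monotone: with positive rates, a longer gap shrinks the pre-update state more
  p$w_gamma[] <- abs(p$w_gamma) + 0.05
  h_after_gap <- function(g) {
    # two observations, the second after gap g: inspect the decayed state
    gamma <- exp(-pmax(drop(p$w_gamma) * g + drop(p$b_gamma), 0))
    h1 <- h_plain
    gamma * h1
  }
  expect_true(all(abs(h_after_gap(10)) < abs(h_after_gap(5))))
  expect_true(all(abs(h_after_gap(5)) < abs(h_after_gap(1e-9)) + 1e-12))
  # and gamma -> 0 for very large gaps
  expect_true(all(exp(-pmax(drop(p$w_gamma) * 1e6 + drop(p$b_gamma), 0)) < 1e-10))

  w_bad <- toy_window(c(2, 5), matrix(0.5, 2, 2), matrix(1L, 2, 2))
  w_bad$dt <- c(2, -3)  # negative gap = unsorted input
  expect_error(decay_rnn_forward(w_bad, p), "unsorted")
})

test_that("ODE-RNN with zero dynamics equals the plain recurrent cell on the event sequence", {
  D <- 2
  p <- sicdic:::init_seq_params("ode_rnn", 3 * D, 4, 2, seed = 12)
  p$W1[] <- 0; p$W2[] <- 0; p$b1[] <- 0
  w <- toy_window(c(1, 7, 16), matrix(runif(6), 3, 2), matrix(1L, 3, 2))
  h_ode <- ode_rnn_forward(w, p)
  b <- sicdic:::build_seq_batch(list(w), "event")
  h_rnn <- drop(sicdic:::seq_forward_batch(p, b, "rnn")$h)
  expect_equal(h_ode, h_rnn, tolerance = 1e-10)
  # batched ODE path agrees too
  h_ode_batch <- drop(sicdic:::seq_forward_batch(p, b, "ode_rnn", n_substeps = 3)$h)
  expect_equal(h_ode_batch, h_rnn, tolerance = 1e-10)
})

test_that("ODE solutions compose over subintervals and match the linear-decay closed form", {
  expect_equal(rk4_solve(function(h, t) -h, 1, 0, 1, 0.05), exp(-1), tolerance = 1e-6)
  set.seed(4)
  for (i in 1:20) {
    H <- 3
    W <- matrix(rnorm(H * H, 0, 0.4), H, H)
    f <- function(h, t) tanh(h) %*% W
    h0 <- rnorm(H)
    t_end <- runif(1, 0.5, 3)
    one <- rk4_solve(f, h0, 0, t_end, 0.05)
    split_at <- runif(1, 0.1, t_end - 0.1)
    two <- rk4_solve(f, rk4_solve(f, h0, 0, split_at, 0.05), split_at, t_end, 0.05)
    expect_lt(max(abs(one - two)), 1e-4)
  }
})

test_that("ODE-RNN hidden state is queryable at arbitrary times, consistently with the full solve", {
  p <- sicdic:::init_seq_params("ode_rnn", 6, 4, 2, seed = 21)
  w <- toy_window(c(2, 9, 15), matrix(runif(6), 3, 2), matrix(1L, 3, 2))
  h_end <- ode_rnn_forward(w, p, ode_step_h = 0.05)
  # query at the last observation then evolve manually to the window end
  h_at_15 <- ode_rnn_forward(w, p, query_t = 15, ode_step_h = 0.05)
  f <- function(h, t) drop(sicdic:::ode_f_forward(p, matrix(h, 1))$out)
  expect_equal(rk4_solve(f, h_at_15, 15, 24, 0.05), h_end, tolerance = 1e-6)
  expect_error(ode_rnn_forward(w, p, query_t = 30), "outside")
})

test_that("gap perturbations are invisible to the discretized RNN but visible to continuous-time cells", {
  # twins: same values, same grid cells, different within-cell timing
  x <- cbind(c(0.2, 0.6, 0.9), c(0.5, 0.1, 0.7))
  m <- matrix(1L, 3, 2)
  wa <- toy_window(c(1, 5, 17), x, m)
  wb <- toy_window(c(1, 3, 19), x, m)  # cells (1,1,3) in both at 8 h grid
  p_rnn <- sicdic:::init_seq_params("rnn", 4, 4, 2, seed = 2)
  expect_equal(rnn_forward(wa, p_rnn), rnn_forward(wb, p_rnn))

  p_dec <- sicdic:::init_seq_params("decay_rnn", 6, 4, 2, seed = 2)
  p_dec$w_gamma[] <- 0.1
  expect_false(isTRUE(all.equal(decay_rnn_forward(wa, p_dec),
                                decay_rnn_forward(wb, p_dec))))
  p_ode <- sicdic:::init_seq_params("ode_rnn", 6, 4, 2, seed = 2)
  expect_false(isTRUE(all.equal(ode_rnn_forward(wa, p_ode),
                                ode_rnn_forward(wb, p_ode))))
})

test_that("risk heads are sigmoidal, independent, and 0.5 at zero weights", {
  w <- make_toy_windows(4, seed = 3)
  p <- sicdic:::init_seq_params("rnn", 4, 4, 2, seed = 2)
  model <- structure(list(params = p, config = seq_model_config("rnn", hidden_dim = 4),
                          heads = sicdic:::head_info(c("sic_h8", "dic_h8")),
                          variables = c("A", "B"), model_id = "rnn"),
                     class = "seq_model")
  model$params$Wy[] <- 0; model$params$by[] <- 0
  ps <- predict_risk(model, w)
  expect_true(all(ps$risk == 0.5))
  # raising one head's bias raises only that head's risk
  model$params$by[1, 1] <- 2
  ps2 <- predict_risk(model, w)
  expect_true(all(ps2$risk[ps2$disease == "sic"] > 0.5))
  expect_true(all(ps2$risk[ps2$disease == "dic"] == 0.5))
  expect_true(all(ps2$risk >= 0 & ps2$risk <= 1))
})

test_that("training separates a constructed separable problem and is seed-deterministic", {
  wins <- make_toy_windows(400, seed = 6)
  tr <- wins[1:300]; va <- wins[301:400]
  cfg <- seq_model_config("rnn", hidden_dim = 8, epochs = 30, seed = 4,
                          learning_rate = 0.02, patience = 30)
  m1 <- train_sequence_model(tr, va, cfg)
  ps <- predict_risk(m1, va)
  p <- ps[ps$disease == "dic", ]
  expect_gt(auroc(p$risk, p$target), 0.95)

  m2 <- train_sequence_model(tr, va, cfg)
  expect_identical(m1$params, m2$params)

  # all-one-class targets abort with a message
  one_class <- lapply(wins[1:50], function(w) { w$targets$sic <- 1L; w$targets$dic <- 1L; w })
  expect_error(train_sequence_model(one_class, one_class, cfg), "one class")
})

test_that("training on shuffled labels yields chance-level validation AUROC", {
  wins <- make_toy_windows(700, seed = 8)
  set.seed(1)
  perm <- sample(700)
  shuffled <- lapply(seq_along(wins), function(i) {
    w <- wins[[i]]
    w$targets <- wins[[perm[i]]]$targets
    w
  })
  tr <- shuffled[1:350]; va <- shuffled[351:700]
  m <- train_sequence_model(tr, va, seq_model_config("rnn", hidden_dim = 8,
                                                     epochs = 10, seed = 4,
                                                     patience = 10))
  ps <- predict_risk(m, va)
  p <- ps[ps$disease == "dic", ]
  expect_gt(auroc(p$risk, p$target), 0.4)
  expect_lt(auroc(p$risk, p$target), 0.6)
})

test_that("tabular baselines separate constructed problems and respect the probability contract", {
  wins <- make_toy_windows(400, seed = 16)
  tr <- wins[1:300]; te <- wins[301:400]
  lr <- suppressWarnings(train_tabular_baselines(tr, "lr", seed = 1))
  p_lr <- predict_risk(lr, te)
  p <- p_lr[p_lr$disease == "dic", ]
  expect_gt(auroc(p$risk, p$target), 0.95)

  # nonlinear band labels: boosted trees beat logistic regression
  nl <- make_toy_windows(600, seed = 17,
                         label_fn = function(z) as.integer(z > 0.35 & z < 0.65))
  tr2 <- nl[1:450]; te2 <- nl[451:600]
  lr2 <- suppressWarnings(train_tabular_baselines(tr2, "lr", seed = 1))
  xg2 <- train_tabular_baselines(tr2, "xgb", seed = 1, nrounds = 80)
  dic8 <- function(ps) ps[ps$disease == "dic" & ps$horizon_h == 8, ]
  p_lr2 <- dic8(predict_risk(lr2, te2))
  p_xg2 <- dic8(predict_risk(xg2, te2))
  expect_gt(auroc(p_xg2$risk, p_xg2$target), auroc(p_lr2$risk, p_lr2$target))

  # probabilities in [0, 1] for every model family (small fits)
  for (mid in c("lr", "svm", "xgb", "xgb_dart")) {
    fit <- suppressWarnings(train_tabular_baselines(wins[1:120], mid, seed = 2,
                                                    nrounds = 20, svm_max_rows = 120))
    pr <- predict_risk(fit, wins[121:160])
    expect_true(all(pr$risk >= 0 & pr$risk <= 1, na.rm = TRUE))
  }

  # constant features are dropped with a warning
  set.seed(9)
  const_w <- lapply(1:80, function(i) {
    toy_window(c(2, 10, 18), cbind(runif(3), 0.5), matrix(1L, 3, 2),
               targets = data.frame(horizon_h = 8, sic = rbinom(1, 1, 0.5),
                                    dic = rbinom(1, 1, 0.5)))
  })
  expect_warning(train_tabular_baselines(const_w, "lr"), "constant")
})
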