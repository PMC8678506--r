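test_that("mask and interval recurrence follow their definitions", {
  X <- matrix(c(1, NA, 3, NA, NA, 6), 2, 3)
  expect_equal(compute_mask(X), matrix(c(1L, 0L, 1L, 0L, 0L, 1L), 2, 3))
  expect_equal(compute_mask(matrix(1:3, 1)), matrix(c(1L, 1L, 1L), 1))
  expect_equal(compute_mask(matrix(NA_real_, 1, 3)), matrix(c(0L, 0L, 0L), 1))

  # worked recurrence examples
  expect_equal(drop(compute_intervals(c(0, 3, 7), matrix(c(1, 0, 1)))), c(0, 3, 7))
  expect_equal(drop(compute_intervals(c(0, 2, 5), matrix(c(1, 1, 1)))), c(0, 2, 3))
  expect_equal(drop(compute_intervals(4.2, matrix(1))), 0)
  expect_error(compute_intervals(c(3, 1), matrix(c(1, 1))), "sorted")
})

test_that("interval recurrence equals the naive backward scan on random instances", {
  set.seed(7)
  for (i in 1:200) {
    Tn <- sample(1:12, 1); D <- sample(1:4, 1)
    s <- sort(runif(Tn, 0, 48))
    m <- matrix(rbinom(Tn * D, 1, 0.5), Tn, D)
    expect_equal(unname(compute_intervals(s, m)), intervals_bruteforce(s, m))
  }
})

test_that("min-max normalization maps training extremes to [0, 1] and clamps beyond", {
  ev <- make_stream("P1", 1:4, rep("PLT", 4), c(100, 150, 200, 300))
  cfg <- encoding_config(variables = "PLT")
  norm <- fit_normalization(ev, "P1", cfg)
  expect_equal(normalize_values(100, "PLT", norm, cfg), 0)
  expect_equal(normalize_values(300, "PLT", norm, cfg), 1)
  expect_equal(normalize_values(200, "PLT", norm, cfg), 0.5)
  expect_equal(normalize_values(500, "PLT", norm, cfg), 1)  # above max clamps

  ev2 <- rbind(ev, make_stream("P1", 1, "INR", 1.2))
  cfg2 <- encoding_config(variables = c("PLT", "INR"))
  expect_warning(norm2 <- fit_normalization(ev2, "P1", cfg2), "constant")
  expect_true(norm2$constant[norm2$variable == "INR"])
  expect_error(normalize_values(1.2, "INR", norm2, cfg2), "constant")
})

test_that("window positions, boundary membership, and degenerate stays behave as specified", {
  cfg <- encoding_config()
  ev <- make_stream("P1", c(0, 8, 16.0, 30, 50, 70), rep("PLT", 6), 100 + 1:6)
  tl <- data.frame(patient_id = "P1", window_index = 0:8, window_start_h = 8 * (0:8),
                   sic_label = 0L, dic_label = 0L)
  attr(tl, "window_len_h") <- 8
  norm <- suppressWarnings(fit_normalization(ev, "P1", cfg))
  # 72 h stay, 24 h window, 8 h slide -> 7 positions starting 0, 8, ..., 48
  w <- build_windows(ev, tl, cfg, norm, drop_unlabeled = FALSE)
  expect_equal(length(w), 7)
  expect_equal(vapply(w, `[[`, numeric(1), "window_start_h"), seq(0, 48, 8))

  # event at t = 16 belongs to the window starting there (half-open membership)
  w0 <- w[[1]]; w3 <- w[[3]]  # [0,24) and [16,40)
  expect_true(16 %in% w0$s)       # 16 in [0, 24)
  expect_true(16 %in% w3$s)       # 16 in [16, 40): inclusive at its own start
  w2 <- w[[2]]                    # [8, 32)
  expect_false(any(w2$s == 32))   # end boundary excluded

  # windowing count property over random stays
  set.seed(5)
  for (stay in c(24, 40, 72, 104, 240)) {
    n_lab <- stay / 8
    tl2 <- data.frame(patient_id = "P1", window_index = 0:(n_lab - 1),
                      window_start_h = 8 * (0:(n_lab - 1)), sic_label = 0L, dic_label = 0L)
    attr(tl2, "window_len_h") <- 8
    w2 <- build_windows(ev, tl2, cfg, norm, drop_unlabeled = FALSE)
    expect_equal(length(w2), floor((stay - 24) / 8) + 1)
  }

  # stay shorter than the sampling window -> zero windows
  tl3 <- tl[1:2, ]; attr(tl3, "window_len_h") <- 8
  expect_equal(length(build_windows(ev, tl3, cfg, norm, drop_unlabeled = FALSE)), 0)
})

test_that("empty windows are kept as all-zero-mask query rows with continued intervals", {
  cfg <- encoding_config()
  ev <- make_stream("P1", c(0, 60), c("PLT", "PLT"), c(100, 120))
  tl <- data.frame(patient_id = "P1", window_index = 0:8, window_start_h = 8 * (0:8),
                   sic_label = 0L, dic_label = 0L)
  attr(tl, "window_len_h") <- 8
  norm <- suppressWarnings(fit_normalization(ev, "P1", cfg))
  w <- build_windows(ev, tl, cfg, norm, drop_unlabeled = FALSE)
  w2 <- w[[2]]  # [8, 32): no observations
  expect_equal(sum(w2$m), 0)
  expect_equal(length(w2$s), 1)
  expect_equal(w2$s, 32)                       # query row at the window end
  expect_equal(unname(w2$delta[1, "PLT"]), 32)         # time since PLT at t = 0
})

test_that("mask totals are conserved over a disjoint tiling of the stay", {
  coh <- generate_cohort(cohort_config(5, seed = 21, max_stay_h = 96, min_stay_h = 96))
  cfg <- encoding_config(sampling_window_h = 24, slide_step_h = 24, horizons_h = c(24, 48))
  tls <- label_cohort(coh, window_len_h = 24)
  norm <- fit_normalization(coh$events, coh$truth$patient_id, cfg)
  for (pid in coh$truth$patient_id) {
    ev <- coh$events[coh$events$patient_id == pid, ]
    ev <- ev[ev$variable %in% norm$variable[!norm$constant], ]
    w <- build_windows(ev, tls[[pid]], cfg, norm, drop_unlabeled = FALSE)
    covered <- ev$time_h < max(vapply(w, `[[`, numeric(1), "window_end_h"))
    expect_equal(sum(vapply(w, function(x) sum(x$m), numeric(1))), sum(covered))
  }
})

test_that("horizon targets align to the labeled window at window-end + horizon", {
  cfg <- encoding_config(horizons_h = c(8, 16))
  ev <- make_stream("P1", c(0, 10, 20, 30), rep("PLT", 4), c(100, 110, 120, 130))
  lab <- c(0L, 0L, 0L, 0L, 1L, 1L, 0L)  # windows 0..6 (stay 56 h)
  tl <- data.frame(patient_id = "P1", window_index = 0:6, window_start_h = 8 * (0:6),
                   sic_label = lab, dic_label = lab)
  attr(tl, "window_len_h") <- 8
  norm <- suppressWarnings(fit_normalization(ev, "P1", cfg))
  w <- build_windows(ev, tl, cfg, norm)
  w1 <- w[[1]]  # [0, 24): horizon 8 -> t = 32 -> window 4 (label 1)
  expect_equal(w1$targets$sic[w1$targets$horizon_h == 8], 1L)
  # horizon 16 -> t = 40 -> window 5 (label 1)
  expect_equal(w1$targets$sic[w1$targets$horizon_h == 16], 1L)
  w2 <- w[[2]]  # [8, 32): horizon 8 -> t = 40 -> window 5 (1); 16 -> 48 -> window 6 (0)
  expect_equal(w2$targets$sic, c(1L, 0L))
})

test_that("encoding a test patient is unaffected by which other test patients are present", {
  coh <- generate_cohort(cohort_config(12, seed = 17))
  tls <- label_cohort(coh)
  cfg <- encoding_config()
  ids <- coh$truth$patient_id
  train <- ids[1:8]; test <- ids[9:12]
  norm <- fit_normalization(coh$events, train, cfg)
  ev_one <- coh$events[coh$events$patient_id == test[1], ]
  w_alone <- build_windows(ev_one, tls[[test[1]]], cfg, norm)
  w_together <- encode_cohort(coh$events[coh$events$patient_id %in% test, ],
                              tls[test], cfg, norm)
  w_same <- Filter(function(w) w$patient_id == test[1], w_together)
  expect_equal(w_alone, w_same)
})

test_that("discretized feature vectors have the documented layout and values", {
  s <- c(2, 10, 18)
  x <- cbind(c(0.2, 0.5, 0.9), c(0.1, 0.4, 0.7))
  w <- toy_window(s, x, matrix(1L, 3, 2))
  f <- discretize_for_tabular(w, grid_h = 8)
  expect_length(f, 3 * 2 * 2 + 2)
  # one observation per cell: last-value slots equal the observations
  expect_equal(unname(f[c("A_v1", "A_v2", "A_v3")]), c(0.2, 0.5, 0.9))
  expect_equal(unname(f[c("B_n1", "B_n2", "B_n3")]), c(1, 1, 1))
  # empty window: fills, zero counts, continued deltas
  w0 <- toy_window(24 - 1e-9, matrix(0, 1, 2), matrix(0L, 1, 2))
  f0 <- discretize_for_tabular(w0, grid_h = 8)
  expect_true(all(f0[grepl("_v", names(f0))] == 0))
  expect_true(all(f0[grepl("_n", names(f0))] == 0))
})

test_that("window tensors round-trip through JSON lines", {
  coh <- generate_cohort(cohort_config(4, seed = 23))
  tls <- label_cohort(coh)
  cfg <- encoding_config()
  norm <- fit_normalization(coh$events, coh$truth$patient_id, cfg)
  w <- encode_cohort(coh, tls, cfg, norm)
  f <- tempfile()
  write_window_tensors(w, f)
  w2 <- read_window_tensors(f)
  expect_equal(length(w), length(w2))
  expect_equal(w[[1]]$x, w2[[1]]$x)
  expect_equal(w[[3]]$delta, w2[[3]]$delta)
  expect_equal(w[[2]]$targets, w2[[2]]$targets)
  expect_equal(w[[1]]$dt, w2[[1]]$dt)
})
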