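# Fixtures built in code: event streams, hand-made window tensors, toy
# separable window sets, and a crafted one-signal cohort for occlusion tests.

make_stream <- function(pid, times, variables, values) {
  data.frame(patient_id = pid, time_h = times, variable = variables,
             value = values, unit = "u", stringsAsFactors = FALSE)
}

# minimal hand-built window tensor (D variables named A, B, ...)
toy_window <- function(s, x, m, window_start_h = 0, window_end_h = 24,
                       targets = data.frame(horizon_h = 8, sic = 0L, dic = 0L),
                       pid = "P1") {
  x <- as.matrix(x); m <- as.matrix(m)
  vars <- LETTERS[seq_len(ncol(x))]
  colnames(x) <- vars; colnames(m) <- vars
  delta <- compute_intervals(s, m)
  structure(list(
    patient_id = pid, window_start_h = window_start_h,
    window_end_h = window_end_h, s = s, x = x, m = m, delta = delta,
    dt = c(s[1] - window_start_h, diff(s)),
    delta_end = sicdic:::delta_at_time(s, m, window_end_h),
    n_obs = sum(m), targets = targets, variables = vars
  ), class = "window_tensor")
}

# n windows, D = 2: variable A carries the label (its level ~ target),
# variable B is pure noise; irregular times, full masks.
make_toy_windows <- function(n, seed = 1, signal = TRUE, noise_sd = 0.05,
                             label_fn = NULL) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    z <- stats::runif(1)
    y <- if (is.null(label_fn)) as.integer(z > 0.5) else label_fn(z)
    Tn <- sample(3:6, 1)
    s <- sort(stats::runif(Tn, 0, 24))
    a <- if (signal) pmin(pmax(z + stats::rnorm(Tn, 0, noise_sd), 0), 1) else stats::runif(Tn)
    b <- stats::runif(Tn)
    toy_window(s, cbind(a, b), matrix(1L, Tn, 2),
               targets = data.frame(horizon_h = 8, sic = y, dic = y),
               pid = sprintf("P%04d", i))
  })
}

# crafted cohort whose labels are driven by a single variable SIG;
# N1 and N2 are noise. Returns events, timelines, config, norm, latent p.
one_signal_cohort <- function(n_patients = 80, seed = 11, stay_h = 72,
                              label_fn = function(p) as.integer(p > 0.5)) {
  set.seed(seed)
  vars <- c("SIG", "N1", "N2")
  cfg <- encoding_config(variables = vars, horizons_h = 8,
                         ranges = list(SIG = c(0, 1), N1 = c(0, 1), N2 = c(0, 1)))
  events <- list(); timelines <- list(); p_lat <- numeric(n_patients)
  n_win <- stay_h / 8
  for (i in seq_len(n_patients)) {
    pid <- sprintf("S%04d", i)
    p <- stats::runif(1)
    p_lat[i] <- p
    tt <- seq(0, stay_h - 1, by = 2)
    ev <- rbind(
      make_stream(pid, tt, "SIG", pmin(pmax(p + stats::rnorm(length(tt), 0, 0.03), 0), 1)),
      make_stream(pid, tt + 0.5, "N1", stats::runif(length(tt))),
      make_stream(pid, tt + 1.0, "N2", stats::runif(length(tt)))
    )
    events[[i]] <- ev
    y <- label_fn(p)
    tl <- data.frame(patient_id = pid, window_index = 0:(n_win - 1),
                     window_start_h = 8 * (0:(n_win - 1)),
                     sic_label = y, dic_label = y,
                     sic_provenance = "observed", dic_provenance = "observed",
                     provenance = "observed", stringsAsFactors = FALSE)
    attr(tl, "window_len_h") <- 8
    class(tl) <- c("label_timeline", "data.frame")
    timelines[[pid]] <- tl
  }
  events <- do.call(rbind, events)
  norm <- suppressWarnings(fit_normalization(events, unique(events$patient_id), cfg))
  list(events = events, timelines = timelines, config = cfg, norm = norm,
       p = p_lat)
}

# numerical vs analytic gradients for one cell type; returns worst relative error
grad_check <- function(cell, seed = 5, eps = 1e-6) {
  set.seed(seed)
  view <- if (cell %in% c("rnn", "lstm")) "grid" else "event"
  N <- 3; D <- 2; Tn <- 4
  b <- list(X = array(stats::runif(N * D * Tn), c(N, D, Tn)),
            M = array(stats::rbinom(N * D * Tn, 1, 0.6), c(N, D, Tn)),
            DL = array(stats::runif(N * D * Tn, 0, 2), c(N, D, Tn)),
            DT = matrix(stats::runif(N * Tn, 0.1, 2), N, Tn),
            V = rbind(matrix(1, N - 1, Tn), c(rep(1, Tn - 1), 0)),
            N = N, T = Tn, D = D,
            input_dim = if (view == "grid") 2 * D else 3 * D,
            view = view, variables = c("A", "B"))
  Y <- matrix(c(1, 0, NA, 0, 1, 1), 3, 2)
  wp <- c(1.2, 0.8); wn <- c(0.9, 1.1)
  p <- sicdic:::init_seq_params(cell, b$input_dim, 3, 2, seed = seed)
  an <- sicdic:::seq_loss(p, b, cell, 2, Y, wp, wn)
  worst <- 0
  for (nm in names(p)) {
    for (i in seq_len(min(length(p[[nm]]), 5))) {
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
      l1 <- sicdic:::seq_loss(p2, b, cell, 2, Y, wp, wn, with_grads = FALSE)$loss
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      l0 <- sicdic:::seq_loss(p2, b, cell, 2, Y, wp, wn, with_grads = FALSE)$loss
      num <- (l1 - l0) / (2 * eps)
      worst <- max(worst, abs(num - an$grads[[nm]][i]) /
                     max(1e-6, abs(num) + abs(an$grads[[nm]][i])))
    }
  }
  worst
}

# independent brute-force AUROC oracle: all-pairs concordance, ties half
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# independent backward-scan oracle for the interval recurrence
intervals_bruteforce <- function(s, m) {
  out <- matrix(0, length(s), ncol(m))
  for (d in seq_len(ncol(m))) {
    for (t in seq_along(s)) {
      if (t == 1) { out[t, d] <- 0; next }
      prev_obs <- which(m[seq_len(t - 1), d] == 1)
      out[t, d] <- if (length(prev_obs)) s[t] - s[max(prev_obs)] else s[t] - s[1]
    }
  }
  out
}
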