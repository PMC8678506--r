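#' Encoding configuration for windowed model inputs
#'
#' Controls how irregular event streams become model-ready window tensors:
#' the sliding sampling window, prediction horizons, the discretization grid
#' used by fixed-dimension (tabular / discretized-RNN) views, and
#' normalization.
#'
#' @param variables ordered character vector of the D input variables
#' @param sampling_window_h sampling window length in hours (default 24)
#' @param slide_step_h slide between window starts (default 8); must divide
#'   the sampling window evenly
#' @param horizons_h prediction horizons in hours measured from the window
#'   end (default `8 * 1:6`); each must be a positive multiple of
#'   `slide_step_h`
#' @param discretization_grid_h grid-cell length for discretized views
#'   (default 8); must divide the sampling window
#' @param delta_scale_h scale used to bring time-since-last-observation
#'   features to unit order (default 24)
#' @param fill_value value carried by unobserved entries after normalization
#'   (default 0; the mask identifies them)
#' @param ranges named list of physiologic clamp ranges per variable
#'   (default [default_ranges()])
#' @return an object of class `encoding_config`
#' @export
encoding_config <- function(variables = default_panel(),
                            sampling_window_h = 24,
                            slide_step_h = 8,
                            horizons_h = 8 * (1:6),
                            discretization_grid_h = 8,
                            delta_scale_h = 24,
                            fill_value = 0,
                            ranges = default_ranges()) {
  if (sampling_window_h %% slide_step_h != 0) {
    stopf("slide_step_h (%s) must divide sampling_window_h (%s) evenly",
          slide_step_h, sampling_window_h)
  }
  if (any(horizons_h <= 0) || any(horizons_h %% slide_step_h != 0)) {
    stopf("horizons_h must be positive multiples of slide_step_h")
  }
  if (sampling_window_h %% discretization_grid_h != 0) {
    stopf("discretization_grid_h must divide sampling_window_h")
  }
  structure(list(
    variables = variables, sampling_window_h = sampling_window_h,
    slide_step_h = slide_step_h, horizons_h = horizons_h,
    discretization_grid_h = discretization_grid_h,
    delta_scale_h = delta_scale_h, fill_value = fill_value, ranges = ranges
  ), class = "encoding_config")
}

#' Observation mask
#'
#' `m[t, d] = 1` exactly where variable `d` is observed at timestamp `t`.
#' @param values numeric matrix (T x D) with `NA` where unobserved
#' @return integer 0/1 matrix of the same shape
#' @export
compute_mask <- function(values) {
  m <- 1L * !is.na(values)
  dimnames(m) <- dimnames(values)
  m
}

#' Time-since-last-observation intervals
#'
#' Per-variable recurrence: `delta[1, d] = 0`; for `t > 1`,
#' `delta[t, d] = s[t] - s[t-1]` if variable `d` was observed at `t-1`, else
#' `s[t] - s[t-1] + delta[t-1, d]` — i.e. elapsed time since the most recent
#' observation of `d`, accumulated through unobserved steps.
#'
#' @param s sorted numeric vector of T timestamps
#' @param m T x D observation mask
#' @return T x D numeric matrix of intervals
#' @export
#' @examples
#' compute_intervals(c(0, 3, 7), matrix(c(1, 0, 1), ncol = 1))  # 0, 3, 7
compute_intervals <- function(s, m) {
  if (is.unsorted(s)) stopf("timestamps must be sorted ascending")
  m <- as.matrix(m)
  T_ <- length(s)
  if (nrow(m) != T_) stopf("mask rows (%d) must match timestamps (%d)", nrow(m), T_)
  delta <- matrix(0, T_, ncol(m), dimnames = dimnames(m))
  if (T_ > 1) {
    gaps <- diff(s)
    for (t in 2:T_) {
      delta[t, ] <- gaps[t - 1] + delta[t - 1, ] * (m[t - 1, ] == 0)
    }
  }
  delta
}

#' Fit min-max normalization statistics on training patients
#'
#' Values are clamped to the configured physiologic range first, then the
#' per-variable training minimum and maximum are recorded. Variables whose
#' training values are constant (`min == max`) are flagged and dropped from
#' the encoded panel with a warning.
#'
#' @param events long events data.frame
#' @param train_ids patient ids of the training split; statistics never see
#'   other patients (no leakage)
#' @param config an [encoding_config()]
#' @return data.frame of class `norm_stats`: variable, min, max, constant
#' @export
fit_normalization <- function(events, train_ids, config = encoding_config()) {
  ev <- events[events$patient_id %in% train_ids & events$variable %in% config$variables, ]
  out <- lapply(config$variables, function(v) {
    x <- ev$value[ev$variable == v]
    rng <- config$ranges[[v]] %||% c(-Inf, Inf)
    x <- clamp(x, rng[1], rng[2])
    if (length(x) == 0) return(data.frame(variable = v, min = NA_real_, max = NA_real_, constant = TRUE))
    data.frame(variable = v, min = min(x), max = max(x), constant = min(x) == max(x))
  })
  ns <- do.call(rbind, out)
  if (any(ns$constant)) {
    warning(sprintf("constant/unseen variable(s) dropped from encoding: %s",
                    paste(ns$variable[ns$constant], collapse = ", ")))
  }
  class(ns) <- c("norm_stats", "data.frame")
  ns
}

#' Min-max normalize raw values
#'
#' Clamps to the physiologic range, then maps the training min/max to 0/1,
#' clamping out-of-range test values into `[0, 1]`.
#' @param values numeric vector of raw values
#' @param variable variable name
#' @param norm a `norm_stats` from [fit_normalization()]
#' @param config an [encoding_config()] (for the clamp ranges)
#' @return normalized values in `[0, 1]`
#' @export
normalize_values <- function(values, variable, norm, config = encoding_config()) {
  i <- match(variable, norm$variable)
  if (is.na(i)) stopf("no normalization stats for variable '%s'", variable)
  if (norm$constant[i]) stopf("variable '%s' was flagged constant and dropped", variable)
  rng <- config$ranges[[variable]] %||% c(-Inf, Inf)
  x <- clamp(values, rng[1], rng[2])
  clamp((x - norm$min[i]) / (norm$max[i] - norm$min[i]), 0, 1)
}

# Per-patient observation matrix on the union timestamp grid.
# Returns s (times), X raw (NA where unobserved), M mask.
patient_matrix <- function(events, variables) {
  ev <- events[events$variable %in% variables, , drop = FALSE]
  ev <- ev[order(ev$time_h), , drop = FALSE]
  s <- sort(unique(ev$time_h))
  X <- matrix(NA_real_, length(s), length(variables),
              dimnames = list(NULL, variables))
  if (nrow(ev)) {
    ti <- match(ev$time_h, s)
    vi <- match(ev$variable, variables)
    X[cbind(ti, vi)] <- ev$value  # later duplicates overwrite earlier
  }
  list(s = s, X = X, M = compute_mask(X))
}

# delta at an arbitrary query time from the full-history observation times:
# time since the most recent observation of each variable at or before t_q,
# accumulating from the first stream timestamp when never observed.
delta_at_time <- function(s, M, t_q) {
  D <- ncol(M)
  out <- numeric(D)
  for (d in seq_len(D)) {
    obs <- s[M[, d] == 1 & s <= t_q]
    out[d] <- if (length(obs)) t_q - max(obs) else t_q - s[1]
  }
  out
}

#' Build sliding-window tensors for one patient
#'
#' Slides a `sampling_window_h` window in `slide_step_h` steps over the stay
#' (window membership is half-open, `time in [start, end)`). Each window
#' carries the in-window timestamps, normalized values (fill where
#' unobserved), mask, global adjacent time steps, per-variable
#' time-since-observation intervals continued across window boundaries from
#' the full patient history, and per-horizon SIC/DIC targets taken from the
#' label timeline window containing `window_end + horizon`. Windows with no
#' in-window observation are retained as a single all-zero-mask query row at
#' the window end (the missingness itself is signal); windows whose targets
#' are absent at every horizon are dropped unless `drop_unlabeled = FALSE`.
#'
#' @param events long events data.frame for one patient
#' @param timeline the patient's `label_timeline`
#' @param config an [encoding_config()]
#' @param norm `norm_stats` from [fit_normalization()]
#' @param drop_unlabeled drop windows with no target at any horizon
#' @return list of `window_tensor` objects
#' @export
build_windows <- function(events, timeline, config, norm, drop_unlabeled = TRUE) {
  vars <- norm$variable[!norm$constant]
  vars <- config$variables[config$variables %in% vars]
  win_len <- attr(timeline, "window_len_h") %||% config$slide_step_h
  stay_h <- nrow(timeline) * win_len
  W <- config$sampling_window_h
  if (stay_h < W) return(list())
  pm <- patient_matrix(events, vars)
  Xn <- pm$X
  for (d in seq_along(vars)) {
    obs <- !is.na(Xn[, d])
    Xn[obs, d] <- normalize_values(pm$X[obs, d], vars[d], norm, config)
  }
  Xn[is.na(Xn)] <- config$fill_value
  delta_full <- compute_intervals(pm$s, pm$M)

  starts <- seq(0, stay_h - W, by = config$slide_step_h)
  out <- vector("list", length(starts))
  pid <- events$patient_id[1]
  for (k in seq_along(starts)) {
    st <- starts[k]; en <- st + W
    idx <- which(pm$s >= st & pm$s < en)
    if (length(idx)) {
      s_w <- pm$s[idx]
      x_w <- Xn[idx, , drop = FALSE]
      m_w <- pm$M[idx, , drop = FALSE]
      d_w <- delta_full[idx, , drop = FALSE]
    } else {
      # query row at the window end: nothing observed, delta continued
      s_w <- en
      x_w <- matrix(config$fill_value, 1, length(vars), dimnames = list(NULL, vars))
      m_w <- matrix(0L, 1, length(vars), dimnames = list(NULL, vars))
      d_w <- matrix(delta_at_time(pm$s, pm$M, en), 1, length(vars),
                    dimnames = list(NULL, vars))
    }
    dt <- c(s_w[1] - st, diff(s_w))
    tg <- data.frame(horizon_h = config$horizons_h,
                     sic = NA_integer_, dic = NA_integer_)
    for (j in seq_along(config$horizons_h)) {
      wi <- floor((en + config$horizons_h[j]) / win_len)
      row <- match(wi, timeline$window_index)
      if (!is.na(row)) {
        tg$sic[j] <- timeline$sic_label[row]
        tg$dic[j] <- timeline$dic_label[row]
      }
    }
    out[[k]] <- structure(list(
      patient_id = pid, window_start_h = st, window_end_h = en,
      s = s_w, x = x_w, m = m_w, delta = d_w, dt = dt,
      delta_end = delta_at_time(pm$s, pm$M, en),
      n_obs = sum(m_w), targets = tg, variables = vars
    ), class = "window_tensor")
  }
  if (drop_unlabeled) {
    keep <- vapply(out, function(w) any(!is.na(w$targets$sic)) || any(!is.na(w$targets$dic)),
                   logical(1))
    out <- out[keep]
  }
  out
}

#' Encode every patient of a cohort into window tensors
#'
#' @param cohort a `sic_cohort` or long events data.frame
#' @param timelines named list of `label_timeline`s from [label_cohort()]
#' @param config an [encoding_config()]
#' @param norm `norm_stats` from [fit_normalization()]
#' @param drop_unlabeled see [build_windows()]
#' @return flat list of `window_tensor`s across patients
#' @export
encode_cohort <- function(cohort, timelines, config, norm, drop_unlabeled = TRUE) {
  ev <- if (inherits(cohort, "sic_cohort")) cohort$events else cohort
  by_pat <- split(ev, ev$patient_id)
  out <- lapply(names(timelines), function(pid) {
    pe <- by_pat[[pid]]
    if (is.null(pe) || nrow(pe) == 0) return(list())
    build_windows(pe, timelines[[pid]], config, norm, drop_unlabeled)
  })
  do.call(c, out)
}

#' Flatten one window into a fixed-length feature vector
#'
#' Temporal discretization for tabular models: the window is cut into
#' `sampling_window_h / grid_h` non-overlapping cells; each cell contributes,
#' per variable, the last observed normalized value (fill when none) and the
#' observation count; the vector ends with each variable's
#' time-since-last-observation at the window end (scaled by `delta_scale_h`).
#' Length: `n_cells * 2 * D + D`.
#'
#' @param window a `window_tensor`
#' @param grid_h grid-cell length (default: the config's grid recorded at
#'   build time is not stored, so pass the same value used in
#'   [encoding_config()]; default 8)
#' @param fill_value fill for cells without an observation
#' @param delta_scale_h scale for the trailing interval block
#' @return named numeric vector
#' @export
discretize_for_tabular <- function(window, grid_h = 8, fill_value = 0,
                                   delta_scale_h = 24) {
  W <- window$window_end_h - window$window_start_h
  if (W %% grid_h != 0) stopf("grid_h must divide the window length")
  n_cells <- W / grid_h
  vars <- window$variables
  D <- length(vars)
  vals <- matrix(fill_value, n_cells, D)
  cnts <- matrix(0, n_cells, D)
  for (t in seq_along(window$s)) {
    if (sum(window$m[t, ]) == 0) next
    cell <- min(floor((window$s[t] - window$window_start_h) / grid_h) + 1, n_cells)
    obs <- which(window$m[t, ] == 1)
    vals[cell, obs] <- window$x[t, obs]
    cnts[cell, obs] <- cnts[cell, obs] + 1
  }
  feat <- numeric(0)
  nm <- character(0)
  for (cell in seq_len(n_cells)) {
    feat <- c(feat, vals[cell, ], cnts[cell, ])
    nm <- c(nm, paste0(vars, "_v", cell), paste0(vars, "_n", cell))
  }
  feat <- c(feat, window$delta_end / delta_scale_h)
  nm <- c(nm, paste0(vars, "_delta"))
  stats::setNames(feat, nm)
}

#' Write / read window tensors as JSON lines
#'
#' One JSON object per window (arrays for `s`, `x`, `m`, `delta`, `dt`; map of
#' horizon targets). Normalization stats can be written alongside with
#' [jsonlite::write_json()].
#' @param windows list of `window_tensor`s
#' @param path output path
#' @return `path` invisibly; the reader returns the list of windows
#' @export
write_window_tensors <- function(windows, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (w in windows) {
    rec <- list(patient_id = w$patient_id, window_start_h = w$window_start_h,
                window_end_h = w$window_end_h, s = w$s,
                x = unname(as.data.frame(w$x)), m = unname(as.data.frame(w$m)),
                delta = unname(as.data.frame(w$delta)), dt = w$dt,
                delta_end = w$delta_end, n_obs = w$n_obs,
                targets = w$targets, variables = w$variables)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_window_tensors
#' @export
read_window_tensors <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    r <- jsonlite::fromJSON(ln, simplifyMatrix = TRUE)
    vars <- r$variables
    as_mat <- function(a) {
      m <- as.matrix(as.data.frame(a))
      dimnames(m) <- list(NULL, vars)
      m
    }
    structure(list(
      patient_id = r$patient_id, window_start_h = r$window_start_h,
      window_end_h = r$window_end_h, s = r$s, x = as_mat(r$x),
      m = as_mat(r$m), delta = as_mat(r$delta), dt = r$dt,
      delta_end = r$delta_end, n_obs = r$n_obs,
      targets = as.data.frame(r$targets), variables = vars
    ), class = "window_tensor")
  })
}
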