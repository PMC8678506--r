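#' Synthetic sepsis cohort configuration
#'
#' Parameters of the synthetic cohort generator. The generator emulates the
#' qualitative structure of real ICU coagulation data: irregular per-variable
#' sampling, missingness whose rate rises with latent disease severity, and
#' coagulation-marker trajectories that drive SIC onset and, in a subset,
#' progression to overt DIC. Default target prevalences follow the reported
#' sepsis-cohort rates (SIC 37.1%, DIC 17.8%). All trajectory parameters are
#' openly synthetic stand-ins: no distributional facts about the private
#' hospital cohorts are available beyond those prevalences.
#'
#' @param n_patients number of patients to generate
#' @param max_stay_h maximum length of stay in hours (default 240)
#' @param target_sic_prevalence fraction of patients that develop SIC
#' @param target_dic_prevalence fraction that progress to overt DIC
#'   (must not exceed `target_sic_prevalence`; progression is sequential)
#' @param sampling_rate_base expected observations per variable per 24 h
#' @param severity_sampling_coupling nonnegative coefficient linking latent
#'   severity (0 = sepsis, 1 = SIC, 2 = DIC) to sampling intensity;
#'   0 switches informative missingness off
#' @param noise_scale per-variable multiplicative lognormal noise sd
#' @param seed integer master seed; per-patient substreams are derived
#'   deterministically from `(seed, patient index)`
#' @param variables character panel of variables to emit (default
#'   [default_panel()])
#' @param min_stay_h minimum stay (default 72 h, matching a >= 3 day
#'   inclusion criterion)
#' @param mean_extra_stay_h mean of the exponential stay extension beyond
#'   `min_stay_h` (default 84 h)
#' @param transition_ramp_h hours over which variable means ramp from one
#'   disease-state level to the next (default 6)
#' @return an object of class `cohort_config`
#' @export
cohort_config <- function(n_patients,
                          max_stay_h = 240,
                          target_sic_prevalence = 0.371,
                          target_dic_prevalence = 0.178,
                          sampling_rate_base = 3,
                          severity_sampling_coupling = 0.6,
                          noise_scale = 0.08,
                          seed = 1L,
                          variables = default_panel(),
                          min_stay_h = 72,
                          mean_extra_stay_h = 84,
                          transition_ramp_h = 6) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    stopf("n_patients must be a positive integer, got %s", format(n_patients))
  }
  if (target_dic_prevalence > target_sic_prevalence) {
    stopf("target_dic_prevalence (%.3f) must not exceed target_sic_prevalence (%.3f): DIC follows SIC",
          target_dic_prevalence, target_sic_prevalence)
  }
  if (target_sic_prevalence <= 0 || target_sic_prevalence >= 1 ||
      target_dic_prevalence <= 0 || target_dic_prevalence >= 1) {
    stopf("target prevalences must lie in (0, 1)")
  }
  if (sampling_rate_base <= 0) stopf("sampling_rate_base must be > 0")
  if (severity_sampling_coupling < 0) stopf("severity_sampling_coupling must be >= 0")
  if (max_stay_h < min_stay_h) stopf("max_stay_h must be >= min_stay_h")
  structure(list(
    n_patients = as.integer(n_patients), max_stay_h = max_stay_h,
    target_sic_prevalence = target_sic_prevalence,
    target_dic_prevalence = target_dic_prevalence,
    sampling_rate_base = sampling_rate_base,
    severity_sampling_coupling = severity_sampling_coupling,
    noise_scale = noise_scale, seed = as.integer(seed),
    variables = variables, min_stay_h = min_stay_h,
    mean_extra_stay_h = mean_extra_stay_h,
    transition_ramp_h = transition_ramp_h
  ), class = "cohort_config")
}

# State-conditional mean levels (sepsis / SIC / DIC) for the default panel.
# Chosen so the published SIC and ISTH overt-DIC bins recover the latent state.
state_means <- function() {
  rbind(
    PLT     = c(220, 110, 60),
    PCT     = c(0.25, 0.15, 0.08),
    INR     = c(1.00, 1.45, 1.80),
    PT      = c(12.5, 16.0, 19.0),
    APTT    = c(32, 42, 55),
    DDIMER  = c(0.8, 2.5, 7.0),
    FDP     = c(4, 12, 30),
    FIB     = c(3.5, 2.3, 0.9),
    SOFA    = c(2, 5, 9),
    LACTATE = c(1.5, 2.8, 4.5)
  )
}

# Continuous mean of one variable at times t given onset hours (NA = never).
state_mean_at <- function(variable, t, sic_onset, dic_onset, ramp_h) {
  m <- state_means()
  if (!variable %in% rownames(m)) stopf("no trajectory model for variable '%s'", variable)
  lv <- m[variable, ]
  f1 <- if (is.na(sic_onset)) 0 else clamp((t - sic_onset) / ramp_h, 0, 1)
  f2 <- if (is.na(dic_onset)) 0 else clamp((t - dic_onset) / ramp_h, 0, 1)
  lv[1] + f1 * (lv[2] - lv[1]) + f2 * (lv[3] - lv[2])
}

# Integer latent severity (0/1/2) at times t.
severity_at <- function(t, sic_onset, dic_onset) {
  s <- numeric(length(t))
  if (!is.na(sic_onset)) s <- s + (t >= sic_onset)
  if (!is.na(dic_onset)) s <- s + (t >= dic_onset)
  s
}

generate_patient <- function(i, config) {
  set.seed(mix_seed(config$seed, i))
  pid <- sprintf("P%05d", i)
  stay <- min(config$max_stay_h,
              config$min_stay_h + stats::rexp(1, 1 / config$mean_extra_stay_h))

  is_sic <- stats::runif(1) < config$target_sic_prevalence
  is_dic <- is_sic &&
    stats::runif(1) < config$target_dic_prevalence / config$target_sic_prevalence
  sic_onset <- NA_real_
  dic_onset <- NA_real_
  if (is_sic) {
    hi <- max(30, min(0.75 * stay, stay - 16))
    sic_onset <- stats::runif(1, 28, hi)
    if (is_dic) {
      dic_onset <- sic_onset + stats::runif(1, 16, 72)
      if (dic_onset > stay - 12) dic_onset <- max(sic_onset + 8, stay - 12)
    }
  }

  vars <- config$variables
  ramp <- config$transition_ramp_h
  c_coupling <- config$severity_sampling_coupling
  lam_base <- config$sampling_rate_base / 24
  lam_max <- lam_base * (1 + 2 * c_coupling)

  rows <- vector("list", length(vars))
  for (k in seq_along(vars)) {
    v <- vars[k]
    if (v == "SOFA") {
      # daily score stream, emitted as an already-computed score
      tt <- seq(0, stay, by = 24)
    } else {
      # thinned Poisson: intensity lam_base * (1 + coupling * severity(t))
      n_cand <- stats::rpois(1, lam_max * stay)
      cand <- sort(stats::runif(n_cand, 0, stay))
      keep_p <- lam_base * (1 + c_coupling * severity_at(cand, sic_onset, dic_onset)) / lam_max
      tt <- cand[stats::runif(length(cand)) < keep_p]
      tt <- c(0, tt)  # admission panel draw
    }
    tt <- sort(unique(round(tt, 2)))
    mu <- state_mean_at(v, tt, sic_onset, dic_onset, ramp)
    if (v == "SOFA") {
      val <- pmax(0, round(mu + stats::rnorm(length(tt), 0, 0.5)))
    } else {
      val <- mu * exp(stats::rnorm(length(tt), 0, config$noise_scale))
      val <- round(val, 4)
    }
    rows[[k]] <- data.frame(patient_id = pid, time_h = tt, variable = v,
                            value = val, stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$time_h, ev$variable), , drop = FALSE]
  rownames(ev) <- NULL
  list(events = ev,
       truth = data.frame(patient_id = pid, stay_h = round(stay, 2),
                          sic_onset_h = round(sic_onset, 2),
                          dic_onset_h = round(dic_onset, 2),
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic sepsis cohort with latent SIC/DIC progression
#'
#' Draws per-patient latent disease trajectories (sepsis, possibly SIC onset,
#' possibly subsequent DIC onset — never DIC without SIC), then emits
#' irregular lab event streams whose values follow state-conditional
#' piecewise-linear means with multiplicative lognormal noise, and whose
#' per-variable sampling times follow a thinned Poisson process with
#' intensity `sampling_rate_base * (1 + severity_sampling_coupling * severity)`.
#' Every patient gets a full admission panel at `t = 0` (SOFA is emitted
#' daily), so labs are always available in the first 24 h.
#'
#' @param config a [cohort_config()]
#' @return an object of class `sic_cohort`: list with `events` (long
#'   data.frame: patient_id, time_h, variable, value, unit), `truth`
#'   (patient_id, stay_h, sic_onset_h, dic_onset_h; NA when absent) and the
#'   echoed `config`
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 5, seed = 42))
#' head(coh$events)
#' coh$truth
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  pats <- lapply(seq_len(config$n_patients), generate_patient, config = config)
  events <- do.call(rbind, lapply(pats, `[[`, "events"))
  truth <- do.call(rbind, lapply(pats, `[[`, "truth"))
  units <- panel_units(config$variables)
  events$unit <- unname(units[events$variable])
  rownames(events) <- NULL
  structure(list(events = events, truth = truth, config = config),
            class = "sic_cohort")
}

#' @export
print.sic_cohort <- function(x, ...) {
  n_sic <- sum(!is.na(x$truth$sic_onset_h))
  n_dic <- sum(!is.na(x$truth$dic_onset_h))
  cat(sprintf("<sic_cohort> %d patients, %d lab events\n  SIC %d (%.1f%%), DIC %d (%.1f%%)\n",
              nrow(x$truth), nrow(x$events),
              n_sic, 100 * n_sic / nrow(x$truth),
              n_dic, 100 * n_dic / nrow(x$truth)))
  invisible(x)
}

#' Realized SIC/DIC prevalences of a generated cohort
#' @param cohort a `sic_cohort`
#' @return named numeric vector `c(sic = ..., dic = ...)`
#' @export
realized_prevalence <- function(cohort) {
  c(sic = mean(!is.na(cohort$truth$sic_onset_h)),
    dic = mean(!is.na(cohort$truth$dic_onset_h)))
}

#' Write / read a cohort event stream as CSV
#'
#' Long format, one lab observation per row: `patient_id, time_h, variable,
#' value, unit`; header mandatory; times in hours since admission. Values are
#' written with up to 15 significant digits so a write/read cycle reproduces
#' the stream exactly at generator precision.
#'
#' @param cohort a `sic_cohort` or a long events data.frame
#' @param path file path
#' @return `path` invisibly for the writer; for the reader, a long events
#'   data.frame sorted by patient, time, variable
#' @export
write_cohort <- function(cohort, path) {
  ev <- if (inherits(cohort, "sic_cohort")) cohort$events else cohort
  stopifnot(is.data.frame(ev))
  cols <- c("patient_id", "time_h", "variable", "value", "unit")
  if (!all(cols %in% names(ev))) stopf("events must have columns %s", paste(cols, collapse = ", "))
  write_canonical_csv(ev[, cols, drop = FALSE], path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stopf("no such cohort file: %s", path)
  ev <- data.table::fread(path, colClasses = list(
    character = c("patient_id", "variable", "unit"),
    numeric = c("time_h", "value")))
  ev <- as.data.frame(ev)
  cols <- c("patient_id", "time_h", "variable", "value", "unit")
  if (!all(cols %in% names(ev))) {
    stopf("malformed cohort file %s: expected header %s", path, paste(cols, collapse = ","))
  }
  check_field <- function(bad, field) {
    if (any(bad)) {
      row <- which(bad)[1]
      stopf("malformed cohort row %d (data line %d): bad %s '%s'",
            row, row + 1L, field, as.character(ev[[field]][row]))
    }
  }
  check_field(!is.finite(ev$time_h) | ev$time_h < 0, "time_h")
  check_field(!is.finite(ev$value), "value")
  check_field(is.na(ev$variable) | ev$variable == "", "variable")
  dup <- duplicated(ev[, c("patient_id", "time_h", "variable")])
  check_field(dup, "variable")
  ev <- ev[order(ev$patient_id, ev$time_h, ev$variable), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Write / read the ground-truth onset sidecar
#'
#' CSV with `patient_id, stay_h, sic_onset_h, dic_onset_h` (empty when the
#' event never occurs). Consumed by recovery tests, never by models.
#' @param truth data.frame as in `sic_cohort$truth`
#' @param path file path
#' @return `path` invisibly; reader returns the data.frame
#' @export
write_truth <- function(truth, path) write_canonical_csv(truth, path)

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- as.data.frame(data.table::fread(path, colClasses = list(character = "patient_id")))
  for (col in c("stay_h", "sic_onset_h", "dic_onset_h")) tr[[col]] <- as.numeric(tr[[col]])
  tr
}
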