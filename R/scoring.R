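#' Scoring cutoffs for SIC and ISTH overt-DIC
#'
#' Threshold configuration for the two scoring systems. Defaults follow the
#' published SIC (2017) and ISTH overt-DIC (2001) tables; hospital-specific
#' variants can be configured and every output echoes the cutoffs used.
#'
#' SIC sub-scores (each 0/1/2): platelets `< 150 -> 1`, `< 100 -> 2`;
#' INR `> 1.2 -> 1`, `> 1.4 -> 2`; SOFA `>= 1 -> 1`, `>= 2 -> 2`;
#' positive when the total (0-6) reaches `sic_positive_total` (default 4).
#'
#' ISTH overt-DIC sub-scores: platelets `< 100 -> 1`, `< 50 -> 2`; fibrin
#' marker (D-dimer, mg/L FEU) `>= 1 -> 2`, `>= 5 -> 3` (moderate/strong
#' increase); PT prolongation over `dic_pt_reference_s` `>= 3 s -> 1`,
#' `>= 6 s -> 2`; fibrinogen `< 1 g/L -> 1`; positive when the total (0-8)
#' reaches `dic_positive_total` (default 5).
#'
#' @param sic_plt_cuts,sic_inr_cuts,sic_sofa_cuts two-threshold vectors
#'   `(mild, severe)` for the SIC bins
#' @param sic_positive_total SIC positivity threshold on the total
#' @param sic_require_coag_subscores if `TRUE`, SIC positivity additionally
#'   requires platelet + INR sub-scores `> 2` (published auxiliary variant)
#' @param dic_plt_cuts platelet thresholds `(mild, severe)` for DIC
#' @param dic_fibrin_marker preferred fibrin-related marker variable
#' @param dic_fibrin_fallback fallback marker when the preferred is missing
#' @param dic_fibrin_cuts moderate/strong increase thresholds for the marker
#' @param dic_fibrin_fallback_cuts thresholds for the fallback marker (mg/L)
#' @param dic_pt_prolong_cuts PT prolongation thresholds in seconds
#' @param dic_pt_reference_s laboratory PT reference in seconds
#' @param dic_fib_cut fibrinogen threshold in g/L
#' @param dic_positive_total DIC positivity threshold on the total
#' @param sequential_dic if `TRUE` (default), a DIC-positive call additionally
#'   requires SIC positivity at or before the same assessment (two-step
#'   sequential diagnosis); `FALSE` relaxes to the raw ISTH rule
#' @return an object of class `scoring_cutoffs`
#' @export
scoring_cutoffs <- function(sic_plt_cuts = c(150, 100),
                            sic_inr_cuts = c(1.2, 1.4),
                            sic_sofa_cuts = c(1, 2),
                            sic_positive_total = 4L,
                            sic_require_coag_subscores = FALSE,
                            dic_plt_cuts = c(100, 50),
                            dic_fibrin_marker = "DDIMER",
                            dic_fibrin_fallback = "FDP",
                            dic_fibrin_cuts = c(1.0, 5.0),
                            dic_fibrin_fallback_cuts = c(10, 25),
                            dic_pt_prolong_cuts = c(3, 6),
                            dic_pt_reference_s = 12.0,
                            dic_fib_cut = 1.0,
                            dic_positive_total = 5L,
                            sequential_dic = TRUE) {
  chk_pair <- function(x, nm, decreasing = FALSE) {
    ok <- length(x) == 2 && (if (decreasing) x[1] > x[2] else x[1] < x[2])
    if (!ok) stopf("%s must be two strictly ordered thresholds", nm)
  }
  chk_pair(sic_plt_cuts, "sic_plt_cuts", decreasing = TRUE)
  chk_pair(sic_inr_cuts, "sic_inr_cuts")
  chk_pair(sic_sofa_cuts, "sic_sofa_cuts")
  chk_pair(dic_plt_cuts, "dic_plt_cuts", decreasing = TRUE)
  chk_pair(dic_fibrin_cuts, "dic_fibrin_cuts")
  chk_pair(dic_pt_prolong_cuts, "dic_pt_prolong_cuts")
  if (sic_positive_total < 0 || sic_positive_total > 6) stopf("sic_positive_total must be in [0, 6]")
  if (dic_positive_total < 0 || dic_positive_total > 8) stopf("dic_positive_total must be in [0, 8]")
  structure(list(
    sic_plt_cuts = sic_plt_cuts, sic_inr_cuts = sic_inr_cuts,
    sic_sofa_cuts = sic_sofa_cuts, sic_positive_total = as.integer(sic_positive_total),
    sic_require_coag_subscores = isTRUE(sic_require_coag_subscores),
    dic_plt_cuts = dic_plt_cuts, dic_fibrin_marker = dic_fibrin_marker,
    dic_fibrin_fallback = dic_fibrin_fallback, dic_fibrin_cuts = dic_fibrin_cuts,
    dic_fibrin_fallback_cuts = dic_fibrin_fallback_cuts,
    dic_pt_prolong_cuts = dic_pt_prolong_cuts,
    dic_pt_reference_s = dic_pt_reference_s, dic_fib_cut = dic_fib_cut,
    dic_positive_total = as.integer(dic_positive_total),
    sequential_dic = isTRUE(sequential_dic)
  ), class = "scoring_cutoffs")
}

#' SIC score from platelets, INR and SOFA
#'
#' @param plt platelet count, x10^9/L
#' @param inr international normalized ratio
#' @param sofa total SOFA score (integer)
#' @param cutoffs a [scoring_cutoffs()]
#' @return list with integer `subscores` `(plt, inr, sofa)`, `total` (0-6) and
#'   logical `positive`
#' @export
#' @examples
#' sic_score(90, 1.5, 3)   # total 6, positive
#' sic_score(120, 1.3, 1)  # total 3, negative
sic_score <- function(plt, inr, sofa, cutoffs = scoring_cutoffs()) {
  if (any(is.na(c(plt, inr, sofa)))) stopf("sic_score inputs must be non-missing")
  if (plt <= 0 || inr <= 0 || sofa < 0) stopf("sic_score inputs out of range")
  s_plt <- (plt < cutoffs$sic_plt_cuts[1]) + (plt < cutoffs$sic_plt_cuts[2])
  s_inr <- (inr > cutoffs$sic_inr_cuts[1]) + (inr > cutoffs$sic_inr_cuts[2])
  s_sofa <- (sofa >= cutoffs$sic_sofa_cuts[1]) + (sofa >= cutoffs$sic_sofa_cuts[2])
  total <- s_plt + s_inr + s_sofa
  positive <- total >= cutoffs$sic_positive_total
  if (cutoffs$sic_require_coag_subscores) positive <- positive && (s_plt + s_inr > 2)
  list(subscores = c(plt = s_plt, inr = s_inr, sofa = s_sofa),
       total = as.integer(total), positive = positive)
}

#' ISTH overt-DIC score
#'
#' @param plt platelet count, x10^9/L
#' @param fibrin_marker fibrin-related marker value (default scale: D-dimer
#'   mg/L FEU; pass `fallback = TRUE` to use the FDP thresholds)
#' @param pt_seconds prothrombin time in seconds; prolongation is
#'   `pt_seconds - dic_pt_reference_s`
#' @param fibrinogen_gL fibrinogen, g/L
#' @param cutoffs a [scoring_cutoffs()]
#' @param fallback use the fallback-marker (FDP) thresholds
#' @return list with integer `subscores` `(plt, fibrin_marker, pt, fib)`,
#'   `total` (0-8) and logical `positive_raw` (total rule only; the
#'   sequential SIC condition is applied by [assess_stream()])
#' @export
#' @examples
#' isth_dic_score(40, 6.0, 19.0, 0.8)   # total 8, positive
#' isth_dic_score(80, 2.0, 16.0, 1.5)   # total 4, negative at threshold 5
isth_dic_score <- function(plt, fibrin_marker, pt_seconds, fibrinogen_gL,
                           cutoffs = scoring_cutoffs(), fallback = FALSE) {
  if (any(is.na(c(plt, fibrin_marker, pt_seconds, fibrinogen_gL)))) {
    stopf("isth_dic_score inputs must be non-missing")
  }
  if (plt <= 0 || fibrin_marker < 0 || pt_seconds <= 0 || fibrinogen_gL <= 0) {
    stopf("isth_dic_score inputs out of range")
  }
  s_plt <- (plt < cutoffs$dic_plt_cuts[1]) + (plt < cutoffs$dic_plt_cuts[2])
  fc <- if (fallback) cutoffs$dic_fibrin_fallback_cuts else cutoffs$dic_fibrin_cuts
  s_fm <- if (fibrin_marker >= fc[2]) 3L else if (fibrin_marker >= fc[1]) 2L else 0L
  prolong <- pt_seconds - cutoffs$dic_pt_reference_s
  s_pt <- (prolong >= cutoffs$dic_pt_prolong_cuts[1]) +
    (prolong >= cutoffs$dic_pt_prolong_cuts[2])
  s_fib <- as.integer(fibrinogen_gL < cutoffs$dic_fib_cut)
  total <- s_plt + s_fm + s_pt + s_fib
  list(subscores = c(plt = s_plt, fibrin_marker = s_fm, pt = s_pt, fib = s_fib),
       total = as.integer(total),
       positive_raw = total >= cutoffs$dic_positive_total)
}

# variables consulted by either scoring system
scoring_variables <- function(cutoffs) {
  unique(c("PLT", "INR", "SOFA", cutoffs$dic_fibrin_marker,
           cutoffs$dic_fibrin_fallback, "PT", "FIB"))
}

#' Assess a patient's event stream at every scoring-relevant timestamp
#'
#' Produces one coagulation assessment per timestamp at which any scoring
#' variable updates. Each input variable takes its most recent observation
#' within `staleness_h` hours (last observation carried forward with a
#' staleness horizon); if a required input is stale or absent, that score is
#' marked not computable — values are never imputed. The two-step sequential
#' diagnosis is applied: `dic_positive` requires the raw ISTH rule plus SIC
#' positivity at or before the same assessment (unless the cutoffs relax it).
#'
#' @param events long events data.frame for one patient (patient_id, time_h,
#'   variable, value)
#' @param cutoffs a [scoring_cutoffs()]
#' @param staleness_h hours a lab value stays usable (default 24)
#' @return data.frame of class `coag_assessments`: one row per assessment with
#'   sub-scores, totals, positivity, computability flags, and the source time
#'   of each input used
#' @export
assess_stream <- function(events, cutoffs = scoring_cutoffs(), staleness_h = 24) {
  stopifnot(is.data.frame(events))
  if (length(unique(events$patient_id)) > 1) stopf("assess_stream expects a single patient")
  sv <- scoring_variables(cutoffs)
  ev <- events[events$variable %in% sv, , drop = FALSE]
  ev <- ev[order(ev$time_h), , drop = FALSE]
  times <- sort(unique(ev$time_h))
  n <- length(times)

  # last observation of each variable at or before each assessment time,
  # dropped when older than the staleness horizon
  locf <- function(v) {
    e <- ev[ev$variable == v, , drop = FALSE]
    if (nrow(e) == 0) return(rep(NA_real_, n))
    i <- findInterval(times, e$time_h)
    val <- ifelse(i > 0 & (times - e$time_h[pmax(i, 1)]) < staleness_h,
                  e$value[pmax(i, 1)], NA_real_)
    val
  }
  plt <- locf("PLT"); inr <- locf("INR"); sofa <- locf("SOFA")
  pt <- locf("PT"); fib <- locf("FIB")
  fm_main <- locf(cutoffs$dic_fibrin_marker)
  fm_fall <- locf(cutoffs$dic_fibrin_fallback)
  fm_fb <- is.na(fm_main) & !is.na(fm_fall)
  fm <- ifelse(fm_fb, fm_fall, fm_main)

  sic_ok <- !is.na(plt) & !is.na(inr) & !is.na(sofa)
  dic_ok <- !is.na(plt) & !is.na(fm) & !is.na(pt) & !is.na(fib)

  res <- data.frame(
    time_h = times,
    sic_computable = sic_ok, sic_plt = NA_integer_, sic_inr = NA_integer_,
    sic_sofa = NA_integer_, sic_total = NA_integer_, sic_positive = NA,
    dic_computable = dic_ok, dic_plt = NA_integer_, dic_fibrin = NA_integer_,
    dic_pt = NA_integer_, dic_fib = NA_integer_, dic_total = NA_integer_,
    dic_positive_raw = NA, dic_positive = NA, fibrin_fallback_used = fm_fb
  )
  for (k in which(sic_ok)) {
    s <- sic_score(plt[k], inr[k], sofa[k], cutoffs)
    res$sic_plt[k] <- s$subscores[["plt"]]; res$sic_inr[k] <- s$subscores[["inr"]]
    res$sic_sofa[k] <- s$subscores[["sofa"]]; res$sic_total[k] <- s$total
    res$sic_positive[k] <- s$positive
  }
  sic_ever <- cumsum(isTRUE_vec(res$sic_positive)) > 0
  for (k in which(dic_ok)) {
    d <- isth_dic_score(plt[k], fm[k], pt[k], fib[k], cutoffs, fallback = fm_fb[k])
    res$dic_plt[k] <- d$subscores[["plt"]]; res$dic_fibrin[k] <- d$subscores[["fibrin_marker"]]
    res$dic_pt[k] <- d$subscores[["pt"]]; res$dic_fib[k] <- d$subscores[["fib"]]
    res$dic_total[k] <- d$total; res$dic_positive_raw[k] <- d$positive_raw
    res$dic_positive[k] <- if (cutoffs$sequential_dic) d$positive_raw && sic_ever[k] else d$positive_raw
  }
  attr(res, "cutoffs") <- cutoffs
  attr(res, "patient_id") <- events$patient_id[1]
  class(res) <- c("coag_assessments", "data.frame")
  res
}

#' Build a windowed SIC/DIC label timeline from assessments
#'
#' Splits the stay into consecutive half-open windows of `window_len_h` hours.
#' Each window's observed label (per disease) is the label of the latest
#' computable assessment inside it. Windows without a computable assessment
#' are filled by forward interpolation: if the flanking observed labels agree
#' the window takes that label; if they disagree the earlier (forward) label
#' wins. Leading windows before any observation stay absent; trailing windows
#' after the last observation are forward-filled. Provenance is recorded per
#' disease.
#'
#' @param assessments output of [assess_stream()] (time-sorted)
#' @param window_len_h window length in hours (default 8)
#' @param total_h total stay length covered by the timeline
#' @return data.frame of class `label_timeline`: `patient_id, window_index,
#'   window_start_h, sic_label, dic_label, sic_provenance, dic_provenance,
#'   provenance` with labels in `{0, 1, NA}` and provenance in
#'   `{"observed", "interpolated", "absent"}`
#' @export
build_label_timeline <- function(assessments, window_len_h = 8, total_h) {
  if (total_h < window_len_h) stopf("total_h (%.1f) < window_len_h (%.1f)", total_h, window_len_h)
  if (nrow(assessments) && is.unsorted(assessments$time_h)) stopf("assessments must be time-sorted")
  n_win <- floor(total_h / window_len_h)
  win_of <- function(t) pmin(floor(t / window_len_h), n_win - 1)

  label_series <- function(lab_col, ok_col) {
    lab <- rep(NA, n_win)
    prov <- rep("absent", n_win)
    a <- assessments[isTRUE_vec(assessments[[ok_col]]), , drop = FALSE]
    if (nrow(a)) {
      for (i in seq_len(nrow(a))) {   # later assessments overwrite earlier in-window
        w <- win_of(a$time_h[i]) + 1
        lab[w] <- as.integer(a[[lab_col]][i])
        prov[w] <- "observed"
      }
      obs <- which(prov == "observed")
      first <- obs[1]; last <- obs[length(obs)]
      for (w in seq_len(n_win)) {
        if (prov[w] == "observed" || w < first) next
        if (w > last) { lab[w] <- lab[last]; prov[w] <- "interpolated"; next }
        # agreeing flanks take the shared label; disagreeing flanks take the
        # earlier one (forward rule) -- both resolve to the previous observed
        prev <- max(obs[obs < w])
        lab[w] <- lab[prev]
        prov[w] <- "interpolated"
      }
    }
    list(label = lab, provenance = prov)
  }
  sic <- label_series("sic_positive", "sic_computable")
  dic <- label_series("dic_positive", "dic_computable")
  tl <- data.frame(
    patient_id = attr(assessments, "patient_id") %||% NA_character_,
    window_index = seq_len(n_win) - 1L,
    window_start_h = (seq_len(n_win) - 1L) * window_len_h,
    sic_label = sic$label, dic_label = dic$label,
    sic_provenance = sic$provenance, dic_provenance = dic$provenance,
    stringsAsFactors = FALSE
  )
  tl$provenance <- ifelse(tl$sic_provenance == "absent" | tl$dic_provenance == "absent",
                          "absent",
                          ifelse(tl$sic_provenance == "interpolated" |
                                   tl$dic_provenance == "interpolated",
                                 "interpolated", "observed"))
  attr(tl, "window_len_h") <- window_len_h
  attr(tl, "cutoffs") <- attr(assessments, "cutoffs")
  class(tl) <- c("label_timeline", "data.frame")
  tl
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Label every patient of a cohort
#'
#' Runs [assess_stream()] and [build_label_timeline()] per patient.
#'
#' @param cohort a `sic_cohort` or long events data.frame
#' @param cutoffs a [scoring_cutoffs()]
#' @param window_len_h label window length (default 8)
#' @param staleness_h lab staleness horizon (default 24)
#' @param stays optional named vector of stay hours per patient; defaults to
#'   the cohort truth (if present) or each patient's last event time
#' @return named list of `label_timeline`s, one per patient
#' @export
label_cohort <- function(cohort, cutoffs = scoring_cutoffs(), window_len_h = 8,
                         staleness_h = 24, stays = NULL) {
  ev <- if (inherits(cohort, "sic_cohort")) cohort$events else cohort
  if (is.null(stays) && inherits(cohort, "sic_cohort")) {
    stays <- stats::setNames(cohort$truth$stay_h, cohort$truth$patient_id)
  }
  by_pat <- split(ev, ev$patient_id)
  out <- lapply(names(by_pat), function(pid) {
    pe <- by_pat[[pid]]
    total <- if (!is.null(stays) && pid %in% names(stays)) stays[[pid]] else max(pe$time_h) + window_len_h
    a <- assess_stream(pe, cutoffs, staleness_h)
    build_label_timeline(a, window_len_h, total_h = total)
  })
  names(out) <- names(by_pat)
  out
}

#' Write label timelines to CSV (cutoffs echoed to a JSON sidecar)
#'
#' @param timelines list of `label_timeline`s from [label_cohort()]
#' @param path CSV path; the cutoffs echo goes to `paste0(path, ".cutoffs.json")`
#' @return `path` invisibly
#' @export
write_timelines <- function(timelines, path) {
  df <- do.call(rbind, timelines)
  rownames(df) <- NULL
  write_canonical_csv(df, path)
  cut <- attr(timelines[[1]], "cutoffs")
  if (!is.null(cut)) {
    jsonlite::write_json(unclass(cut), paste0(path, ".cutoffs.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
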