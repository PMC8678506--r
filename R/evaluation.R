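#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive outranks a
#' random negative, with ties counted half. Exactly equal to all-pairs
#' concordance counting.
#'
#' @param scores numeric risk scores
#' @param labels 0/1 labels
#' @return AUROC in `[0, 1]`; `NA` (with a `reason` attribute) when only one
#'   class is present
#' @export
#' @examples
#' auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))  # 1
#' auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))  # 0.75
auroc <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    return(structure(NA_real_, reason = "single-class input: AUROC undefined"))
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: sum over distinct score thresholds of
#' `(recall_i - recall_{i-1}) * precision_i`, scores descending, tied scores
#' grouped.
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`; `NA` with reason when no positives
#' @export
auprc <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) {
    return(structure(NA_real_, reason = "single-class input: AUPRC undefined"))
  }
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  tp <- cumsum(y)[grp_end]
  n_pred <- grp_end
  prec <- tp / n_pred
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' F1 score at a decision threshold
#'
#' Harmonic mean of precision and recall with predictions `score >= threshold`.
#' @inheritParams auroc
#' @param threshold decision threshold (default 0.5)
#' @return F1 in `[0, 1]` (0 when no true positives)
#' @export
f1_at_threshold <- function(scores, labels, threshold = 0.5) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1)
  if (tp == 0) return(0)
  precision <- tp / sum(pred)
  recall <- tp / sum(labels == 1)
  2 * precision * recall / (precision + recall)
}

#' Percentile bootstrap confidence interval for a ranking metric
#'
#' Resamples at the patient level by default (windows of one patient stay
#' together, respecting within-patient correlation); window-level resampling
#' is available for fidelity with evaluations that resample test samples
#' directly. Resamples containing a single class are skipped and counted; more
#' than 10% skips triggers a warning. Deterministic given `seed`.
#'
#' @param metric_fn function `(scores, labels) -> value`, e.g. [auroc()]
#' @param scores,labels as in [auroc()]
#' @param patient_ids patient id per observation (required for
#'   `unit = "patient"`)
#' @param resamples bootstrap draws (default 1000)
#' @param level confidence level (default 0.95)
#' @param seed integer seed
#' @param unit `"patient"` or `"window"`
#' @return list `(point, lo, hi, n_used, n_skipped)`
#' @export
bootstrap_ci <- function(metric_fn, scores, labels, patient_ids = NULL,
                         resamples = 1000, level = 0.95, seed = 1L,
                         unit = c("patient", "window")) {
  unit <- match.arg(unit)
  if (unit == "patient" && is.null(patient_ids)) {
    stopf("patient_ids required for patient-level bootstrap")
  }
  point <- metric_fn(scores, labels)
  set.seed(mix_seed(seed, 104729))
  vals <- numeric(resamples)
  skipped <- 0L
  if (unit == "patient") {
    pats <- unique(patient_ids)
    by_pat <- split(seq_along(scores), match(patient_ids, pats))
  }
  for (r in seq_len(resamples)) {
    idx <- if (unit == "patient") {
      unlist(by_pat[sample.int(length(by_pat), replace = TRUE)], use.names = FALSE)
    } else {
      sample.int(length(scores), replace = TRUE)
    }
    v <- metric_fn(scores[idx], labels[idx])
    if (is.na(v)) { skipped <- skipped + 1L; vals[r] <- NA_real_ } else vals[r] <- v
  }
  if (skipped > 0.1 * resamples) {
    warning(sprintf("%d/%d bootstrap resamples had a single class and were skipped",
                    skipped, resamples))
  }
  qs <- stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE,
                        names = FALSE)
  list(point = as.numeric(point), lo = qs[1], hi = qs[2],
       n_used = resamples - skipped, n_skipped = skipped)
}

#' Alert-threshold sweep with event-level precision and recall
#'
#' For predictions at lead time `horizon_h`: an alert is a window whose
#' predicted risk reaches the threshold. Precision is the fraction of alerts
#' whose target window is truly positive (correct alerts `horizon_h` before
#' the labeled state). Recall is event-level: the fraction of patients' first
#' positive target windows that received an alert from the window `horizon_h`
#' before them. Window-level sensitivity/specificity are reported alongside.
#'
#' @param predictions a `prediction_set` (must carry `target`)
#' @param horizon_h lead time to sweep (default 8)
#' @param thresholds thresholds to sweep (default 0.1-0.9 by 0.05, including
#'   the commonly highlighted 0.7)
#' @param disease `"sic"`, `"dic"` or both
#' @return data.frame: disease, threshold, n_alerts, precision, recall,
#'   sensitivity, specificity
#' @export
alarm_metrics <- function(predictions, horizon_h = 8,
                          thresholds = seq(0.1, 0.9, by = 0.05),
                          disease = c("sic", "dic")) {
  out <- list()
  for (dz in intersect(disease, unique(predictions$disease))) {
    p <- predictions[predictions$disease == dz &
                       predictions$horizon_h == horizon_h &
                       !is.na(predictions$target), , drop = FALSE]
    if (nrow(p) == 0) next
    # event = each patient's first positive target window at this horizon
    pos <- p[p$target == 1, , drop = FALSE]
    first_pos <- pos[order(pos$patient_id, pos$window_start_h), , drop = FALSE]
    first_pos <- first_pos[!duplicated(first_pos$patient_id), , drop = FALSE]
    for (thr in thresholds) {
      alert <- p$risk >= thr
      tp <- sum(alert & p$target == 1)
      fp <- sum(alert & p$target == 0)
      tn <- sum(!alert & p$target == 0)
      fn <- sum(!alert & p$target == 1)
      out[[length(out) + 1]] <- data.frame(
        disease = dz, threshold = thr, n_alerts = tp + fp,
        precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
        recall = if (nrow(first_pos)) mean(first_pos$risk >= thr) else NA_real_,
        sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
        specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
      )
    }
  }
  do.call(rbind, out)
}

#' Horizon-wise evaluation report with bootstrap confidence intervals
#'
#' One row per (model, disease, horizon, metric) with the point estimate and a
#' percentile bootstrap 95% CI: the per-horizon model comparison table.
#'
#' @param predictions one `prediction_set` or a list of them (one per model)
#' @param metrics metric names among `"AUROC"`, `"AUPRC"`, `"F1"`
#' @param resamples bootstrap draws (default 1000)
#' @param level CI level
#' @param seed integer seed
#' @param unit bootstrap unit, see [bootstrap_ci()]
#' @param f1_threshold decision threshold for F1 (default 0.5)
#' @return data.frame of class `eval_report`
#' @export
horizon_report <- function(predictions, metrics = c("AUROC", "AUPRC", "F1"),
                           resamples = 1000, level = 0.95, seed = 1L,
                           unit = "patient", f1_threshold = 0.5) {
  if (inherits(predictions, "prediction_set")) predictions <- list(predictions)
  metric_fns <- list(
    AUROC = auroc,
    AUPRC = auprc,
    F1 = function(s, l) f1_at_threshold(s, l, f1_threshold)
  )
  rows <- list()
  for (ps in predictions) {
    for (dz in sort(unique(ps$disease))) {
      for (hz in sort(unique(ps$horizon_h))) {
        p <- ps[ps$disease == dz & ps$horizon_h == hz & !is.na(ps$target), , drop = FALSE]
        n_pos <- sum(p$target == 1)
        for (mt in metrics) {
          if (nrow(p) == 0 || n_pos == 0 || n_pos == nrow(p)) {
            rows[[length(rows) + 1]] <- data.frame(
              model = ps$model[1], disease = dz, horizon_h = hz, metric = mt,
              point = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              n_windows = nrow(p), n_positive = n_pos)
            next
          }
          ci <- bootstrap_ci(metric_fns[[mt]], p$risk, p$target, p$patient_id,
                             resamples = resamples, level = level, seed = seed)
          rows[[length(rows) + 1]] <- data.frame(
            model = ps$model[1], disease = dz, horizon_h = hz, metric = mt,
            point = ci$point, ci_low = ci$lo, ci_high = ci$hi,
            n_windows = nrow(p), n_positive = n_pos)
        }
      }
    }
  }
  rep <- do.call(rbind, rows)
  class(rep) <- c("eval_report", "data.frame")
  rep
}

#' Pivot an evaluation report into the model x (disease, horizon) layout
#'
#' @param report an `eval_report`
#' @param metric which metric to tabulate (default AUROC)
#' @return data.frame: one row per model, one column per disease/horizon cell;
#'   missing cells stay empty (`NA`), never zero
#' @export
report_table <- function(report, metric = "AUROC") {
  r <- report[report$metric == metric, , drop = FALSE]
  models <- unique(r$model)
  cells <- unique(r[, c("disease", "horizon_h")])
  cells <- cells[order(cells$disease, cells$horizon_h), , drop = FALSE]
  out <- data.frame(model = models, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cells))) {
    cn <- sprintf("%s_%dh", toupper(cells$disease[i]), cells$horizon_h[i])
    out[[cn]] <- vapply(models, function(m) {
      v <- r$point[r$model == m & r$disease == cells$disease[i] &
                     r$horizon_h == cells$horizon_h[i]]
      if (length(v)) v[1] else NA_real_
    }, numeric(1))
  }
  out
}
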