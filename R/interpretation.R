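#' Re-encode a cohort with one variable globally occluded
#'
#' Removes every observation of `variable` from the event stream and
#' re-encodes the windows against the same panel and normalization statistics:
#' the variable behaves as never observed (mask 0 everywhere, fill values,
#' time-since-observation intervals accumulating from the start of each
#' stream), exactly as the interval recurrence prescribes for a missing
#' variable. No model is retrained.
#'
#' @param events long events data.frame
#' @param timelines list of `label_timeline`s
#' @param config an [encoding_config()]
#' @param norm `norm_stats` fitted on the unoccluded training data
#' @param variable variable name to occlude
#' @param drop_unlabeled see [build_windows()]
#' @return list of occluded `window_tensor`s
#' @export
occlude_cohort <- function(events, timelines, config, norm, variable,
                           drop_unlabeled = TRUE) {
  if (!variable %in% config$variables) {
    stopf("variable '%s' is not in the configured panel", variable)
  }
  ev <- events[events$variable != variable, , drop = FALSE]
  encode_cohort(ev, timelines, config, norm, drop_unlabeled)
}

#' Occlusion analysis: metric change when one variable is never observed
#'
#' Computes the evaluation metric on the baseline windows and on windows
#' re-encoded with `variable` occluded ([occlude_cohort()]); the difference
#' `baseline - occluded` measures how much the trained model relies on that
#' variable being measured at all. Side-effect free: the model and the
#' baseline windows are untouched.
#'
#' @param model a trained `seq_model` or `tabular_model`
#' @param events long events data.frame of the evaluation patients
#' @param timelines their `label_timeline`s
#' @param config,norm encoding settings used at training time
#' @param variable variable to occlude
#' @param disease `"sic"` or `"dic"`
#' @param horizon_h evaluation horizon (default 8)
#' @param metric_fn metric `(scores, labels) -> value` (default [auroc()])
#' @param baseline_windows optionally precomputed baseline windows (avoids
#'   re-encoding per variable)
#' @return one-row data.frame: variable, baseline, occluded, delta
#' @export
occlude_and_score <- function(model, events, timelines, config, norm, variable,
                              disease = "dic", horizon_h = 8,
                              metric_fn = auroc, baseline_windows = NULL) {
  base_w <- baseline_windows %||% encode_cohort(events, timelines, config, norm)
  occ_w <- occlude_cohort(events, timelines, config, norm, variable)
  score_of <- function(wins) {
    ps <- predict_risk(model, wins)
    p <- ps[ps$disease == disease & ps$horizon_h == horizon_h & !is.na(ps$target), ]
    as.numeric(metric_fn(p$risk, p$target))
  }
  b <- score_of(base_w)
  o <- score_of(occ_w)
  data.frame(variable = variable, baseline = b, occluded = o, delta = b - o,
             disease = disease, horizon_h = horizon_h, model = model$model_id,
             stringsAsFactors = FALSE)
}

#' Occlusion analysis over a whole panel
#'
#' @inheritParams occlude_and_score
#' @param variables variables to occlude (default: the encoded panel)
#' @return data.frame with one row per variable, sorted by decreasing delta
#' @export
occlusion_analysis <- function(model, events, timelines, config, norm,
                               variables = NULL, disease = "dic",
                               horizon_h = 8, metric_fn = auroc) {
  base_w <- encode_cohort(events, timelines, config, norm)
  variables <- variables %||% base_w[[1]]$variables
  rows <- lapply(variables, function(v) {
    occlude_and_score(model, events, timelines, config, norm, v, disease,
                      horizon_h, metric_fn, baseline_windows = base_w)
  })
  out <- do.call(rbind, rows)
  out[order(-out$delta), , drop = FALSE]
}

#' Export SHAP attributions for a boosted-tree model
#'
#' Delegates to xgboost's exact tree-path additive attributions
#' (`predcontrib`). Returns global importance (mean absolute attribution) at
#' both feature and variable level (derived discretization features summed per
#' source variable), the raw per-sample attribution rows (base value in
#' `BIAS`; rows + BIAS sum to the margin output), and a dependence table for
#' the top variable pair.
#'
#' @param model a `tabular_model` whose fits are boosted trees
#' @param windows evaluation windows
#' @param disease,horizon_h which head to explain (default DIC at 8 h)
#' @return list: `global` (feature-level), `global_variable` (variable-level),
#'   `per_sample` (matrix incl. BIAS), `dependence` (top-pair table)
#' @export
export_attributions <- function(model, windows, disease = "dic", horizon_h = 8) {
  if (!inherits(model, "tabular_model")) {
    stopf("attribution export supports tree models; use occlusion analysis for sequence models")
  }
  head_nm <- sprintf("%s_h%d", disease, horizon_h)
  fit <- model$fits[[head_nm]]
  if (is.null(fit) || fit$kind != "xgb") {
    stopf("head %s is not a fitted boosted-tree model; use occlusion analysis instead", head_nm)
  }
  X <- window_features(windows, model$grid_h, model$delta_scale_h)
  X <- X[, model$features, drop = FALSE]
  contrib <- predict(fit$fit, xgboost::xgb.DMatrix(X), predcontrib = TRUE)
  colnames(contrib) <- c(model$features, "BIAS")
  gi <- colMeans(abs(contrib[, model$features, drop = FALSE]))
  global <- data.frame(feature = names(gi), importance = unname(gi))
  global <- global[order(-global$importance), , drop = FALSE]
  src <- feature_variable(model$features, windows[[1]]$variables)
  gv <- tapply(gi, src, sum)
  global_variable <- data.frame(variable = names(gv), importance = as.numeric(gv))
  global_variable <- global_variable[order(-global_variable$importance), , drop = FALSE]
  top2 <- utils::head(global$feature, 2)
  dependence <- data.frame(
    f1_value = X[, top2[1]], f1_shap = contrib[, top2[1]],
    f2_value = if (length(top2) > 1) X[, top2[2]] else NA_real_,
    f2_shap = if (length(top2) > 1) contrib[, top2[2]] else NA_real_
  )
  names(dependence) <- c(paste0(top2[1], c("_value", "_shap")),
                         paste0(top2[min(2, length(top2))], c("_value", "_shap")))
  list(global = global, global_variable = global_variable,
       per_sample = contrib, dependence = dependence)
}

# map derived feature names (PLT_v1, PLT_n2, PLT_delta, ...) to their variable
feature_variable <- function(features, variables) {
  out <- rep(NA_character_, length(features))
  for (v in variables[order(-nchar(variables))]) {
    hit <- is.na(out) & startsWith(features, paste0(v, "_"))
    out[hit] <- v
  }
  out[is.na(out)] <- "other"
  out
}

#' Select a reduced ("Lite") feature set from two importance analyses
#'
#' Combines SHAP-style global variable importance and occlusion deltas by mean
#' rank, applies manual clinical overrides, and returns at most `k` variables.
#'
#' @param shap_importance data.frame `variable, importance` (higher = more
#'   important), e.g. `export_attributions(...)$global_variable`
#' @param occlusion data.frame `variable, delta` from [occlusion_analysis()]
#' @param k maximum number of variables (default 10)
#' @param include variables to force in (must belong to the panel)
#' @param exclude variables to drop regardless of rank
#' @return object of class `lite_feature_set`: list with `variables` (ordered)
#'   and `provenance` (the rank table)
#' @export
build_lite_set <- function(shap_importance, occlusion, k = 10,
                           include = NULL, exclude = NULL) {
  panel <- union(shap_importance$variable, occlusion$variable)
  bad <- setdiff(include, panel)
  if (length(bad)) stopf("manual include not in panel: %s", paste(bad, collapse = ", "))
  r1 <- rank(-shap_importance$importance)[match(panel, shap_importance$variable)]
  r2 <- rank(-occlusion$delta)[match(panel, occlusion$variable)]
  combined <- rowMeans(cbind(r1, r2), na.rm = TRUE)
  tab <- data.frame(variable = panel, shap_rank = r1, occlusion_rank = r2,
                    combined_rank = combined, manual = panel %in% include,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$combined_rank), , drop = FALSE]
  sel <- setdiff(tab$variable, exclude)
  sel <- unique(c(intersect(include, sel), sel))
  sel <- utils::head(sel, k)
  structure(list(variables = sel, provenance = tab), class = "lite_feature_set")
}

#' Write a Lite feature set as JSON
#' @param lite a `lite_feature_set`
#' @param path output path
#' @return `path` invisibly
#' @export
write_lite_set <- function(lite, path) {
  jsonlite::write_json(list(variables = lite$variables,
                            provenance = lite$provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
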