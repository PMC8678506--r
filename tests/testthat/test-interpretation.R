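# a crafted cohort where variable SIG alone drives the labels lets occlusion
# deltas be predicted by construction
fit_one_signal <- function(n_patients = 80, seed = 11) {
  oc <- one_signal_cohort(n_patients, seed)
  wins <- encode_cohort(oc$events, oc$timelines, oc$config, oc$norm)
  ids <- unique(oc$events$patient_id)
  tr_ids <- ids[1:round(0.7 * length(ids))]
  te_ids <- setdiff(ids, tr_ids)
  w_tr <- Filter(function(w) w$patient_id %in% tr_ids, wins)
  model <- suppressWarnings(train_tabular_baselines(w_tr, "xgb", seed = 1, nrounds = 60))
  list(oc = oc, model = model, te_ids = te_ids,
       ev_te = oc$events[oc$events$patient_id %in% te_ids, ],
       tls_te = oc$timelines[te_ids])
}

one_sig <- fit_one_signal()

test_that("occlusion deltas reflect constructed signal: noise variables are inert, the driver collapses AUROC", {
  fx <- one_sig
  occ <- occlusion_analysis(fx$model, fx$ev_te, fx$tls_te, fx$oc$config,
                            fx$oc$norm, disease = "dic", horizon_h = 8)
  base <- occ$baseline[1]
  expect_gt(base, 0.9)
  # pure-noise variable: negligible impact
  expect_lt(abs(occ$delta[occ$variable == "N1"]), 0.02)
  expect_lt(abs(occ$delta[occ$variable == "N2"]), 0.02)
  # sole driving variable: performance collapses to chance
  expect_gte(occ$occluded[occ$variable == "SIG"], 0.4)
  expect_lte(occ$occluded[occ$variable == "SIG"], 0.6)
  expect_equal(occ$variable[1], "SIG")  # sorted by delta
})

test_that("occlusion is side-effect free and un-occluding restores the baseline exactly", {
  fx <- one_sig
  params_before <- serialize(fx$model, NULL)
  base_w <- encode_cohort(fx$ev_te, fx$tls_te, fx$oc$config, fx$oc$norm)
  hash_before <- serialize(base_w, NULL)
  r1 <- occlude_and_score(fx$model, fx$ev_te, fx$tls_te, fx$oc$config,
                          fx$oc$norm, "SIG", baseline_windows = base_w)
  r2 <- occlude_and_score(fx$model, fx$ev_te, fx$tls_te, fx$oc$config,
                          fx$oc$norm, "N1", baseline_windows = base_w)
  expect_identical(serialize(fx$model, NULL), params_before)
  expect_identical(serialize(base_w, NULL), hash_before)
  # re-scoring the untouched windows reproduces the baseline metric exactly
  r3 <- occlude_and_score(fx$model, fx$ev_te, fx$tls_te, fx$oc$config,
                          fx$oc$norm, "SIG", baseline_windows = base_w)
  expect_identical(r1$baseline, r3$baseline)
  expect_identical(r1$occluded, r3$occluded)

  # occluded deltas obey the interval recurrence: variable behaves never-observed
  occ_w <- occlude_cohort(fx$ev_te, fx$tls_te, fx$oc$config, fx$oc$norm, "SIG")
  w <- occ_w[[5]]
  expect_true(all(w$m[, "SIG"] == 0))
  # never-observed: the interval accumulates through every step of the stay
  expect_equal(diff(w$delta[, "SIG"]), diff(w$s))
  pe <- fx$ev_te[fx$ev_te$patient_id == w$patient_id & fx$ev_te$variable != "SIG", ]
  expect_equal(unname(w$delta[1, "SIG"]), w$s[1] - min(pe$time_h))
  expect_error(occlude_cohort(fx$ev_te, fx$tls_te, fx$oc$config, fx$oc$norm,
                              "NOT_A_VAR"), "panel")
})

test_that("tree attributions are additive, rank the driver first, and zero out unused features", {
  fx <- one_sig
  w_te <- encode_cohort(fx$ev_te, fx$tls_te, fx$oc$config, fx$oc$norm)
  att <- export_attributions(fx$model, w_te, disease = "dic", horizon_h = 8)
  expect_equal(att$global_variable$variable[1], "SIG")

  # additivity: per-sample contributions + base value = margin = logit(prob)
  ps <- predict_risk(fx$model, w_te)
  pr <- ps[ps$disease == "dic" & ps$horizon_h == 8, "risk"]
  margin <- rowSums(att$per_sample)
  expect_equal(plogis(margin), pr, tolerance = 1e-5)

  # features absent from every tree have exactly zero attribution
  fit <- fx$model$fits[["dic_h8"]]$fit
  used <- unique(xgboost::xgb.model.dt.tree(model = fit)$Feature)
  unused <- setdiff(fx$model$features, used)
  if (length(unused)) {
    expect_true(all(att$global$importance[att$global$feature %in% unused] == 0))
  }
  # sequence models are redirected to occlusion
  sm <- structure(list(model_id = "rnn"), class = "seq_model")
  expect_error(export_attributions(sm, w_te), "occlusion")
})

test_that("occlusion rankings are stable across evaluation-set bootstrap draws", {
  fx <- one_sig
  top3 <- lapply(1:3, function(s) {
    set.seed(s)
    ids <- sample(fx$te_ids, length(fx$te_ids), replace = TRUE)
    ids <- unique(ids)  # block resample of evaluation patients
    occ <- occlusion_analysis(fx$model,
                              fx$ev_te[fx$ev_te$patient_id %in% ids, ],
                              fx$tls_te[ids], fx$oc$config, fx$oc$norm,
                              disease = "dic", horizon_h = 8)
    occ$variable[1]
  })
  expect_true(all(unlist(top3) == "SIG"))
})

test_that("lite feature sets combine ranks, honor overrides, and keep near-full accuracy", {
  shap <- data.frame(variable = c("A", "B", "C", "D"), importance = c(4, 3, 2, 1))
  occ <- data.frame(variable = c("A", "B", "C", "D"), delta = c(0.4, 0.3, 0.2, 0.1))
  # full agreement -> shared top-k
  ls <- build_lite_set(shap, occ, k = 2)
  expect_equal(ls$variables, c("A", "B"))
  # k covering the whole panel -> identity set
  ls_all <- build_lite_set(shap, occ, k = 4)
  expect_setequal(ls_all$variables, c("A", "B", "C", "D"))
  # manual overrides
  ls_inc <- build_lite_set(shap, occ, k = 2, include = "D")
  expect_true("D" %in% ls_inc$variables)
  ls_exc <- build_lite_set(shap, occ, k = 2, exclude = "A")
  expect_false("A" %in% ls_exc$variables)
  expect_error(build_lite_set(shap, occ, include = "Z"), "panel")

  f <- tempfile(fileext = ".json")
  write_lite_set(ls, f)
  expect_equal(jsonlite::fromJSON(f)$variables, c("A", "B"))

  # reduced panel keeps near-full discrimination on a generated cohort
  coh <- generate_cohort(cohort_config(150, seed = 19))
  tls <- label_cohort(coh)
  sp <- split_patients(coh$truth$patient_id, seed = 2)
  cfg <- encoding_config(horizons_h = 8)
  norm <- fit_normalization(coh$events, sp$train, cfg)
  ev <- coh$events
  w_tr <- encode_cohort(ev[ev$patient_id %in% sp$train, ], tls[sp$train], cfg, norm)
  w_te <- encode_cohort(ev[ev$patient_id %in% sp$test, ], tls[sp$test], cfg, norm)
  full <- train_tabular_baselines(w_tr, "xgb", seed = 3, nrounds = 80)
  att <- export_attributions(full, w_te, disease = "dic", horizon_h = 8)
  lite_vars <- utils::head(att$global_variable$variable, 6)
  cfg_l <- encoding_config(variables = lite_vars, horizons_h = 8)
  norm_l <- norm[norm$variable %in% lite_vars, ]
  wl_tr <- encode_cohort(ev[ev$patient_id %in% sp$train, ], tls[sp$train], cfg_l, norm_l)
  wl_te <- encode_cohort(ev[ev$patient_id %in% sp$test, ], tls[sp$test], cfg_l, norm_l)
  lite <- train_tabular_baselines(wl_tr, "xgb", seed = 3, nrounds = 80)
  dic8 <- function(m, w) {
    p <- predict_risk(m, w)
    p <- p[p$disease == "dic" & p$horizon_h == 8 & !is.na(p$target), ]
    auroc(p$risk, p$target)
  }
  expect_lt(abs(dic8(full, w_te) - dic8(lite, wl_te)), 0.05)
})
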