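#' Patient-disjoint train/valid/test split
#'
#' Splits patient ids by the largest-remainder rounding rule (so `n = 10` with
#' the default fractions gives sizes 7/1/2). No window of one patient can land
#' in two splits because assignment is at the patient level. Deterministic
#' given `seed`.
#'
#' @param patients character vector of patient ids
#' @param fractions split fractions summing to 1 (default `c(0.7, 0.1, 0.2)`)
#' @param seed integer seed
#' @return list with character vectors `train`, `valid`, `test`
#' @export
split_patients <- function(patients, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stopf("fractions must sum to 1")
  n <- length(patients)
  base <- floor(n * fractions)
  rem <- n * fractions - base
  left <- n - sum(base)
  if (left > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[add] <- base[add] + 1
  }
  if (any(base == 0)) stopf("n = %d is too small for nonempty splits at fractions %s",
                            n, paste(fractions, collapse = "/"))
  set.seed(mix_seed(seed, 31L))
  ord <- sample(patients)
  list(train = sort(ord[seq_len(base[1])]),
       valid = sort(ord[base[1] + seq_len(base[2])]),
       test = sort(ord[base[1] + base[2] + seq_len(base[3])]))
}

#' Assemble (or load) a full pipeline run configuration
#'
#' A run configuration composes the cohort, scoring, encoding, model and
#' evaluation settings plus a global seed that propagates to every stochastic
#' stage. `load_run_config()` reads the same structure from a YAML or JSON
#' file. Validation is fail-fast: the sub-configuration constructors run (and
#' throw) before any compute starts.
#'
#' @param n_patients cohort size
#' @param seed global seed
#' @param models character vector of model ids among `lr, svm, xgb, xgb_dart,
#'   rnn, lstm, decay_rnn, ode_rnn`
#' @param cohort named list of [cohort_config()] overrides
#' @param cutoffs named list of [scoring_cutoffs()] overrides
#' @param encoding named list of [encoding_config()] overrides
#' @param seq_model named list of [seq_model_config()] overrides (applied to
#'   every sequence model in `models`)
#' @param tabular named list of [train_tabular_baselines()] overrides
#' @param evaluation list: `resamples` (default 200), `level`, `unit`
#' @param interpret list: `disease`, `horizon_h`, `lite_k`
#' @return object of class `run_config`
#' @export
run_config <- function(n_patients = 200, seed = 1L,
                       models = c("xgb", "ode_rnn"),
                       cohort = list(), cutoffs = list(), encoding = list(),
                       seq_model = list(), tabular = list(),
                       evaluation = list(), interpret = list()) {
  known <- c("lr", "svm", "xgb", "xgb_dart", "rnn", "lstm", "decay_rnn", "ode_rnn")
  bad <- setdiff(models, known)
  if (length(bad)) stopf("unknown model id(s): %s", paste(bad, collapse = ", "))
  cohort$n_patients <- cohort$n_patients %||% n_patients
  cohort$seed <- cohort$seed %||% seed
  cc <- do.call(cohort_config, cohort)          # validates
  sc <- do.call(scoring_cutoffs, cutoffs)       # validates
  ec <- do.call(encoding_config, c(list(variables = cc$variables), encoding))
  evaluation$resamples <- evaluation$resamples %||% 200
  evaluation$level <- evaluation$level %||% 0.95
  evaluation$unit <- evaluation$unit %||% "patient"
  interpret$disease <- interpret$disease %||% "dic"
  interpret$horizon_h <- interpret$horizon_h %||% 8
  interpret$lite_k <- interpret$lite_k %||% 10
  structure(list(seed = as.integer(seed), models = models,
                 cohort = cc, cutoffs = sc, encoding = ec,
                 seq_model = seq_model, tabular = tabular,
                 evaluation = evaluation, interpret = interpret),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML (`.yml`/`.yaml`) or JSON file with the fields of
#'   [run_config()]
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stopf("no such config file: %s", path)
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  do.call(run_config, raw)
}

pipeline_stages <- function() {
  c("generate", "label", "encode", "train", "evaluate", "interpret")
}

config_fingerprint <- function(config) {
  # stable digest of the config via canonical JSON -> md5 of a temp file
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                                           digits = NA, force = TRUE)), tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) x <- lapply(x, function(e) if (is.list(e)) unclass_deep(e) else e)
  x
}

stage_manifest_path <- function(out_dir, stage) {
  file.path(out_dir, sprintf("%s.manifest.json", stage))
}

stage_up_to_date <- function(out_dir, stage, cfg_fp, inputs) {
  mp <- stage_manifest_path(out_dir, stage)
  if (!file.exists(mp)) return(FALSE)
  man <- tryCatch(jsonlite::fromJSON(mp), error = function(e) NULL)
  if (is.null(man)) return(FALSE)
  if (!identical(man$config_fingerprint, cfg_fp)) return(FALSE)
  ins <- names(man$inputs)
  if (length(ins)) {
    if (!all(file.exists(ins))) return(FALSE)
    if (!identical(unname(unlist(man$inputs)), unname(file_md5(ins)))) return(FALSE)
  }
  outs <- names(man$outputs)
  length(outs) > 0 && all(file.exists(outs)) &&
    identical(unname(unlist(man$outputs)), unname(file_md5(outs)))
}

write_stage_manifest <- function(out_dir, stage, cfg_fp, inputs, outputs, seed) {
  man <- list(stage = stage, config_fingerprint = cfg_fp,
              inputs = if (length(inputs)) as.list(stats::setNames(file_md5(inputs), inputs)) else list(),
              outputs = as.list(stats::setNames(file_md5(outputs), outputs)),
              seed = seed,
              package_version = as.character(utils::packageVersion("sicdic")))
  jsonlite::write_json(man, stage_manifest_path(out_dir, stage),
                       auto_unbox = TRUE, digits = NA)
}

pipe_log <- function(out_dir, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message("[sicdic] ", msg)
  cat(msg, "\n", file = file.path(out_dir, "run.log"), append = TRUE)
}

#' Run the end-to-end pipeline
#'
#' Orchestrates generate -> label -> encode -> train -> evaluate -> interpret
#' into an artifact directory. Each stage writes its outputs plus a manifest
#' (config fingerprint, input/output checksums, seed, package version);
#' rerunning with an unchanged configuration skips stages whose manifests
#' still verify. `stages` must be a prefix of the stage DAG.
#'
#' @param config a [run_config()] (or a path accepted by [load_run_config()])
#' @param out_dir artifact directory (created if missing)
#' @param stages stages to run; must be prefix-closed (default: all)
#' @return `out_dir`, invisibly; artifacts: `cohort.csv`, `truth.csv`,
#'   `timelines.csv`, `splits.json`, `norm_stats.csv`, `windows_*.jsonl`,
#'   `predictions.csv`, `eval_report.csv`, `report_table_*.csv`,
#'   `threshold_sweep.csv`, `metrics.json`, `occlusion.csv`,
#'   `shap_global.csv`, `lite_features.json`, per-stage manifests and `run.log`
#' @export
run_pipeline <- function(config, out_dir, stages = pipeline_stages()) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  all_st <- pipeline_stages()
  idx <- sort(match(stages, all_st))
  if (anyNA(idx)) stopf("unknown stage(s): %s", paste(stages[is.na(idx)], collapse = ", "))
  if (length(idx) > 1 && !all(diff(idx) == 1)) {
    stopf("stages must be a contiguous prefix-closed chain of %s",
          paste(all_st, collapse = " -> "))
  }
  stages <- all_st[seq(min(idx), max(idx))]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_fp <- config_fingerprint(config)

  paths <- list(
    cohort = file.path(out_dir, "cohort.csv"),
    truth = file.path(out_dir, "truth.csv"),
    timelines = file.path(out_dir, "timelines.csv"),
    splits = file.path(out_dir, "splits.json"),
    norm = file.path(out_dir, "norm_stats.csv"),
    predictions = file.path(out_dir, "predictions.csv"),
    report = file.path(out_dir, "eval_report.csv"),
    sweep = file.path(out_dir, "threshold_sweep.csv"),
    metrics = file.path(out_dir, "metrics.json"),
    occlusion = file.path(out_dir, "occlusion.csv"),
    shap = file.path(out_dir, "shap_global.csv"),
    lite = file.path(out_dir, "lite_features.json")
  )
  win_path <- function(split) file.path(out_dir, sprintf("windows_%s.jsonl", split))

  run_stage <- function(stage, inputs, outputs, fn) {
    if (stage_up_to_date(out_dir, stage, cfg_fp, inputs)) {
      pipe_log(out_dir, "stage %-9s skipped (manifest verifies)", stage)
      return(invisible(FALSE))
    }
    t0 <- Sys.time()
    fn()
    write_stage_manifest(out_dir, stage, cfg_fp, inputs, outputs, config$seed)
    pipe_log(out_dir, "stage %-9s done in %.1fs", stage,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
    invisible(TRUE)
  }

  if ("generate" %in% stages) {
    run_stage("generate", character(0), c(paths$cohort, paths$truth), function() {
      coh <- generate_cohort(config$cohort)
      write_cohort(coh, paths$cohort)
      write_truth(coh$truth, paths$truth)
    })
  }
  if ("label" %in% stages) {
    require_inputs(paths$cohort, "generate")
    run_stage("label", c(paths$cohort, paths$truth), paths$timelines, function() {
      ev <- read_cohort(paths$cohort)
      tr <- read_truth(paths$truth)
      tls <- label_cohort(ev, config$cutoffs,
                          window_len_h = config$encoding$slide_step_h,
                          stays = stats::setNames(tr$stay_h, tr$patient_id))
      write_timelines(tls, paths$timelines)
    })
  }
  if ("encode" %in% stages) {
    require_inputs(paths$timelines, "label")
    outs <- c(paths$splits, paths$norm, win_path("train"), win_path("valid"), win_path("test"))
    run_stage("encode", c(paths$cohort, paths$timelines), outs, function() {
      ev <- read_cohort(paths$cohort)
      tr <- read_truth(paths$truth)
      tls <- read_timelines_csv(paths$timelines)
      sp <- split_patients(sort(unique(ev$patient_id)), seed = mix_seed(config$seed, 1L))
      jsonlite::write_json(sp, paths$splits, auto_unbox = FALSE, digits = NA)
      norm <- fit_normalization(ev, sp$train, config$encoding)
      write_canonical_csv(norm, paths$norm)
      for (split in names(sp)) {
        wins <- encode_cohort(ev[ev$patient_id %in% sp[[split]], ],
                              tls[names(tls) %in% sp[[split]]],
                              config$encoding, norm)
        write_window_tensors(wins, win_path(split))
      }
    })
  }
  if ("train" %in% stages) {
    require_inputs(win_path("train"), "encode")
    run_stage("train", c(win_path("train"), win_path("valid"), win_path("test")),
              paths$predictions, function() {
      w_tr <- read_window_tensors(win_path("train"))
      w_va <- read_window_tensors(win_path("valid"))
      w_te <- read_window_tensors(win_path("test"))
      preds <- list()
      for (mi in seq_along(config$models)) {
        mid <- config$models[mi]
        mseed <- mix_seed(config$seed, 100L + mi)
        if (mid %in% c("lr", "svm", "xgb", "xgb_dart")) {
          args <- c(list(train_windows = w_tr, model = mid,
                         grid_h = config$encoding$discretization_grid_h,
                         delta_scale_h = config$encoding$delta_scale_h,
                         seed = mseed), config$tabular)
          fit <- do.call(train_tabular_baselines, args)
        } else {
          args <- c(list(cell = mid, seed = mseed,
                         grid_h = config$encoding$discretization_grid_h,
                         delta_scale_h = config$encoding$delta_scale_h),
                    config$seq_model)
          fit <- train_sequence_model(w_tr, w_va, do.call(seq_model_config, args))
        }
        saveRDS(fit, file.path(out_dir, sprintf("model_%s.rds", mid)))
        jsonlite::write_json(
          list(model = mid, seed = mseed, config_fingerprint = cfg_fp,
               n_train_windows = length(w_tr)),
          file.path(out_dir, sprintf("model_%s.manifest.json", mid)),
          auto_unbox = TRUE, digits = NA)
        preds[[mid]] <- predict_risk(fit, w_te)
      }
      all_preds <- do.call(rbind, preds)
      write_canonical_csv(all_preds, paths$predictions)
    })
  }
  if ("evaluate" %in% stages) {
    require_inputs(paths$predictions, "train")
    run_stage("evaluate", paths$predictions,
              c(paths$report, paths$sweep, paths$metrics), function() {
      preds <- read_predictions_csv(paths$predictions)
      by_model <- split(preds, preds$model)
      by_model <- lapply(by_model, function(p) { class(p) <- c("prediction_set", class(p)); p })
      rep <- horizon_report(by_model, resamples = config$evaluation$resamples,
                            level = config$evaluation$level,
                            seed = mix_seed(config$seed, 2L),
                            unit = config$evaluation$unit)
      write_canonical_csv(rep, paths$report)
      for (mt in unique(rep$metric)) {
        write_canonical_csv(report_table(rep, mt),
                            file.path(out_dir, sprintf("report_table_%s.csv", tolower(mt))))
      }
      sweeps <- lapply(by_model, function(p) {
        s <- alarm_metrics(p, horizon_h = config$interpret$horizon_h)
        if (!is.null(s)) s$model <- p$model[1]
        s
      })
      write_canonical_csv(do.call(rbind, sweeps), paths$sweep)
      jsonlite::write_json(rep, paths$metrics, auto_unbox = TRUE, digits = NA)
    })
  }
  if ("interpret" %in% stages) {
    require_inputs(paths$report, "evaluate")
    run_stage("interpret", c(paths$cohort, paths$timelines, paths$norm),
              c(paths$occlusion, paths$lite), function() {
      ev <- read_cohort(paths$cohort)
      tls <- read_timelines_csv(paths$timelines)
      sp <- jsonlite::fromJSON(paths$splits)
      norm <- read_norm_csv(paths$norm)
      ev_te <- ev[ev$patient_id %in% sp$test, ]
      tls_te <- tls[names(tls) %in% sp$test]
      # occlusion on the first sequence model if present, else the first model
      seq_ids <- intersect(config$models, c("rnn", "lstm", "decay_rnn", "ode_rnn"))
      occ_id <- if (length(seq_ids)) seq_ids[1] else config$models[1]
      occ_model <- readRDS(file.path(out_dir, sprintf("model_%s.rds", occ_id)))
      occ <- occlusion_analysis(occ_model, ev_te, tls_te, config$encoding, norm,
                                disease = config$interpret$disease,
                                horizon_h = config$interpret$horizon_h)
      write_canonical_csv(occ, paths$occlusion)
      tree_ids <- intersect(config$models, c("xgb", "xgb_dart"))
      if (length(tree_ids)) {
        tree_model <- readRDS(file.path(out_dir, sprintf("model_%s.rds", tree_ids[1])))
        w_te <- read_window_tensors(win_path("test"))
        attr_out <- export_attributions(tree_model, w_te,
                                        disease = config$interpret$disease,
                                        horizon_h = config$interpret$horizon_h)
        write_canonical_csv(attr_out$global_variable, paths$shap)
        shap_tab <- attr_out$global_variable
      } else {
        shap_tab <- data.frame(variable = occ$variable, importance = occ$delta)
      }
      lite <- build_lite_set(shap_tab, occ, k = config$interpret$lite_k)
      write_lite_set(lite, paths$lite)
    })
  }
  invisible(out_dir)
}

require_inputs <- function(path, producing_stage) {
  missing <- path[!file.exists(path)]
  if (length(missing)) {
    stopf("missing input %s: run the '%s' stage first", missing[1], producing_stage)
  }
}

read_timelines_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path, colClasses = list(
    character = c("patient_id", "sic_provenance", "dic_provenance", "provenance"))))
  for (col in c("sic_label", "dic_label")) df[[col]] <- as.integer(df[[col]])
  out <- split(df, df$patient_id)
  lapply(out, function(tl) {
    rownames(tl) <- NULL
    attr(tl, "window_len_h") <- if (nrow(tl) > 1) diff(tl$window_start_h[1:2]) else 8
    class(tl) <- c("label_timeline", "data.frame")
    tl
  })
}

read_norm_csv <- function(path) {
  ns <- as.data.frame(data.table::fread(path, colClasses = list(character = "variable",
                                                                logical = "constant")))
  class(ns) <- c("norm_stats", "data.frame")
  ns
}

read_predictions_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path, colClasses = list(
    character = c("patient_id", "disease", "model"))))
  df$target <- as.integer(df$target)
  df
}

#' Sampling-window pre-experiment sweep
#'
#' Reruns the pipeline for several sampling-window lengths and collects the
#' evaluation reports (one subdirectory per window length).
#'
#' @param config a [run_config()]
#' @param out_dir parent artifact directory
#' @param windows_h sampling windows to try (default 8, 24, 48)
#' @return combined `eval_report` with a `sampling_window_h` column
#' @export
sweep_sampling_windows <- function(config, out_dir, windows_h = c(8, 24, 48)) {
  reps <- lapply(windows_h, function(w) {
    cfg <- config
    cfg$encoding$sampling_window_h <- w
    sub <- file.path(out_dir, sprintf("window_%dh", w))
    run_pipeline(cfg, sub, stages = c("generate", "label", "encode", "train", "evaluate"))
    rep <- as.data.frame(data.table::fread(file.path(sub, "eval_report.csv")))
    rep$sampling_window_h <- w
    rep
  })
  do.call(rbind, reps)
}
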