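#' Tabular baseline models on discretized window features
#'
#' Fits one independent classifier per (disease, horizon) head on the
#' fixed-length features from [discretize_for_tabular()]. The fits are
#' delegated to established implementations: logistic regression
#' (`stats::glm`), support vector machine (`e1071::svm` with probability
#' outputs; training rows are subsampled to `svm_max_rows` because kernel
#' fitting is quadratic), and two gradient-boosted tree variants
#' (`xgboost` with the `"gbtree"` and `"dart"` boosters). All models emit
#' probabilities through the shared prediction-set contract.
#'
#' @param train_windows list of `window_tensor`s
#' @param model one of `"lr"`, `"svm"`, `"xgb"`, `"xgb_dart"`
#' @param grid_h,delta_scale_h discretization settings (match the encoding)
#' @param seed integer seed (xgboost subsampling / svm subsample)
#' @param nrounds,max_depth,eta boosted-tree hyperparameters
#' @param svm_max_rows row cap for the SVM fit
#' @param class_weighting inverse-prevalence weighting (default on)
#' @return object of class `tabular_model`
#' @export
train_tabular_baselines <- function(train_windows,
                                    model = c("lr", "svm", "xgb", "xgb_dart"),
                                    grid_h = 8, delta_scale_h = 24, seed = 1L,
                                    nrounds = 150, max_depth = 4, eta = 0.1,
                                    svm_max_rows = 2000, class_weighting = TRUE) {
  model <- match.arg(model)
  X <- window_features(train_windows, grid_h, delta_scale_h)
  Y <- targets_matrix(train_windows)
  heads <- head_info(colnames(Y))

  const <- apply(X, 2, function(col) min(col) == max(col))
  if (any(const)) {
    warning(sprintf("dropping %d constant feature(s): %s", sum(const),
                    paste(utils::head(colnames(X)[const], 5), collapse = ", ")))
  }
  keep <- colnames(X)[!const]
  X <- X[, keep, drop = FALSE]

  fits <- vector("list", nrow(heads))
  names(fits) <- heads$head
  for (k in seq_len(nrow(heads))) {
    ok <- !is.na(Y[, k])
    y <- Y[ok, k]
    if (length(unique(y)) < 2) { fits[[k]] <- NULL; next }
    Xk <- X[ok, , drop = FALSE]
    w <- if (class_weighting) {
      ifelse(y == 1, length(y) / (2 * sum(y == 1)), length(y) / (2 * sum(y == 0)))
    } else rep(1, length(y))
    fits[[k]] <- switch(model,
      lr = fit_lr(Xk, y, w),
      svm = fit_svm(Xk, y, svm_max_rows, mix_seed(seed, k)),
      xgb = fit_xgb(Xk, y, "gbtree", nrounds, max_depth, eta, mix_seed(seed, k)),
      xgb_dart = fit_xgb(Xk, y, "dart", nrounds, max_depth, eta, mix_seed(seed, k))
    )
  }
  structure(list(model_id = model, fits = fits, heads = heads,
                 features = keep, grid_h = grid_h,
                 delta_scale_h = delta_scale_h),
            class = "tabular_model")
}

window_features <- function(windows, grid_h, delta_scale_h) {
  t(vapply(windows,
           function(w) discretize_for_tabular(w, grid_h, delta_scale_h = delta_scale_h),
           numeric(length(discretize_for_tabular(windows[[1]], grid_h,
                                                 delta_scale_h = delta_scale_h)))))
}

fit_lr <- function(X, y, w) {
  df <- as.data.frame(X)
  df$.y <- y
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial(), weights = w,
               control = list(maxit = 50))
  )
  # strip the heavy environments; keep only what predict needs
  fit$model <- NULL; fit$data <- NULL; fit$y <- NULL
  list(kind = "lr", fit = fit)
}

fit_svm <- function(X, y, max_rows, seed) {
  set.seed(seed)
  if (nrow(X) > max_rows) {
    idx <- sample.int(nrow(X), max_rows)
    X <- X[idx, , drop = FALSE]; y <- y[idx]
  }
  fit <- e1071::svm(X, factor(y, levels = c(0, 1)), probability = TRUE,
                    kernel = "radial", cost = 1, scale = TRUE)
  list(kind = "svm", fit = fit)
}

fit_xgb <- function(X, y, booster, nrounds, max_depth, eta, seed) {
  spw <- sum(y == 0) / max(sum(y == 1), 1)
  params <- list(objective = "binary:logistic", booster = booster,
                 max_depth = max_depth, eta = eta, nthread = 1,
                 scale_pos_weight = spw, seed = seed)
  dtr <- xgboost::xgb.DMatrix(X, label = y)
  fit <- xgboost::xgb.train(params = params, data = dtr, nrounds = nrounds,
                            verbose = 0)
  list(kind = "xgb", fit = fit, features = colnames(X))
}

predict_head <- function(fit, X) {
  if (is.null(fit)) return(rep(NA_real_, nrow(X)))
  switch(fit$kind,
    lr = {
      co <- stats::coef(fit$fit)
      co[is.na(co)] <- 0
      as.numeric(stats::plogis(cbind(1, X[, names(co)[-1], drop = FALSE]) %*% co))
    },
    svm = {
      pr <- attr(predict(fit$fit, X, probability = TRUE), "probabilities")
      as.numeric(pr[, "1"])
    },
    xgb = as.numeric(predict(fit$fit, xgboost::xgb.DMatrix(X)))
  )
}

#' @export
predict_risk.tabular_model <- function(model, windows, ...) {
  X <- window_features(windows, model$grid_h, model$delta_scale_h)
  X <- X[, model$features, drop = FALSE]
  probs <- matrix(NA_real_, nrow(X), nrow(model$heads))
  for (k in seq_len(nrow(model$heads))) {
    probs[, k] <- predict_head(model$fits[[k]], X)
  }
  prediction_frame(windows, probs, model$heads, model$model_id)
}
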