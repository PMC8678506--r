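#' Sequence-model configuration
#'
#' Hyperparameters of the recurrent risk models. Cells: `"rnn"` and `"lstm"`
#' consume the temporally discretized grid view of a window (fixed steps,
#' inputs `(x, m)` per grid cell); `"decay_rnn"` and `"ode_rnn"` consume the
#' irregular event view directly (inputs `(x, m, delta/delta_scale)` at each
#' observation timestamp). The decay cell multiplies the hidden state by
#' `exp(-max(0, w_gamma * gap + b_gamma))` before each update; the ODE cell
#' propagates the hidden state between observations by a learned ODE
#' `dh/dt = tanh(h W1 + b1) W2` solved with fixed-step RK4.
#'
#' @param cell one of `"rnn"`, `"lstm"`, `"decay_rnn"`, `"ode_rnn"`
#' @param hidden_dim latent dimension (default 32)
#' @param epochs training epochs (default 20)
#' @param learning_rate optimizer step size
#' @param batch_size minibatch size
#' @param optimizer `"adam"` or `"sgd"` (momentum 0.9)
#' @param seed integer seed controlling init and shuffling
#' @param ode_substeps RK4 substeps per inter-observation gap during batched
#'   training (default 2)
#' @param ode_step_h maximum RK4 step in hours for single-window queries
#'   (default 0.1; the effective step is `min(ode_step_h, gap/4)`)
#' @param grad_clip global gradient-norm clip (default 5)
#' @param class_weighting inverse-prevalence loss weights per head (default on)
#' @param grid_h discretization grid for the rnn/lstm view (default 8)
#' @param delta_scale_h scale for interval inputs (default 24)
#' @param max_train_windows optional cap on training windows per epoch
#'   (seeded subsample; `Inf` to disable)
#' @param patience epochs without validation improvement before stopping early
#' @return object of class `seq_model_config`
#' @export
seq_model_config <- function(cell = c("ode_rnn", "decay_rnn", "rnn", "lstm"),
                             hidden_dim = 32, epochs = 20, learning_rate = 0.005,
                             batch_size = 256, optimizer = c("adam", "sgd"),
                             seed = 1L, ode_substeps = 2, ode_step_h = 0.1,
                             grad_clip = 5, class_weighting = TRUE,
                             grid_h = 8, delta_scale_h = 24,
                             max_train_windows = Inf, patience = 6) {
  cell <- match.arg(cell)
  optimizer <- match.arg(optimizer)
  if (hidden_dim < 1) stopf("hidden_dim must be positive")
  if (ode_step_h <= 0 || ode_substeps < 1) stopf("ODE solver settings must be positive")
  structure(list(cell = cell, hidden_dim = as.integer(hidden_dim),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 seed = as.integer(seed), ode_substeps = as.integer(ode_substeps),
                 ode_step_h = ode_step_h, grad_clip = grad_clip,
                 class_weighting = isTRUE(class_weighting), grid_h = grid_h,
                 delta_scale_h = delta_scale_h,
                 max_train_windows = max_train_windows,
                 patience = as.integer(patience)),
            class = "seq_model_config")
}

seq_view <- function(cell) if (cell %in% c("rnn", "lstm")) "grid" else "event"

#' Stack window tensors into padded batch arrays
#'
#' `view = "event"` keeps the irregular timestamps (one step per observation
#' time, gaps in `DT`, padded steps flagged invalid in `V`); `view = "grid"`
#' temporally discretizes each window onto fixed cells of `grid_h` hours
#' (last observed value + mask per cell).
#'
#' @param windows list of `window_tensor`s
#' @param view `"event"` or `"grid"`
#' @param grid_h grid-cell hours for the grid view
#' @param delta_scale_h scale for interval inputs
#' @return batch list consumed by the sequence models
#' @keywords internal
build_seq_batch <- function(windows, view = c("event", "grid"), grid_h = 8,
                            delta_scale_h = 24) {
  view <- match.arg(view)
  N <- length(windows)
  vars <- windows[[1]]$variables
  D <- length(vars)
  if (view == "grid") {
    W <- windows[[1]]$window_end_h - windows[[1]]$window_start_h
    Tn <- as.integer(W / grid_h)
    X <- array(0, c(N, D, Tn)); M <- array(0, c(N, D, Tn))
    for (i in seq_len(N)) {
      w <- windows[[i]]
      for (t in seq_along(w$s)) {
        if (sum(w$m[t, ]) == 0) next
        cell_i <- min(floor((w$s[t] - w$window_start_h) / grid_h) + 1, Tn)
        obs <- which(w$m[t, ] == 1)
        X[i, obs, cell_i] <- w$x[t, obs]
        M[i, obs, cell_i] <- 1
      }
    }
    DT <- matrix(grid_h, N, Tn)
    V <- matrix(1, N, Tn)
    return(list(X = X, M = M, DL = NULL, DT = DT, V = V, N = N, T = Tn, D = D,
                input_dim = 2 * D, view = "grid", variables = vars))
  }
  lens <- vapply(windows, function(w) length(w$s), integer(1))
  Tn <- max(lens)
  X <- array(0, c(N, D, Tn)); M <- array(0, c(N, D, Tn)); DL <- array(0, c(N, D, Tn))
  DT <- matrix(0, N, Tn); V <- matrix(0, N, Tn)
  for (i in seq_len(N)) {
    w <- windows[[i]]
    Ti <- lens[i]
    X[i, , seq_len(Ti)] <- t(w$x)
    M[i, , seq_len(Ti)] <- t(w$m)
    DL[i, , seq_len(Ti)] <- t(w$delta) / delta_scale_h
    DT[i, seq_len(Ti)] <- w$dt
    V[i, seq_len(Ti)] <- 1
  }
  list(X = X, M = M, DL = DL, DT = DT, V = V, N = N, T = Tn, D = D,
       input_dim = 3 * D, view = "event", variables = vars)
}

# N x K target matrix over (disease, horizon) heads, NA where absent
targets_matrix <- function(windows, horizons = NULL) {
  tg0 <- windows[[1]]$targets
  horizons <- horizons %||% tg0$horizon_h
  heads <- c(paste0("sic_h", horizons), paste0("dic_h", horizons))
  Y <- matrix(NA_real_, length(windows), length(heads),
              dimnames = list(NULL, heads))
  for (i in seq_along(windows)) {
    tg <- windows[[i]]$targets
    j <- match(horizons, tg$horizon_h)
    Y[i, seq_along(horizons)] <- tg$sic[j]
    Y[i, length(horizons) + seq_along(horizons)] <- tg$dic[j]
  }
  Y
}

head_info <- function(head_names) {
  data.frame(head = head_names,
             disease = sub("_h.*$", "", head_names),
             horizon_h = as.numeric(sub("^.*_h", "", head_names)),
             stringsAsFactors = FALSE)
}

#' Train a recurrent risk model on window tensors
#'
#' Fits a shared recurrent trunk with one sigmoid head per (disease, horizon)
#' by minibatch gradient descent on masked binary cross-entropy (heads with an
#' absent target contribute nothing for that window). Class-imbalance weights
#' are inverse prevalence per head. Model selection: the weights of the epoch
#' with the best mean validation AUROC (over heads with both classes) are
#' kept. Deterministic given `config$seed`.
#'
#' @param train_windows,valid_windows patient-disjoint lists of
#'   `window_tensor`s
#' @param config a [seq_model_config()]
#' @return object of class `seq_model` with elements `params`, `config`,
#'   `heads`, `variables`, and `log` (per-epoch loss and validation AUROC)
#' @export
train_sequence_model <- function(train_windows, valid_windows, config) {
  stopifnot(inherits(config, "seq_model_config"))
  view <- seq_view(config$cell)
  batch_tr <- build_seq_batch(train_windows, view, config$grid_h, config$delta_scale_h)
  batch_va <- build_seq_batch(valid_windows, view, config$grid_h, config$delta_scale_h)
  Y_tr <- targets_matrix(train_windows)
  Y_va <- targets_matrix(valid_windows)
  heads <- head_info(colnames(Y_tr))

  pos <- colSums(Y_tr == 1, na.rm = TRUE)
  neg <- colSums(Y_tr == 0, na.rm = TRUE)
  seen <- colSums(!is.na(Y_tr))
  if (all(pos == 0) || all(neg == 0)) {
    stopf("training targets are all one class; cannot fit a discriminative model")
  }
  if (config$class_weighting) {
    w_pos <- ifelse(pos > 0, seen / (2 * pos), 0)
    w_neg <- ifelse(neg > 0, seen / (2 * neg), 0)
  } else {
    w_pos <- rep(1, ncol(Y_tr)); w_neg <- rep(1, ncol(Y_tr))
  }

  params <- init_seq_params(config$cell, batch_tr$input_dim, config$hidden_dim,
                            ncol(Y_tr), config$seed)
  opt_state <- if (config$optimizer == "adam") adam_init(params) else sgd_init(params)
  set.seed(mix_seed(config$seed, 7919))

  best <- list(auroc = -Inf, params = params, epoch = 0L)
  log <- data.frame(epoch = integer(), train_loss = numeric(), valid_auroc = numeric())
  n_tr <- batch_tr$N
  since_best <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n_tr)
    if (is.finite(config$max_train_windows) && config$max_train_windows < n_tr) {
      ord <- ord[seq_len(config$max_train_windows)]
    }
    total_loss <- 0; n_batches <- 0
    for (b0 in seq(1, length(ord), by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
      mb <- slice_batch(batch_tr, idx)
      ls <- seq_loss(params, mb, config$cell, config$ode_substeps,
                     Y_tr[idx, , drop = FALSE], w_pos, w_neg)
      grads <- clip_global_norm(ls$grads, config$grad_clip)
      if (config$optimizer == "adam") {
        up <- adam_update(params, grads, opt_state, config$learning_rate)
      } else {
        up <- sgd_update(params, grads, opt_state, config$learning_rate)
      }
      params <- up$params; opt_state <- up$state
      total_loss <- total_loss + ls$loss; n_batches <- n_batches + 1
    }
    va <- seq_loss(params, batch_va, config$cell, config$ode_substeps,
                   Y_va, w_pos, w_neg, with_grads = FALSE)
    va_auroc <- mean_head_auroc(va$probs, Y_va)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = total_loss / n_batches,
                                 valid_auroc = va_auroc))
    if (is.finite(va_auroc) && va_auroc > best$auroc) {
      best <- list(auroc = va_auroc, params = params, epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
  }
  structure(list(params = best$params, config = config, heads = heads,
                 variables = batch_tr$variables, log = log,
                 best_epoch = best$epoch, model_id = config$cell),
            class = "seq_model")
}

mean_head_auroc <- function(probs, Y) {
  vals <- vapply(seq_len(ncol(Y)), function(k) {
    y <- Y[, k]; ok <- !is.na(y)
    if (sum(y[ok] == 1) == 0 || sum(y[ok] == 0) == 0) return(NA_real_)
    auroc(probs[ok, k], y[ok])
  }, numeric(1))
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

slice_batch <- function(batch, idx) {
  out <- batch
  out$X <- batch$X[idx, , , drop = FALSE]
  out$M <- batch$M[idx, , , drop = FALSE]
  if (!is.null(batch$DL)) out$DL <- batch$DL[idx, , , drop = FALSE]
  out$DT <- batch$DT[idx, , drop = FALSE]
  out$V <- batch$V[idx, , drop = FALSE]
  out$N <- length(idx)
  out
}

#' Per-horizon risk predictions from a trained model
#'
#' Applies the model to a set of windows and returns one risk in `[0, 1]` per
#' (window, disease, horizon) — the prediction-set contract shared by the
#' sequence models and the tabular baselines.
#'
#' @param model a `seq_model` (or `tabular_model`)
#' @param windows list of `window_tensor`s
#' @param ... unused
#' @return data.frame of class `prediction_set`: `patient_id, window_start_h,
#'   disease, horizon_h, risk, target, model`
#' @export
predict_risk <- function(model, windows, ...) UseMethod("predict_risk")

#' @export
predict_risk.seq_model <- function(model, windows, ...) {
  cfg <- model$config
  batch <- build_seq_batch(windows, seq_view(cfg$cell), cfg$grid_h, cfg$delta_scale_h)
  probs <- matrix(NA_real_, batch$N, nrow(model$heads))
  for (b0 in seq(1, batch$N, by = 1024)) {
    idx <- b0:min(b0 + 1023, batch$N)
    fw <- seq_forward_batch(model$params, slice_batch(batch, idx), cfg$cell,
                            cfg$ode_substeps)
    probs[idx, ] <- sigm(fw$h %*% model$params$Wy +
                           rowvec(model$params$by, length(idx)))
  }
  prediction_frame(windows, probs, model$heads, model$model_id)
}

prediction_frame <- function(windows, probs, heads, model_id) {
  Y <- targets_matrix(windows, unique(heads$horizon_h))
  n <- length(windows)
  pid <- vapply(windows, `[[`, character(1), "patient_id")
  ws <- vapply(windows, `[[`, numeric(1), "window_start_h")
  out <- do.call(rbind, lapply(seq_len(nrow(heads)), function(k) {
    data.frame(patient_id = pid, window_start_h = ws,
               disease = heads$disease[k], horizon_h = heads$horizon_h[k],
               risk = probs[, k], target = Y[, k], model = model_id,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("prediction_set", "data.frame")
  out
}

# --- single-window forward APIs ----------------------------------------------

single_window_batch <- function(window, view, grid_h = 8, delta_scale_h = 24) {
  build_seq_batch(list(window), view, grid_h, delta_scale_h)
}

#' Hidden state of the discretized RNN at the window end
#'
#' Runs the plain recurrent cell over the temporally discretized view of one
#' window (fixed grid steps; the cell never sees gap lengths).
#' @param window a `window_tensor`
#' @param params parameter list (e.g. `model$params` of a trained `"rnn"`
#'   model, or [init_seq_params()] output)
#' @param grid_h grid-cell hours
#' @return hidden-state vector at the window end
#' @export
rnn_forward <- function(window, params, grid_h = 8) {
  b <- single_window_batch(window, "grid", grid_h)
  drop(seq_forward_batch(params, b, "rnn")$h)
}

#' Hidden state of the decay RNN at the window end
#'
#' Before each update at an observation timestamp, the hidden state is decayed
#' elementwise by `gamma = exp(-max(0, w_gamma * gap + b_gamma))`, then the
#' recurrent update consumes `(x, m, delta)`.
#' @inheritParams rnn_forward
#' @param delta_scale_h interval input scale
#' @return hidden-state vector at the window end
#' @export
decay_rnn_forward <- function(window, params, delta_scale_h = 24) {
  if (any(window$dt < 0)) stopf("negative time gap: window timestamps unsorted")
  b <- single_window_batch(window, "event", delta_scale_h = delta_scale_h)
  drop(seq_forward_batch(params, b, "decay_rnn")$h)
}

#' Hidden state of the ODE-RNN, queryable at arbitrary times
#'
#' Between consecutive observations the hidden state evolves by the learned
#' dynamics `dh/dt = tanh(h W1 + b1) W2` (fixed-step RK4, step
#' `min(ode_step_h, gap/4)`); at each observation a recurrent-cell jump update
#' consumes `(x, m, delta)`. With `query_t` given, returns `h(query_t)` by
#' partial solve from the last observation at or before `query_t`.
#'
#' @inheritParams decay_rnn_forward
#' @param query_t optional time (hours, within the window span) at which to
#'   query the latent state; default: the window end
#' @param ode_step_h maximum RK4 step in hours
#' @return hidden-state vector at the window end (or at `query_t`)
#' @export
ode_rnn_forward <- function(window, params, query_t = NULL,
                            ode_step_h = 0.1, delta_scale_h = 24) {
  if (is.unsorted(window$s)) stopf("window timestamps must be sorted")
  H <- ncol(params$Wh)
  f <- function(h, t) drop(ode_f_forward(params, matrix(h, 1))$out)
  solve_to <- function(h, t0, t1) {
    if (t1 <= t0) return(h)
    rk4_solve(f, h, t0, t1, min(ode_step_h, max((t1 - t0) / 4, 1e-9)))
  }
  h <- rep(0, H)
  t_cur <- window$window_start_h
  end_t <- query_t %||% window$window_end_h
  if (end_t < window$window_start_h || end_t > window$window_end_h) {
    stopf("query_t %g outside window span [%g, %g]", end_t,
          window$window_start_h, window$window_end_h)
  }
  for (t in seq_along(window$s)) {
    if (window$s[t] > end_t) break
    h <- solve_to(h, t_cur, window$s[t])
    u <- c(window$x[t, ], window$m[t, ], window$delta[t, ] / delta_scale_h)
    h <- drop(tanh(matrix(u, 1) %*% params$Wx + matrix(h, 1) %*% params$Wh + params$b))
    t_cur <- window$s[t]
  }
  solve_to(h, t_cur, end_t)
}
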