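# Batched recurrent-network core: forward passes, backpropagation through
# time, an RK4 solver for the continuous-time hidden dynamics, and Adam/SGD.
# All math is plain matrix algebra over the minibatch so BLAS does the work;
# gradients are verified against numerical differentiation in the test suite.

sigm <- function(x) 1 / (1 + exp(-x))

# slice step t out of an N x D x T array without dropping dims
arr_step <- function(A, t) matrix(A[, , t], nrow = dim(A)[1], ncol = dim(A)[2])

rowvec <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

#' Fixed-step fourth-order Runge-Kutta solver
#'
#' Integrates `dh/dt = f(h, t)` from `t0` to `t1` with step
#' `(t1 - t0) / ceiling((t1 - t0) / step_h)` (so the span is covered exactly).
#' Used for the continuous hidden-state propagation of the ODE-RNN between
#' observations; exposed because it is also a convenient numerics utility.
#'
#' @param f function `(h, t) -> dh/dt` on numeric vectors
#' @param h0 initial state
#' @param t0,t1 time span (`t1 >= t0`)
#' @param step_h maximum step size
#' @return the state at `t1`
#' @export
#' @examples
#' rk4_solve(function(h, t) -h, 1, 0, 1, 0.05)  # ~ exp(-1)
rk4_solve <- function(f, h0, t0, t1, step_h = 0.1) {
  if (t1 < t0) stopf("rk4_solve: t1 (%g) < t0 (%g)", t1, t0)
  if (t1 == t0) return(h0)
  n <- ceiling((t1 - t0) / step_h)
  dt <- (t1 - t0) / n
  h <- h0
  t <- t0
  for (i in seq_len(n)) {
    k1 <- f(h, t)
    k2 <- f(h + dt / 2 * k1, t + dt / 2)
    k3 <- f(h + dt / 2 * k2, t + dt / 2)
    k4 <- f(h + dt * k3, t + dt)
    if (any(!is.finite(k4))) stopf("rk4_solve: solver failure on interval [%g, %g]", t, t + dt)
    h <- h + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  h
}

# --- parameter initialization ------------------------------------------------

init_seq_params <- function(cell, input_dim, hidden_dim, n_heads, seed) {
  set.seed(seed)
  H <- hidden_dim
  rmat <- function(nr, nc) {
    r <- 1 / sqrt(nr)
    matrix(stats::runif(nr * nc, -r, r), nr, nc)
  }
  p <- list()
  if (cell == "lstm") {
    p$Wx <- rmat(input_dim, 4 * H)
    p$Wh <- rmat(H, 4 * H)
    b <- rep(0, 4 * H)
    b[(H + 1):(2 * H)] <- 1  # forget-gate bias
    p$b <- matrix(b, 1)
  } else {
    p$Wx <- rmat(input_dim, H)
    p$Wh <- rmat(H, H)
    p$b <- matrix(0, 1, H)
  }
  if (cell == "decay_rnn") {
    p$w_gamma <- matrix(stats::runif(H, 0, 0.2), 1)  # per-dimension decay rates
    p$b_gamma <- matrix(0, 1, H)
  }
  if (cell == "ode_rnn") {
    p$W1 <- rmat(H, H)
    p$b1 <- matrix(0, 1, H)
    p$W2 <- rmat(H, H) * 0.1  # gentle initial dynamics
  }
  p$Wy <- rmat(H, n_heads)
  p$by <- matrix(0, 1, n_heads)
  p
}

# --- ODE dynamics f(h) = tanh(h W1 + b1) W2 ---------------------------------

ode_f_forward <- function(p, h) {
  n <- nrow(h)
  a <- tanh(h %*% p$W1 + rowvec(p$b1, n))
  list(out = a %*% p$W2, g = h, a = a)
}

ode_f_backward <- function(p, cache, dout, grads) {
  da <- dout %*% t(p$W2)
  grads$W2 <- grads$W2 + t(cache$a) %*% dout
  dz <- da * (1 - cache$a^2)
  grads$W1 <- grads$W1 + t(cache$g) %*% dz
  grads$b1 <- grads$b1 + colSums(dz)
  list(dg = dz %*% t(p$W1), grads = grads)
}

# one batched RK4 substep with per-sample step sizes dt (vector length N)
ode_rk4_step_forward <- function(p, h0, dt) {
  f1 <- ode_f_forward(p, h0)
  f2 <- ode_f_forward(p, h0 + (dt / 2) * f1$out)
  f3 <- ode_f_forward(p, h0 + (dt / 2) * f2$out)
  f4 <- ode_f_forward(p, h0 + dt * f3$out)
  h1 <- h0 + (dt / 6) * (f1$out + 2 * f2$out + 2 * f3$out + f4$out)
  list(h1 = h1, h0 = h0, dt = dt, f1 = f1, f2 = f2, f3 = f3, f4 = f4)
}

ode_rk4_step_backward <- function(p, cache, dh1, grads) {
  dt <- cache$dt
  dh0 <- dh1
  dk1 <- dh1 * (dt / 6)
  dk2 <- dh1 * (dt / 3)
  dk3 <- dh1 * (dt / 3)
  dk4 <- dh1 * (dt / 6)
  bk <- ode_f_backward(p, cache$f4, dk4, grads); grads <- bk$grads
  dh0 <- dh0 + bk$dg
  dk3 <- dk3 + bk$dg * dt
  bk <- ode_f_backward(p, cache$f3, dk3, grads); grads <- bk$grads
  dh0 <- dh0 + bk$dg
  dk2 <- dk2 + bk$dg * (dt / 2)
  bk <- ode_f_backward(p, cache$f2, dk2, grads); grads <- bk$grads
  dh0 <- dh0 + bk$dg
  dk1 <- dk1 + bk$dg * (dt / 2)
  bk <- ode_f_backward(p, cache$f1, dk1, grads); grads <- bk$grads
  dh0 <- dh0 + bk$dg
  list(dh0 = dh0, grads = grads)
}

# --- forward -----------------------------------------------------------------

# batch: list(X, M, DL (N x D x T), DT (N x T gaps), V (N x T valid), N, T, D,
#             input_dim, view) -- see build_seq_batch()
seq_forward_batch <- function(params, batch, cell, n_substeps = 2,
                              with_cache = FALSE) {
  N <- batch$N; Tn <- batch$T; H <- ncol(params$Wh)
  if (cell == "lstm") H <- ncol(params$Wh) / 4
  h <- matrix(0, N, H)
  cc <- matrix(0, N, H)
  caches <- if (with_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    u <- batch_input(batch, t)
    v <- batch$V[, t]
    dt <- batch$DT[, t]
    st <- list(u = u, v = v, dt = dt, h_in = h, c_in = cc)

    hd <- h
    if (cell == "ode_rnn") {
      dt_sub <- dt / n_substeps
      sub <- vector("list", n_substeps)
      for (k in seq_len(n_substeps)) {
        sc <- ode_rk4_step_forward(params, hd, dt_sub)
        hd <- sc$h1
        sub[[k]] <- sc
      }
      st$ode_sub <- sub
    } else if (cell == "decay_rnn") {
      z <- outer(dt, drop(params$w_gamma)) + rowvec(params$b_gamma, N)
      gamma <- exp(-pmax(z, 0))
      hd <- gamma * h
      st$z_decay <- z; st$gamma <- gamma
    }
    st$hd <- hd

    if (cell == "lstm") {
      zg <- u %*% params$Wx + h %*% params$Wh + rowvec(params$b, N)
      i_g <- sigm(zg[, 1:H, drop = FALSE])
      f_g <- sigm(zg[, (H + 1):(2 * H), drop = FALSE])
      o_g <- sigm(zg[, (2 * H + 1):(3 * H), drop = FALSE])
      g_g <- tanh(zg[, (3 * H + 1):(4 * H), drop = FALSE])
      c_new <- f_g * cc + i_g * g_g
      tc <- tanh(c_new)
      h_new <- o_g * tc
      st$i <- i_g; st$f <- f_g; st$o <- o_g; st$g <- g_g
      st$c_new <- c_new; st$tc <- tc
      cc <- v * c_new + (1 - v) * cc
    } else {
      a <- u %*% params$Wx + hd %*% params$Wh + rowvec(params$b, N)
      h_new <- tanh(a)
    }
    st$h_new <- h_new
    if (any(!is.finite(h_new))) {
      stopf("non-finite hidden state at step %d: training aborted (try a lower learning rate)", t)
    }
    h <- v * h_new + (1 - v) * h
    if (with_cache) caches[[t]] <- st
  }
  list(h = h, caches = caches)
}

batch_input <- function(batch, t) {
  x <- arr_step(batch$X, t)
  m <- arr_step(batch$M, t)
  if (batch$view == "grid") cbind(x, m) else cbind(x, m, arr_step(batch$DL, t))
}

# --- backward ----------------------------------------------------------------

zero_like <- function(params) lapply(params, function(p) p * 0)

seq_backward_batch <- function(params, batch, cell, n_substeps, caches, dh_final) {
  Tn <- batch$T
  H <- ncol(dh_final)
  grads <- zero_like(params)
  dh <- dh_final
  dc <- matrix(0, nrow(dh_final), H)
  for (t in rev(seq_len(Tn))) {
    st <- caches[[t]]
    v <- st$v
    dh_new <- dh * v
    dh_prev <- dh * (1 - v)

    if (cell == "lstm") {
      dc_new <- dc * v
      d_o <- dh_new * st$tc
      dc_new <- dc_new + dh_new * st$o * (1 - st$tc^2)
      d_f <- dc_new * st$c_in
      d_i <- dc_new * st$g
      d_g <- dc_new * st$i
      dc <- dc_new * st$f + dc * (1 - v)
      dz <- cbind(d_i * st$i * (1 - st$i),
                  d_f * st$f * (1 - st$f),
                  d_o * st$o * (1 - st$o),
                  d_g * (1 - st$g^2))
      grads$Wx <- grads$Wx + t(st$u) %*% dz
      grads$Wh <- grads$Wh + t(st$h_in) %*% dz
      grads$b <- grads$b + colSums(dz)
      dh_prev <- dh_prev + dz %*% t(params$Wh)
    } else {
      da <- dh_new * (1 - st$h_new^2)
      grads$Wx <- grads$Wx + t(st$u) %*% da
      grads$Wh <- grads$Wh + t(st$hd) %*% da
      grads$b <- grads$b + colSums(da)
      dhd <- da %*% t(params$Wh)
      if (cell == "ode_rnn") {
        for (k in rev(seq_len(n_substeps))) {
          bk <- ode_rk4_step_backward(params, st$ode_sub[[k]], dhd, grads)
          dhd <- bk$dh0
          grads <- bk$grads
        }
        dh_prev <- dh_prev + dhd
      } else if (cell == "decay_rnn") {
        dgamma <- dhd * st$h_in
        dh_prev <- dh_prev + dhd * st$gamma
        dz <- -dgamma * st$gamma * (st$z_decay > 0)
        grads$w_gamma <- grads$w_gamma + colSums(dz * st$dt)
        grads$b_gamma <- grads$b_gamma + colSums(dz)
      } else {
        dh_prev <- dh_prev + dhd
      }
    }
    dh <- dh_prev
  }
  grads
}

# --- loss over sigmoid heads -------------------------------------------------

# Y: N x K targets in {0,1,NA}; w_pos/w_neg: per-head class weights (length K)
seq_loss <- function(params, batch, cell, n_substeps, Y, w_pos, w_neg,
                     with_grads = TRUE) {
  fw <- seq_forward_batch(params, batch, cell, n_substeps, with_cache = with_grads)
  n <- nrow(fw$h)
  logits <- fw$h %*% params$Wy + rowvec(params$by, n)
  p <- sigm(logits)
  Wt <- matrix(0, nrow(Y), ncol(Y))
  obs <- !is.na(Y)
  Y0 <- ifelse(obs, Y, 0)
  Wt[obs] <- ifelse(Y0[obs] == 1,
                    rowvec(w_pos, nrow(Y))[obs],
                    rowvec(w_neg, nrow(Y))[obs])
  norm <- sum(Wt)
  if (norm == 0) stopf("no observed targets in batch")
  pc <- clamp(p, 1e-7, 1 - 1e-7)
  loss <- -sum(Wt * (Y0 * log(pc) + (1 - Y0) * log(1 - pc))) / norm
  out <- list(loss = loss, probs = p, h = fw$h)
  if (with_grads) {
    dlogits <- Wt * (p - Y0) / norm
    grads <- seq_backward_batch(params, batch, cell, n_substeps, fw$caches,
                                dlogits %*% t(params$Wy))
    grads$Wy <- grads$Wy + t(fw$h) %*% dlogits
    grads$by <- grads$by + colSums(dlogits)
    out$grads <- grads
  }
  out
}

# --- optimizers --------------------------------------------------------------

clip_global_norm <- function(grads, max_norm) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(gn) && gn > max_norm) grads <- lapply(grads, function(g) g * (max_norm / gn))
  grads
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

sgd_init <- function(params) list(vel = zero_like(params))

sgd_update <- function(params, grads, state, lr, momentum = 0.9) {
  for (nm in names(params)) {
    state$vel[[nm]] <- momentum * state$vel[[nm]] - lr * grads[[nm]]
    params[[nm]] <- params[[nm]] + state$vel[[nm]]
  }
  list(params = params, state = state)
}
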