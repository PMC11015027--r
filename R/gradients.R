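#' Dampened pseudo-derivative of the spike function
#'
#' Surrogate derivative used in place of the non-differentiable Heaviside
#' spike: \code{gamma * max(0, 1 - |v_norm|)}, where
#' \code{v_norm = (V - A) / A} is the membrane potential normalised by the
#' current (possibly adaptive) threshold. The dampening factor
#' \code{gamma < 1} keeps backpropagated errors from growing across the
#' many time slices of the unrolled network.
#'
#' @param v_norm normalised membrane potential (any shape).
#' @param gamma dampening factor in (0, 1).
#' @return the derivative value, same shape.
#' @export
pseudo_derivative <- function(v_norm, gamma = 0.3) {
  gamma * pmax(0, 1 - abs(v_norm))
}

#' Reverse-mode gradients through the unrolled simulation
#'
#' Backpropagation through time over a recorded forward pass
#' (\code{\link{rsnn_forward}} with \code{record = TRUE}). Every spike
#' Heaviside is given the dampened pseudo-derivative
#' (\code{\link{pseudo_derivative}}, evaluated at
#' \code{v_norm = (V - A)/A} with the step's adaptive threshold \code{A});
#' the adaptation-variable recursion is differentiated exactly, with no
#' dampening. The refractory gate is treated as a non-differentiable
#' constant: the pseudo-derivative is zeroed while the neuron is
#' refractory. The subtractive reset uses the same spike node, so its
#' gradient flows through the same pseudo-derivative.
#'
#' @param net the \code{\link{rsnn_network}} that produced the record.
#' @param fwd recorded forward pass.
#' @param dZ upstream gradient of the loss w.r.t. the spikes, array
#'   \code{(n, B, T)} (from the readout adjoint and any firing-rate term).
#' @param dV_direct optional direct gradient w.r.t. the recorded membrane
#'   potential (same shape), for losses defined on potentials.
#' @return list of gradients \code{dW_in}, \code{dW_rec} (masked), and
#'   \code{dnu} when the record carries noise draws. All entries are finite
#'   or an error is raised.
#' @export
rsnn_backward <- function(net, fwd, dZ, dV_direct = NULL) {
  n <- net$n_rec; B <- fwd$B; TT <- fwd$T
  stopifnot(all(dim(dZ) == c(n, B, TT)))
  alpha <- net$params$alpha; one_m_alpha <- 1 - alpha
  rho <- net$adapt$rho; one_m_rho <- 1 - rho
  beta <- net$adapt$beta; vth <- net$params$v_th
  gamma <- net$gamma

  dZacc <- dZ                      # accumulates recurrent-path terms
  dVnext <- matrix(0, n, B)
  danext <- matrix(0, n, B)
  rec_groups <- net$rec_groups
  tW <- lapply(rec_groups, function(g) t(g$W))
  want_nu <- !is.null(fwd$noise) && !is.null(net$nu)
  # per-delay drive-gradient buffers, written pre-shifted so the weight
  # gradients below are plain full-matrix products (no giant slice copies)
  delays <- sort(unique(c(vapply(net$in_groups, `[[`, 0, "d"),
                          vapply(rec_groups, `[[`, 0, "d"))))
  DIS <- lapply(delays, function(d) matrix(0, n, B * TT))
  names(DIS) <- as.character(delays)
  DInu <- if (want_nu) matrix(0, n, B * TT) else NULL

  for (t in rev(seq_len(TT))) {
    dI <- one_m_alpha * dVnext
    for (di in seq_along(delays)) {
      s <- t - delays[di]
      if (s >= 1) DIS[[di]][, ((s - 1) * B + 1):(s * B)] <- dI
    }
    if (want_nu) DInu[, ((t - 1) * B + 1):(t * B)] <- dI
    for (gi in seq_along(rec_groups)) {
      d <- rec_groups[[gi]]$d
      if (t - d >= 1) {
        dZacc[, , t - d] <- dZacc[, , t - d] + tW[[gi]] %*% dI
      }
    }
    dz <- dZacc[, , t] - vth * dVnext + one_m_rho * danext
    A <- vth + beta * fwd$a[, , t]
    vnorm <- (fwd$V[, , t] - A) / A
    pd <- fwd$gate[, , t] * pseudo_derivative(vnorm, gamma)
    dV <- alpha * dVnext + dz * pd / A
    if (!is.null(dV_direct)) dV <- dV + dV_direct[, , t]
    da <- rho * danext + dz * pd * (-beta * fwd$V[, , t] / A^2)
    dVnext <- dV
    danext <- da
  }

  xf <- matrix(fwd$x, net$n_in, B * TT)
  zf <- matrix(fwd$z, n, B * TT)
  grad_for <- function(groups, pre, n_pre) {
    G <- matrix(0, n, n_pre)
    for (g in groups) {
      gd <- tcrossprod(DIS[[as.character(g$d)]], pre)
      G[g$sel] <- G[g$sel] + gd[g$sel]
    }
    G
  }
  dW_in <- grad_for(net$in_groups, xf, net$n_in) * net$mask_in
  dW_rec <- grad_for(net$rec_groups, zf, n) * net$mask_rec
  diag(dW_rec) <- 0
  out <- list(dW_in = dW_in, dW_rec = dW_rec)
  if (want_nu) {
    out$dnu <- net$w0 *
      rowSums(DInu * matrix(fwd$noise, n, B * TT))
  }
  if (!all(vapply(out, function(g) all(is.finite(g)), TRUE))) {
    stop_cfg("non-finite gradient in backpropagation through time")
  }
  out
}

#' Adjoint of the mean-rate readout
#'
#' Maps a gradient w.r.t. the per-window affine readout outputs back to
#' gradients w.r.t. spikes, readout weights and bias.
#'
#' @param dY gradient w.r.t. outputs, array \code{(n_out, B, K)} (or
#'   \code{n_out x K}).
#' @param fwd recorded forward pass (provides the spikes).
#' @param W_out readout weights.
#' @param window window length in steps.
#' @return list \code{dZ} (\code{(n, B, T)}), \code{dW_out}, \code{db}.
#' @export
mean_rate_adjoint <- function(dY, fwd, W_out, window = 20) {
  n <- dim(fwd$z)[1]; B <- fwd$B; TT <- fwd$T
  K <- TT %/% window
  if (is.matrix(dY)) dY <- array(dY, c(nrow(dY), 1, ncol(dY)))
  stopifnot(all(dim(dY) == c(nrow(W_out), B, K)))
  ind <- matrix(0, TT, K)
  ind[cbind(seq_len(TT), rep(seq_len(K), each = window))] <- 1
  feats <- (matrix(fwd$z, n * B, TT) %*% ind) / window    # (n*B) x K
  dYf <- matrix(dY, nrow(W_out), B * K)
  dW_out <- tcrossprod(dYf, matrix(array(feats, c(n, B, K)), n, B * K))
  db <- rowSums(dYf)
  dF <- crossprod(W_out, dYf)                              # n x (B*K)
  dFarr <- array(dF, c(n, B, K))
  # spread each window's feature gradient uniformly over its steps
  dZ <- dFarr[, , rep(seq_len(K), each = window), drop = FALSE] / window
  list(dZ = dZ, dW_out = dW_out, db = db)
}

#' Adjoint of the exponential-trace readout
#'
#' @param dY gradient w.r.t. the per-step outputs \code{(n_out, B, T)}.
#' @param fwd recorded forward pass.
#' @param W_out readout weights.
#' @param tau_trace kernel time constant (ms).
#' @param delta_t step (ms).
#' @return list \code{dZ}, \code{dW_out}, \code{db}.
#' @export
trace_adjoint <- function(dY, fwd, W_out, tau_trace, delta_t = 1) {
  n <- dim(fwd$z)[1]; B <- fwd$B; TT <- fwd$T
  if (is.matrix(dY)) dY <- array(dY, c(nrow(dY), 1, ncol(dY)))
  kap <- exp(-delta_t / tau_trace)
  # recompute traces (cheap, avoids storing them in the record)
  tr <- array(0, c(n, B, TT))
  prev <- matrix(0, n, B)
  for (t in seq_len(TT)) {
    prev <- kap * prev + fwd$z[, , t]
    tr[, , t] <- prev
  }
  dYf <- matrix(dY, nrow(W_out), B * TT)
  dW_out <- tcrossprod(dYf, matrix(tr, n, B * TT))
  db <- rowSums(dYf)
  dTr <- crossprod(W_out, dYf)             # n x (B*T)
  dTarr <- array(dTr, c(n, B, TT))
  dZ <- array(0, c(n, B, TT))
  snext <- matrix(0, n, B)
  for (t in rev(seq_len(TT))) {
    snext <- dTarr[, , t] + kap * snext
    dZ[, , t] <- snext
  }
  list(dZ = dZ, dW_out = dW_out, db = db)
}

#' Adjoint of the leaky-integrator (membrane-potential) readout
#'
#' The navigation task reads out through non-spiking leaky integrators
#' \code{y_t = kappa y_{t-1} + (1 - kappa)(W_out z_t + b)} with
#' \code{kappa = exp(-delta_t / tau_out)}.
#'
#' @inheritParams trace_adjoint
#' @param tau_out readout membrane time constant (ms).
#' @return list \code{dZ}, \code{dW_out}, \code{db}.
#' @export
leaky_readout_adjoint <- function(dY, fwd, W_out, tau_out = 20,
                                  delta_t = 1) {
  n <- dim(fwd$z)[1]; B <- fwd$B; TT <- fwd$T
  if (is.matrix(dY)) dY <- array(dY, c(nrow(dY), 1, ncol(dY)))
  kap <- exp(-delta_t / tau_out)
  # u_t = sum_{s >= t} kap^{s-t} dY_s  (reverse filter)
  U <- array(0, c(nrow(W_out), B, TT))
  unext <- matrix(0, nrow(W_out), B)
  for (t in rev(seq_len(TT))) {
    unext <- dY[, , t] + kap * unext
    U[, , t] <- unext
  }
  Uf <- matrix(U, nrow(W_out), B * TT)
  zf <- matrix(fwd$z, n, B * TT)
  dW_out <- (1 - kap) * tcrossprod(Uf, zf)
  db <- (1 - kap) * rowSums(Uf)
  dZf <- (1 - kap) * crossprod(W_out, Uf)
  list(dZ = array(dZf, c(n, B, TT)), dW_out = dW_out, db = db)
}

#' Leaky-integrator readout forward pass
#'
#' @param z spikes \code{(n, B, T)} (or n x T).
#' @param W_out readout weights; \code{b} bias.
#' @param tau_out time constant (ms); \code{delta_t} step (ms).
#' @return outputs array \code{(n_out, B, T)} (or matrix for B = 1 input).
#' @export
leaky_readout <- function(z, W_out, b = 0, tau_out = 20, delta_t = 1) {
  was_mat <- is.matrix(z)
  if (was_mat) z <- array(z, c(nrow(z), 1, ncol(z)))
  n <- dim(z)[1]; B <- dim(z)[2]; TT <- dim(z)[3]
  kap <- exp(-delta_t / tau_out)
  drive <- array(W_out %*% matrix(z, n, B * TT) + b,
                 c(nrow(W_out), B, TT))
  y <- array(0, dim(drive))
  prev <- matrix(0, nrow(W_out), B)
  for (t in seq_len(TT)) {
    prev <- kap * prev + (1 - kap) * drive[, , t]
    y[, , t] <- prev
  }
  if (was_mat) matrix(y, nrow(W_out), TT) else y
}

#' Gradient of the episode-average firing-rate penalty
#'
#' Returns the per-spike upstream gradient of
#' \code{coeff * (f_avg - f0)^2} with per-episode rates, ready to be added
#' to the readout's \code{dZ} before \code{\link{rsnn_backward}}.
#'
#' @param z spike array \code{(n, B, T)}.
#' @param f0 target rate (Hz); \code{coeff} penalty weight.
#' @param delta_t step (ms).
#' @param batch_mean divide by B (losses averaged over the batch).
#' @return array \code{(n, B, T)}.
#' @export
firing_reg_grad <- function(z, f0, coeff, delta_t = 1, batch_mean = TRUE) {
  n <- dim(z)[1]; B <- dim(z)[2]; TT <- dim(z)[3]
  secs <- TT * delta_t / 1000
  f_ep <- apply(z, 2, function(zz) sum(zz) / (n * secs))
  per_spike <- 2 * coeff * (f_ep - f0) / (n * secs)
  if (batch_mean) per_spike <- per_spike / B
  array(rep(rep(per_spike, each = n), TT), c(n, B, TT))
}

#' Full surrogate-gradient computation for a simulated episode batch
#'
#' Convenience wrapper: runs the forward pass, applies a readout-specific
#' loss adjoint, and backpropagates to all weight matrices. Used by the
#' outer-loop trainer and by the gradient-oracle tests.
#'
#' @param net an \code{\link{rsnn_network}}.
#' @param x input spike array \code{(n_in, B, T)}.
#' @param loss_fn function(fwd, net) returning list(loss, dZ, dV_direct
#'   (optional), dW_out, db) -- everything downstream of the spikes.
#' @param state optional initial state; \code{noise} optional draws.
#' @return list with \code{loss}, \code{grads} (dW_in, dW_rec, dW_out, db,
#'   and dnu if applicable) and the forward record \code{fwd}.
#' @export
unrolled_gradients <- function(net, x, loss_fn, state = NULL, noise = NULL) {
  fwd <- rsnn_forward(net, x, state = state, noise = noise, record = TRUE)
  parts <- loss_fn(fwd, net)
  core <- rsnn_backward(net, fwd, parts$dZ, parts$dV_direct)
  grads <- list(W_in = core$dW_in, W_rec = core$dW_rec,
                W_out = parts$dW_out, b_out = parts$db)
  if (!is.null(core$dnu)) grads$nu <- core$dnu
  list(loss = parts$loss, grads = grads, fwd = fwd, extra = parts$extra)
}
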