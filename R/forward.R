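#' Simulate a batch of episodes
#'
#' Vectorised discrete-time simulation of the recurrent network over a batch
#' of episodes. Equivalent, step for step, to iterating
#' \code{\link{network_step}} (the test suite checks bit-identity), but runs
#' the whole batch through BLAS per time step and records the trajectories
#' needed for backpropagation through time.
#'
#' @param net an \code{\link{rsnn_network}}.
#' @param x input spikes, array of dim \code{(n_in, B, T)} (a matrix is read
#'   as \code{(n_in, T)} with B = 1).
#' @param state optional initial \code{\link{rsnn_state}} (default: zeros).
#' @param noise optional standard-normal draws of dim \code{(n_rec, B, T)};
#'   scaled by the trainable per-neuron noise amplitude \code{net$nu} (in
#'   units of \code{w0}) and added to the synaptic current each step.
#' @param record if TRUE, return full trajectories (needed for gradients
#'   and probing); if FALSE only spikes and the final state.
#' @return list with \code{z} (spikes, \code{(n, B, T)}), and when recorded
#'   \code{V} (membrane potential at the spike decision), \code{a}
#'   (adaptation variable), \code{gate} (1 where the neuron was not
#'   refractory), plus \code{state} (final \code{rsnn_state}) and the
#'   episode length \code{T}.
#' @export
rsnn_forward <- function(net, x, state = NULL, noise = NULL, record = TRUE) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), 1, ncol(x)))
  n_in <- dim(x)[1]; B <- dim(x)[2]; TT <- dim(x)[3]
  if (n_in != net$n_in) stop_cfg("input width mismatch: got %d, expected %d",
                                 n_in, net$n_in)
  n <- net$n_rec
  alpha <- net$params$alpha; one_m_alpha <- 1 - alpha
  rho <- net$adapt$rho; one_m_rho <- 1 - rho
  beta <- net$adapt$beta; vth <- net$params$v_th
  n_ref <- net$params$n_ref

  if (is.null(state)) state <- rsnn_state(net, B)
  stopifnot(ncol(state$V) == B)

  # input currents for all steps at once (per delay group, shifted in time)
  xf <- matrix(x, n_in, B * TT)
  Iin <- matrix(0, n, B * TT)
  for (g in net$in_groups) {
    d <- g$d
    prod <- g$W %*% xf
    if (d < TT) {
      Iin[, (d * B + 1):(TT * B)] <-
        Iin[, (d * B + 1):(TT * B)] + prod[, 1:((TT - d) * B), drop = FALSE]
    }
    # spikes already sitting in the initial state's ring buffer
    bufdepth <- dim(state$in_buffer)[3]
    for (t in seq_len(min(d, TT))) {
      k <- d - t + 1  # buffer slot feeding step t
      if (k <= bufdepth) {
        Iin[, ((t - 1) * B + 1):(t * B)] <-
          Iin[, ((t - 1) * B + 1):(t * B)] + g$W %*% state$in_buffer[, , k]
      }
    }
  }

  use_noise <- !is.null(noise) && !is.null(net$nu)
  if (use_noise) {
    stopifnot(all(dim(noise) == c(n, B, TT)))
    nu_scale <- net$nu * net$w0
  }

  V <- state$V; a <- state$a; refrac <- state$refrac
  Z <- array(0, c(n, B, TT))
  rec_groups <- net$rec_groups
  rec_bufdepth <- dim(state$rec_buffer)[3]
  if (record) {
    Vrec <- array(0, c(n, B, TT))
    arec <- array(0, c(n, B, TT))
    gate <- array(0, c(n, B, TT))
  }

  for (t in seq_len(TT)) {
    I <- Iin[, ((t - 1) * B + 1):(t * B), drop = FALSE]
    for (g in rec_groups) {
      d <- g$d
      if (t - d >= 1) {
        I <- I + g$W %*% Z[, , t - d]
      } else {
        k <- d - t + 1
        if (k <= rec_bufdepth) I <- I + g$W %*% state$rec_buffer[, , k]
      }
    }
    if (use_noise) I <- I + nu_scale * noise[, , t]

    A <- vth + beta * a
    open <- refrac == 0L
    z <- (V > A) & open
    zd <- z + 0
    if (record) {
      Vrec[, , t] <- V; arec[, , t] <- a; gate[, , t] <- open + 0
    }
    Z[, , t] <- zd
    V <- alpha * V + one_m_alpha * I - vth * zd
    a <- rho * a + one_m_rho * zd
    refrac <- ifelse(z, n_ref, pmax(refrac - 1L, 0L))
  }
  if (!all(is.finite(V))) stop_cfg("non-finite membrane potential during episode")

  # final state incl. ring buffers rebuilt from the recorded tail
  fill_buf <- function(buf, spikes_arr, old_buf) {
    depth <- dim(buf)[3]
    for (k in seq_len(depth)) {
      tt <- TT - k + 1
      buf[, , k] <- if (tt >= 1) spikes_arr[, , tt] else old_buf[, , k - TT]
    }
    buf
  }
  st <- state
  st$V <- V; st$a <- a
  st$refrac <- matrix(as.integer(refrac), n, B)
  st$in_buffer <- fill_buf(state$in_buffer, x, state$in_buffer)
  st$rec_buffer <- fill_buf(state$rec_buffer, Z, state$rec_buffer)
  st$t <- state$t + as.integer(TT)

  out <- list(z = Z, state = st, T = TT, B = B)
  if (record) {
    out$V <- Vrec; out$a <- arec; out$gate <- gate
    out$x <- x
    if (use_noise) out$noise <- noise
  }
  out
}

#' Reconstruct the network state at an intermediate step of a recorded run
#'
#' Builds an \code{\link{rsnn_state}} equal to the simulator state just
#' before step \code{t + 1} of a recorded forward pass, i.e. after \code{t}
#' steps have been consumed. Used by the internal-model probe, which resumes
#' hypothetical simulations from stored snapshots without disturbing the
#' original episode.
#'
#' @param net the network the record came from.
#' @param fwd a recorded result of \code{\link{rsnn_forward}}.
#' @param t step index in 1..T (snapshot after this step).
#' @param b episode index within the batch.
#' @return an \code{\link{rsnn_state}} with batch 1.
#' @export
rsnn_snapshot <- function(net, fwd, t, b = 1) {
  stopifnot(!is.null(fwd$V), t >= 1, t <= fwd$T)
  n <- net$n_rec
  st <- rsnn_state(net, 1)
  # state after step t: replay the step-t update from the recorded arrays
  alpha <- net$params$alpha
  vth <- net$params$v_th
  Vt <- fwd$V[, b, t]; at <- fwd$a[, b, t]; zt <- fwd$z[, b, t]
  # recover the drive from the recorded transition
  Vnext <- if (t < fwd$T) fwd$V[, b, t + 1] else fwd$state$V[, b]
  anext <- if (t < fwd$T) fwd$a[, b, t + 1] else fwd$state$a[, b]
  st$V <- matrix(Vnext, n, 1)
  st$a <- matrix(anext, n, 1)
  refrac <- integer(n)
  # replay refractory counters from the recorded spikes
  cnt <- rep(0L, n)
  for (s in seq_len(t)) {
    cnt <- ifelse(fwd$z[, b, s] > 0, net$params$n_ref, pmax(cnt - 1L, 0L))
  }
  st$refrac <- matrix(as.integer(cnt), n, 1)
  for (k in seq_len(dim(st$in_buffer)[3])) {
    s <- t - k + 1
    if (s >= 1) st$in_buffer[, , k] <- fwd$x[, b, s]
  }
  for (k in seq_len(dim(st$rec_buffer)[3])) {
    s <- t - k + 1
    if (s >= 1) st$rec_buffer[, , k] <- fwd$z[, b, s]
  }
  st$t <- as.integer(t)
  st
}
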