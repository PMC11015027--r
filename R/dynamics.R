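#' Parameters of leaky integrate-and-fire neurons
#'
#' Container for the discrete-time LIF membrane parameters. Voltages are in
#' mV throughout the package; the synaptic drive \code{R_m * I} is stored
#' directly as a voltage so the membrane resistance never needs separate
#' bookkeeping (the weight scale \code{w0} absorbs it, see
#' \code{\link{rsnn_network}}).
#'
#' The decay factor \code{alpha = exp(-delta_t / tau_m)} is computed here and
#' must be recomputed whenever \code{tau_m} or \code{delta_t} changes; use
#' this constructor rather than editing fields.
#'
#' @param n number of neurons.
#' @param tau_m membrane time constant in ms (scalar or length-n).
#' @param v_th baseline firing threshold in mV (> 0).
#' @param tau_ref refractory period in ms (>= 0).
#' @param R_m membrane resistance (GOhm); kept for completeness, 1 by default.
#' @param delta_t simulation step in ms.
#' @return an object of class \code{neuron_params}.
#' @export
neuron_params <- function(n, tau_m = 20, v_th = 30, tau_ref = 5, R_m = 1,
                          delta_t = 1) {
  stopifnot(n >= 1, all(tau_m > 0), v_th > 0, tau_ref >= 0, delta_t > 0)
  tau_m <- rep_len(tau_m, n)
  alpha <- exp(-delta_t / tau_m)
  stopifnot(all(alpha > 0), all(alpha < 1))
  structure(list(n = as.integer(n), tau_m = tau_m, v_th = v_th,
                 tau_ref = tau_ref, R_m = R_m, delta_t = delta_t,
                 alpha = alpha,
                 n_ref = as.integer(ceiling(tau_ref / delta_t))),
            class = "neuron_params")
}

#' Parameters of the spike-frequency-adaptation threshold
#'
#' Each spike increments the adaptation variable \code{a}, which decays
#' geometrically with factor \code{rho = exp(-delta_t / tau_a)}; the
#' effective threshold is \code{A = v_th + beta * a}. Setting \code{beta = 0}
#' recovers the plain LIF neuron exactly.
#'
#' @param n number of neurons.
#' @param beta threshold amplitude in mV (>= 0; scalar or length-n).
#' @param tau_a adaptation time constant in ms (> 0; scalar or length-n).
#' @param delta_t simulation step in ms.
#' @return an object of class \code{adaptation_params}.
#' @export
adaptation_params <- function(n, beta = 0, tau_a = 1000, delta_t = 1) {
  stopifnot(n >= 1, all(beta >= 0), all(tau_a > 0), delta_t > 0)
  beta <- rep_len(beta, n)
  tau_a <- rep_len(tau_a, n)
  rho <- exp(-delta_t / tau_a)
  stopifnot(all(rho > 0), all(rho < 1))
  structure(list(n = as.integer(n), beta = beta, tau_a = tau_a, rho = rho,
                 delta_t = delta_t),
            class = "adaptation_params")
}

#' Initialise the dynamic state of a network
#'
#' Membrane potentials, adaptation variables and refractory counters start
#' at zero; the delay ring buffers are empty (all zeros) and exactly deep
#' enough for the largest synaptic delay.
#'
#' @param net an \code{\link{rsnn_network}}.
#' @param batch number of independent episodes simulated in parallel.
#' @return an object of class \code{rsnn_state}: fields \code{V}, \code{a},
#'   \code{refrac} (n x batch), and ring buffers \code{in_buffer},
#'   \code{rec_buffer} with column block k holding the spikes of step t-k.
#' @export
rsnn_state <- function(net, batch = 1) {
  n <- net$n_rec
  d_in_max <- max(net$d_in)
  d_rec_max <- max(net$d_rec)
  structure(list(
    V = matrix(0, n, batch),
    a = matrix(0, n, batch),
    refrac = matrix(0L, n, batch),
    in_buffer = array(0, c(net$n_in, batch, d_in_max)),
    rec_buffer = array(0, c(n, batch, d_rec_max)),
    t = 0L
  ), class = "rsnn_state")
}

#' Synaptic input current from buffered spikes
#'
#' Computes the voltage-equivalent drive
#' \code{I_j = sum_i W_in[j,i] x_i(t - d_in[j,i]) +
#'             sum_i W_rec[j,i] z_i(t - d_rec[j,i])}
#' from the delay ring buffers of a state. Masked-out (zero) weights
#' contribute nothing; self-connections in \code{W_rec} are zero by
#' construction of the network. Delays are at least 1 step, so only strictly
#' past spikes enter.
#'
#' @param state an \code{\link{rsnn_state}} whose buffers hold spikes up to
#'   step t-1.
#' @param net an \code{\link{rsnn_network}} (weights and integer delays).
#' @return an n x batch matrix of currents.
#' @export
synaptic_current <- function(state, net) {
  if (max(net$d_in) > dim(state$in_buffer)[3] ||
      max(net$d_rec) > dim(state$rec_buffer)[3]) {
    stop_cfg("synaptic delay exceeds ring-buffer depth")
  }
  batch <- ncol(state$V)
  I <- matrix(0, net$n_rec, batch)
  for (g in net$in_groups) {
    I <- I + g$W %*% state$in_buffer[, , g$d, drop = FALSE][, , 1]
  }
  for (g in net$rec_groups) {
    I <- I + g$W %*% state$rec_buffer[, , g$d, drop = FALSE][, , 1]
  }
  I
}

#' One membrane-potential update
#'
#' Discrete-time leak-and-integrate step with subtractive reset:
#' \code{V' = alpha V + (1 - alpha) R_m I - v_th z}. The reset magnitude is
#' the fixed baseline threshold \code{v_th}, also for adaptive-threshold
#' neurons (see the methods vignette for the rationale).
#'
#' @param V membrane potential (mV), vector or matrix.
#' @param I input current for this step (voltage-equivalent, same shape).
#' @param params a \code{\link{neuron_params}}.
#' @param z spikes emitted at this step (0/1, same shape as V).
#' @return updated membrane potential.
#' @export
membrane_step <- function(V, I, params, z) {
  V2 <- params$alpha * V + (1 - params$alpha) * (params$R_m * I) -
    params$v_th * z
  if (!all(is.finite(V2))) stop_cfg("non-finite membrane potential")
  V2
}

#' One adaptation-threshold update
#'
#' \code{a' = rho a + (1 - rho) z}; effective threshold
#' \code{A' = v_th + beta a'}. With \code{beta = 0} the threshold is
#' constantly \code{v_th}.
#'
#' @param a adaptation variable (dimensionless, >= 0).
#' @param z spikes at this step (0/1).
#' @param params an \code{\link{adaptation_params}}.
#' @param v_th baseline threshold (mV).
#' @return list with updated \code{a} and threshold \code{A}.
#' @export
threshold_step <- function(a, z, params, v_th) {
  a2 <- params$rho * a + (1 - params$rho) * z
  list(a = a2, A = v_th + params$beta * a2)
}

#' Spike decision and refractory gating
#'
#' A neuron spikes iff its refractory counter is zero and \code{V > A}
#' strictly (Heaviside with H(0) = 0). A spike reloads the counter to
#' \code{ceiling(tau_ref / delta_t)} steps; otherwise the counter counts
#' down. While the counter is positive the spike is forced to 0 but the
#' membrane keeps integrating.
#'
#' @param V membrane potential.
#' @param A effective threshold (same shape).
#' @param refrac integer refractory counters (same shape).
#' @param params a \code{\link{neuron_params}}.
#' @return list with binary \code{z} and updated \code{refrac}.
#' @export
spike_and_refractory <- function(V, A, refrac, params) {
  open <- refrac == 0L
  z <- (V > A) & open
  refrac2 <- ifelse(z, params$n_ref, pmax(refrac - 1L, 0L))
  storage.mode(refrac2) <- "integer"
  list(z = z + 0, refrac = refrac2)
}

#' Advance the network by one time step
#'
#' Composes the per-step operations in a fixed order: (1) synaptic currents
#' from the buffered past spikes, (2) spike decision from the current
#' membrane potential against the current adaptive threshold, (3) membrane
#' update using that spike (subtractive reset), (4) adaptation update with
#' the new spikes, (5) push the new input and recurrent spikes into the ring
#' buffers. Deterministic given state and input.
#'
#' @param state an \code{\link{rsnn_state}}.
#' @param x_t input spikes at this step (n_in vector or n_in x batch matrix).
#' @param net an \code{\link{rsnn_network}}.
#' @param extra_current optional additional voltage-equivalent drive
#'   (n x batch), e.g. exploration noise.
#' @return list with the updated \code{state} and the emitted spikes
#'   \code{z} (n x batch).
#' @export
network_step <- function(state, x_t, net, extra_current = NULL) {
  batch <- ncol(state$V)
  x_t <- matrix(x_t, net$n_in, batch)
  if (nrow(x_t) != net$n_in) stop_cfg("input width mismatch")

  I <- synaptic_current(state, net)
  if (!is.null(extra_current)) I <- I + extra_current

  A <- net$params$v_th + net$adapt$beta * state$a
  sp <- spike_and_refractory(state$V, A, state$refrac, net$params)
  z <- sp$z
  state$V <- membrane_step(state$V, I, net$params, z)
  state$a <- threshold_step(state$a, z, net$adapt, net$params$v_th)$a
  state$refrac <- sp$refrac

  # ring-buffer push: newest spikes at slice 1
  di <- dim(state$in_buffer)[3]
  if (di > 1) state$in_buffer[, , 2:di] <- state$in_buffer[, , 1:(di - 1)]
  state$in_buffer[, , 1] <- x_t
  dr <- dim(state$rec_buffer)[3]
  if (dr > 1) state$rec_buffer[, , 2:dr] <- state$rec_buffer[, , 1:(dr - 1)]
  state$rec_buffer[, , 1] <- z
  state$t <- state$t + 1L

  list(state = state, z = z)
}
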