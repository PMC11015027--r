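#' Gaussian population-code specification
#'
#' A scalar value is represented by the firing rates of \code{n_neurons}
#' units with Gaussian tuning curves whose preferred values are evenly
#' spaced over \code{[value_min, value_max]}.
#'
#' @param n_neurons number of units.
#' @param value_min,value_max encoded range (preferred values span it).
#' @param r_max peak rate in Hz.
#' @param sigma tuning width, in the units of the encoded value.
#' @return an object of class \code{population_code}.
#' @export
population_code <- function(n_neurons, value_min, value_max, r_max = 200,
                            sigma = (value_max - value_min) / 1000) {
  stopifnot(value_min < value_max, r_max > 0, sigma > 0, n_neurons >= 1)
  structure(list(n_neurons = as.integer(n_neurons), value_min = value_min,
                 value_max = value_max, r_max = r_max, sigma = sigma,
                 preferred = seq(value_min, value_max,
                                 length.out = n_neurons)),
            class = "population_code")
}

#' Population firing rates for a value
#'
#' \code{r_i = r_max exp(-(m_i - value)^2 / (2 sigma^2))}. Values outside
#' the encoded range are allowed; the rates simply decay with distance from
#' the nearest preferred value (no clipping). Shifting the value and all
#' centres by the same constant leaves the rates unchanged.
#'
#' @param value scalar or vector of values to encode.
#' @param spec a \code{\link{population_code}}.
#' @return a matrix \code{n_neurons x length(value)} of rates in Hz.
#' @export
population_rates <- function(value, spec) {
  stopifnot(all(is.finite(value)))
  d <- outer(spec$preferred, value, "-")
  spec$r_max * exp(-d^2 / (2 * spec$sigma^2))
}

#' Place-cell code for maze coordinates
#'
#' The navigation task encodes each position coordinate \code{xi in [-1,1]}
#' with 40 units at rate \code{r_max exp(-100 (xi_i - xi)^2)}, peak 500 Hz.
#' The exponent is used exactly as stated (equivalent to sigma ~ 0.0707).
#'
#' @param n_neurons units per coordinate.
#' @param r_max peak rate (Hz).
#' @return a \code{\link{population_code}} whose rates use the fixed
#'   exponent -100 (sigma = sqrt(1/200)).
#' @export
maze_position_code <- function(n_neurons = 40, r_max = 500) {
  population_code(n_neurons, -1, 1, r_max = r_max, sigma = sqrt(1 / 200))
}

#' Sample spike trains from rates
#'
#' Independent Bernoulli draw per time step with
#' \code{p = min(rate * delta_t, 1)} (rates in Hz, \code{delta_t} in ms).
#' With 1 ms steps and rates up to 500 Hz this is practically identical to
#' Poisson sampling while keeping the spike tensor binary.
#'
#' @param rates vector (one rate per neuron) or matrix
#'   \code{n_neurons x n_windows} of rates in Hz; each window spans
#'   \code{duration_steps} steps.
#' @param duration_steps steps per window.
#' @param delta_t step length in ms.
#' @param seed integer seed (deterministic given the seed).
#' @return binary matrix \code{n_neurons x (n_windows * duration_steps)}.
#' @export
rates_to_spikes <- function(rates, duration_steps, delta_t = 1, seed = NULL) {
  stopifnot(all(rates >= 0))
  if (is.vector(rates)) rates <- matrix(rates, ncol = 1)
  p <- pmin(rates * delta_t / 1000, 1)
  n <- nrow(rates); K <- ncol(rates)
  # expand window probabilities to per-step: (n, duration, K)
  pfull <- aperm(array(p, c(n, K, duration_steps)), c(1, 3, 2))
  with_seed(seed, {
    u <- array(stats::runif(n * duration_steps * K), c(n, duration_steps, K))
    matrix((u < pfull) + 0, n, duration_steps * K)
  })
}

#' Spike encoding of a bit vector
#'
#' Each bit is represented by 5 neurons firing at 200 Hz when the bit is 1
#' and at a 2 Hz background rate when it is 0.
#'
#' @param bits binary vector.
#' @param duration_steps presentation length in steps (1 ms each).
#' @param seed integer seed.
#' @param rate_hi,rate_lo rates (Hz) for 1- and 0-bits.
#' @param per_bit neurons per bit.
#' @return binary matrix \code{(per_bit * length(bits)) x duration_steps}.
#' @export
bit_pattern_spikes <- function(bits, duration_steps, seed = NULL,
                               rate_hi = 200, rate_lo = 2, per_bit = 5) {
  stopifnot(all(bits %in% c(0, 1)))
  rates <- rep(ifelse(bits == 1, rate_hi, rate_lo), each = per_bit)
  rates_to_spikes(rates, duration_steps, seed = seed)
}

#' Spike encoding of instantaneous reward
#'
#' Two groups of 40 neurons: the first spikes in synchrony whenever a
#' reward of +1 is delivered (goal reached), the second whenever the wall
#' penalty of -0.02 is delivered; otherwise all are silent.
#'
#' @param reward_value one of 0, +1, -0.02.
#' @param group_size neurons per group.
#' @return binary vector of length \code{2 * group_size} (one time step).
#' @export
reward_spikes <- function(reward_value, group_size = 40) {
  z <- numeric(2 * group_size)
  if (reward_value > 0) {
    z[seq_len(group_size)] <- 1
  } else if (reward_value < 0) {
    z[group_size + seq_len(group_size)] <- 1
  }
  z
}

#' Mean-firing-rate readout over fixed windows
#'
#' The per-neuron feature of a window is its spike count divided by the
#' window length (20 steps of 1 ms by default); the output is an affine
#' readout of the feature vector.
#'
#' @param z spikes: matrix \code{n x T} or array \code{(n, B, T)} with T a
#'   multiple of \code{window}.
#' @param W_out readout weights \code{n_out x n}; \code{b} bias.
#' @param window window length in steps.
#' @return list with \code{features} (\code{n x K} or \code{(n, B, K)}) and
#'   \code{y} (outputs per window, \code{n_out x K} or \code{(n_out, B, K)}).
#' @export
mean_rate_decode <- function(z, W_out, b = 0, window = 20) {
  if (is.matrix(z)) z <- array(z, c(nrow(z), 1, ncol(z)))
  n <- dim(z)[1]; B <- dim(z)[2]; TT <- dim(z)[3]
  stopifnot(TT %% window == 0)
  K <- TT %/% window
  ind <- matrix(0, TT, K)
  ind[cbind(seq_len(TT), rep(seq_len(K), each = window))] <- 1
  counts <- matrix(z, n * B, TT) %*% ind     # (n*B) x K, one BLAS call
  feats <- array(counts / window, c(n, B, K))
  yf <- W_out %*% matrix(feats, n, B * K) + b
  y <- array(yf, c(nrow(W_out), B, K))
  if (B == 1) {
    list(features = matrix(feats, n, K), y = matrix(y, nrow(W_out), K))
  } else {
    list(features = feats, y = y)
  }
}

#' Exponential-trace readout
#'
#' Each neuron's spike train is low-pass filtered by the recursion
#' \code{trace(t) = trace(t - dt) exp(-dt / tau) + z(t)} (equivalently a
#' convolution with a causal exponential kernel); the output is an affine
#' readout of the traces at every step.
#'
#' @param z spikes: matrix \code{n x T} or array \code{(n, B, T)}.
#' @param tau_trace kernel time constant in ms.
#' @param W_out readout weights \code{n_out x n}; \code{b} bias.
#' @param delta_t step in ms.
#' @return list with \code{traces} (same shape as z) and \code{y}
#'   (\code{n_out x T} or \code{(n_out, B, T)}).
#' @export
trace_decode <- function(z, tau_trace, W_out, b = 0, delta_t = 1) {
  stopifnot(tau_trace > 0)
  if (is.matrix(z)) z <- array(z, c(nrow(z), 1, ncol(z)))
  n <- dim(z)[1]; B <- dim(z)[2]; TT <- dim(z)[3]
  kap <- exp(-delta_t / tau_trace)
  tr <- array(0, c(n, B, TT))
  prev <- matrix(0, n, B)
  for (t in seq_len(TT)) {
    prev <- kap * prev + z[, , t]
    tr[, , t] <- prev
  }
  yf <- W_out %*% matrix(tr, n, B * TT) + b
  y <- array(yf, c(nrow(W_out), B, TT))
  if (B == 1) {
    list(traces = matrix(tr, n, TT), y = matrix(y, nrow(W_out), TT))
  } else {
    list(traces = tr, y = y)
  }
}

#' Stochastic policy head for the navigation task
#'
#' Maps the five readout potentials to the action distribution and value
#' estimate: means \code{mu = tanh(y[1:2])}, variances
#' \code{phi = sigmoid(y[3:4])}, value \code{V = y[5]}. Actions are sampled
#' coordinate-wise Gaussian; the velocity applied to the agent is
#' \code{a_scale * a}, clipped to Euclidean norm \code{a_scale}.
#'
#' @param y readout potentials: length-5 vector or 5 x m matrix.
#' @param a_scale velocity scale.
#' @param sample if TRUE also sample actions (consumes RNG).
#' @return list with \code{mu} (2 x m), \code{phi} (2 x m), \code{value}
#'   (length m), and when sampled \code{action} (2 x m), \code{velocity}
#'   (2 x m, clipped), \code{logp} (length m).
#' @export
policy_decode <- function(y, a_scale = 0.02, sample = TRUE) {
  y <- matrix(y, nrow = 5)
  mu <- tanh(y[1:2, , drop = FALSE])
  phi <- 1 / (1 + exp(-y[3:4, , drop = FALSE]))
  value <- y[5, ]
  out <- list(mu = mu, phi = phi, value = value)
  if (sample) {
    eps <- matrix(stats::rnorm(2 * ncol(y)), 2)
    action <- mu + sqrt(phi) * eps
    nrm <- sqrt(colSums(action^2))
    shrink <- pmin(1, 1 / pmax(nrm, 1e-300))
    velocity <- a_scale * action * rep(shrink, each = 2)
    out$action <- action
    out$velocity <- velocity
    out$logp <- gaussian_logp(action, mu, phi)
  }
  out
}

#' @keywords internal
gaussian_logp <- function(action, mu, phi) {
  colSums(-0.5 * log(2 * pi * phi) - (action - mu)^2 / (2 * phi))
}

#' @keywords internal
gaussian_entropy <- function(phi) {
  colSums(0.5 * log(2 * pi * exp(1) * phi))
}
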