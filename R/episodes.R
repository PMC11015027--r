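# Episode builders: sample tasks, generate analog streams, encode to spikes.
# These produce the (n_in, B, T) input arrays consumed by rsnn_forward().

#' Default input codes for the sinusoid task
#'
#' Both the input x and the feedback value use a 100-neuron Gaussian
#' population code over [-5, 5] with peak rate 200 Hz; the feedback range
#' covers the largest amplitude. The tuning width is (range)/100, i.e.
#' about one centre spacing, so every value drives a couple of neurons
#' appreciably (see the methods vignette for this choice).
#' @param n_neurons neurons per channel.
#' @return list of two \code{\link{population_code}}s (\code{x}, \code{y}).
#' @export
sinusoid_codes <- function(n_neurons = 100) {
  list(x = population_code(n_neurons, -5, 5, r_max = 200, sigma = 0.1),
       y = population_code(n_neurons, -5, 5, r_max = 200, sigma = 0.1))
}

#' Encode a batch of sinusoid episodes
#'
#' @param tasks list of B \code{sinusoid_task}s.
#' @param K steps per episode (20 ms each).
#' @param codes from \code{\link{sinusoid_codes}}.
#' @param step_ms step length in ms.
#' @param seed integer seed (episode content and spike sampling).
#' @return list: \code{x} input spike array \code{(2 n_code, B, K step_ms)},
#'   \code{targets} and \code{xs} (K x B matrices).
#' @export
sinusoid_episode_batch <- function(tasks, K = 500, codes = sinusoid_codes(),
                                   step_ms = 20, seed = NULL) {
  B <- length(tasks)
  nx <- codes$x$n_neurons; ny <- codes$y$n_neurons
  with_seed(seed, {
    xs <- matrix(stats::runif(K * B, -5, 5), K, B)
    targets <- vapply(seq_len(B), function(b) tasks[[b]]$f(xs[, b]),
                      numeric(K))
    targets <- matrix(targets, K, B)
    feedback <- rbind(0, targets[-K, , drop = FALSE])
    # rates for all (step, episode) at once
    rx <- population_rates(as.vector(xs), codes$x)        # nx x (K*B)
    ry <- population_rates(as.vector(feedback), codes$y)  # ny x (K*B)
    rates <- rbind(rx, ry)                                # (nx+ny) x (K*B)
    sp <- rates_to_spikes(rates, step_ms)                 # rows x (K*B*step_ms)
    # reorder: column blocks are (k, b) pairs with k fastest; target layout
    # is (n_in, B, K*step_ms)
    sp <- array(sp, c(nx + ny, step_ms, K, B))
    x <- aperm(sp, c(1, 4, 2, 3))         # n, B, ms-in-step, k
    dim(x) <- c(nx + ny, B, step_ms * K)
    list(x = x, targets = targets, xs = xs, feedback = feedback)
  })
}

#' Encode a single value sequence as one probe step
#'
#' Helper for the internal-model probe: spikes for one 20 ms presentation of
#' input value \code{x} with silent feedback channel.
#' @keywords internal
sinusoid_probe_input <- function(x_value, codes = sinusoid_codes(),
                                 step_ms = 20, seed = NULL) {
  rx <- population_rates(x_value, codes$x)
  sp_x <- rates_to_spikes(rx, step_ms, seed = seed)
  rbind(sp_x, matrix(0, codes$y$n_neurons, step_ms))
}

#' Default input codes for the arm task
#'
#' Torques are encoded over their sampling range; joint-angle feedback over
#' [-2 pi, 2 pi] (values drifting outside are still defined, their rates
#' just decay).
#' @param n_neurons neurons per channel.
#' @param torque_max torque bound used by \code{\link{torque_sequence}}.
#' @return list of four \code{\link{population_code}}s
#'   (\code{phi1}, \code{phi2}, \code{c1}, \code{c2}).
#' @export
arm_codes <- function(n_neurons = 100, torque_max = 5) {
  ang <- function() population_code(n_neurons, -2 * pi, 2 * pi, r_max = 200)
  trq <- function() population_code(n_neurons, -torque_max, torque_max,
                                    r_max = 200)
  list(phi1 = ang(), phi2 = ang(), c1 = trq(), c2 = trq())
}

#' Encode a batch of arm episodes
#'
#' Simulates each sampled arm under a fresh random torque sequence and
#' encodes, per ms: the joint-angle feedback delayed by
#' \code{feedback_delay_ms} (silent for the first delay window) and the
#' current motor command.
#'
#' @param arms list of B \code{arm_task}s.
#' @param duration_ms episode length.
#' @param codes from \code{\link{arm_codes}}.
#' @param feedback_delay_ms sensory feedback delay.
#' @param seed integer seed.
#' @return list: \code{x} spike array \code{(4 n_code, B, T)},
#'   \code{targets} angle array \code{(2, B, T)}, \code{torques}
#'   \code{(2, B, T)}.
#' @export
arm_episode_batch <- function(arms, duration_ms = 30000, codes = arm_codes(),
                              feedback_delay_ms = 100, seed = NULL) {
  B <- length(arms)
  nc <- codes$phi1$n_neurons
  with_seed(seed, {
    x <- array(0, c(4 * nc, B, duration_ms))
    targets <- array(0, c(2, B, duration_ms))
    torques <- array(0, c(2, B, duration_ms))
    for (b in seq_len(B)) {
      tq <- torque_sequence(duration_ms)
      st <- arm_trajectory(arms[[b]], tq)
      targets[, b, ] <- st[1:2, ]
      torques[, b, ] <- tq
      fb <- cbind(matrix(NA, 2, feedback_delay_ms),
                  st[1:2, seq_len(duration_ms - feedback_delay_ms),
                     drop = FALSE])
      enc <- function(vals, code) {
        r <- matrix(0, nc, duration_ms)
        ok <- !is.na(vals)
        if (any(ok)) r[, ok] <- population_rates(vals[ok], code)
        rates_to_spikes(r, 1)
      }
      x[, b, ] <- rbind(enc(fb[1, ], codes$phi1),
                        enc(fb[2, ], codes$phi2),
                        enc(tq[1, ], codes$c1),
                        enc(tq[2, ], codes$c2))
    }
    list(x = x, targets = targets, torques = torques)
  })
}

#' Encode a batch of pattern episodes as spike streams
#'
#' Lays out the four phases on the time axis (items of \code{item_ms} each):
#' A = full patterns, B = partials, C = delete cue, D = partials again. The
#' input has \code{5 * 25} pattern neurons plus \code{5 * 3} cue neurons;
#' bits at 0 fire at the 2 Hz background rate throughout.
#'
#' @param episodes list of B \code{pattern_task}s.
#' @param seed integer seed for spike sampling.
#' @return list: \code{x} spike array \code{(140, B, T)}, \code{windows}
#'   data frame of phase/item time windows, \code{T} episode length.
#' @export
pattern_episode_batch <- function(episodes, seed = NULL) {
  B <- length(episodes)
  ep1 <- episodes[[1]]
  nb <- ep1$n_bits; np <- ep1$n_patterns; ms <- ep1$item_ms
  n_pat_neurons <- 5 * nb; n_cue_neurons <- 5 * np
  TT <- (3 * np + 1) * ms
  segs <- data.frame(
    phase = c(rep("A", np), rep("B", np), "C", rep("D", np)),
    item = c(seq_len(np), seq_len(np), NA, seq_len(np))
  )
  segs$t0 <- (seq_len(nrow(segs)) - 1) * ms + 1
  segs$t1 <- segs$t0 + ms - 1
  with_seed(seed, {
    x <- array(0, c(n_pat_neurons + n_cue_neurons, B, TT))
    for (b in seq_len(B)) {
      ep <- episodes[[b]]
      for (s in seq_len(nrow(segs))) {
        idx <- segs$t0[s]:segs$t1[s]
        pat_bits <- switch(segs$phase[s],
                           A = ep$patterns[segs$item[s], ],
                           B = ,
                           D = ep$partials[segs$item[s], ],
                           C = rep(0, nb))
        cue_bits <- if (segs$phase[s] == "C") {
          as.numeric(seq_len(np) == ep$delete_index)
        } else rep(0, np)
        x[, b, idx] <- rbind(bit_pattern_spikes(pat_bits, ms),
                             bit_pattern_spikes(cue_bits, ms))
      }
    }
    list(x = x, windows = segs, T = TT)
  })
}

#' Per-step maze input encoding
#'
#' Concatenates the place-cell codes of the x and y coordinates with the
#' reward spike groups.
#' @param position length-2 agent position.
#' @param reward instantaneous reward being signalled.
#' @param code a \code{\link{maze_position_code}}.
#' @param seed integer seed for the rate sampling.
#' @return binary input vector of length \code{2 n_code + 80} (one step).
#' @export
maze_input_step <- function(position, reward, code = maze_position_code(),
                            seed = NULL) {
  r <- rbind(population_rates(position[1], code),
             population_rates(position[2], code))
  sp <- rates_to_spikes(r, 1, seed = seed)
  c(sp, reward_spikes(reward))
}
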