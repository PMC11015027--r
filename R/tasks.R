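#' Sample a sinusoid regression task
#'
#' One task is a target function \code{y = A sin(phi + x)} over
#' \code{x in [-5, 5]} with amplitude \code{A ~ U[0.1, 5]} and phase
#' \code{phi ~ U[0, pi]}.
#'
#' @param seed integer seed (NULL: use the current RNG stream).
#' @return an object of class \code{sinusoid_task} with fields \code{A},
#'   \code{phi}, \code{domain}, and the target function \code{f}.
#' @export
sample_sinusoid_task <- function(seed = NULL) {
  with_seed(seed, {
    A <- stats::runif(1, 0.1, 5)
    phi <- stats::runif(1, 0, pi)
    structure(list(A = A, phi = phi, domain = c(-5, 5),
                   f = local({
                     A0 <- A; p0 <- phi
                     function(x) A0 * sin(p0 + x)
                   })),
              class = "sinusoid_task")
  })
}

#' Build one sinusoid regression episode
#'
#' A sequence of K steps; at step k the network sees a fresh input
#' \code{x^k ~ U[-5, 5]} together with the delayed feedback
#' \code{y^{k-1} = A sin(phi + x^{k-1})} (0 at the first step), and must
#' predict \code{y^k}. Only the analog values are generated here; spike
#' encoding is applied by the episode encoder.
#'
#' @param task a \code{\link{sample_sinusoid_task}} result.
#' @param K number of steps.
#' @param seed integer seed.
#' @return list with vectors \code{x}, \code{target} (\code{y^k}) and
#'   \code{feedback} (\code{y^{k-1}}, leading 0).
#' @export
regression_episode <- function(task, K = 500, seed = NULL) {
  with_seed(seed, {
    x <- stats::runif(K, task$domain[1], task$domain[2])
    y <- task$f(x)
    list(x = x, target = y, feedback = c(0, y[-K]))
  })
}

# ---------------------------------------------------------------- two-link arm

#' Sample a two-link arm
#'
#' Link masses and lengths drawn uniformly from [0.5, 2] (kg, m). The arm is
#' a planar double pendulum with point masses at the link ends, under
#' gravity, driven by torques at both joints.
#'
#' @param seed integer seed.
#' @return an object of class \code{arm_task}.
#' @export
sample_arm_task <- function(seed = NULL) {
  with_seed(seed, {
    p <- stats::runif(4, 0.5, 2)
    structure(list(m1 = p[1], m2 = p[2], l1 = p[3], l2 = p[4], g = 9.81),
              class = "arm_task")
  })
}

#' Piecewise-constant random torque sequence
#'
#' Torques are refreshed every \code{block_ms} (10 ms) and held constant in
#' between; each block is drawn i.i.d. uniform in
#' \code{[-torque_max, torque_max]} per joint.
#'
#' @param duration_ms episode length in ms.
#' @param block_ms refresh interval in ms.
#' @param torque_max torque bound (N m).
#' @param seed integer seed.
#' @return a \code{2 x duration_ms} matrix of torques (one column per ms).
#' @export
torque_sequence <- function(duration_ms, block_ms = 10, torque_max = 5,
                            seed = NULL) {
  n_blocks <- ceiling(duration_ms / block_ms)
  with_seed(seed, {
    blocks <- matrix(stats::runif(2 * n_blocks, -torque_max, torque_max),
                     2, n_blocks)
    blocks[, rep(seq_len(n_blocks), each = block_ms)[seq_len(duration_ms)],
           drop = FALSE]
  })
}

#' Arm dynamics: accelerations from state and torque
#'
#' Planar two-link rigid-body dynamics with point masses at the distal ends:
#' \code{M(q) qdd + C(q, qd) + G(q) = torque}. Angles are measured from the
#' hanging (downward) vertical, \code{phi2} relative to link 1, and are
#' never wrapped.
#' @keywords internal
arm_accel <- function(state, torque, arm) {
  p1 <- state[1]; p2 <- state[2]; w1 <- state[3]; w2 <- state[4]
  m1 <- arm$m1; m2 <- arm$m2; l1 <- arm$l1; l2 <- arm$l2; g <- arm$g
  c2 <- cos(p2); s2 <- sin(p2)
  M11 <- (m1 + m2) * l1^2 + m2 * l2^2 + 2 * m2 * l1 * l2 * c2
  M12 <- m2 * l2^2 + m2 * l1 * l2 * c2
  M22 <- m2 * l2^2
  C1 <- -m2 * l1 * l2 * s2 * (2 * w1 * w2 + w2^2)
  C2 <- m2 * l1 * l2 * s2 * w1^2
  G1 <- g * ((m1 + m2) * l1 * sin(p1) + m2 * l2 * sin(p1 + p2))
  G2 <- g * m2 * l2 * sin(p1 + p2)
  rhs1 <- torque[1] - C1 - G1
  rhs2 <- torque[2] - C2 - G2
  det <- M11 * M22 - M12 * M12
  qdd1 <- (M22 * rhs1 - M12 * rhs2) / det
  qdd2 <- (M11 * rhs2 - M12 * rhs1) / det
  c(w1, w2, qdd1, qdd2)
}

#' One integration step of the two-link arm
#'
#' Advances the state \code{(phi1, phi2, omega1, omega2)} by
#' \code{dt_physics} seconds of classical Runge-Kutta (RK4) under a constant
#' torque. With zero torque the system is conservative; energy drift is a
#' test oracle.
#'
#' @param state numeric length 4: angles (rad, unwrapped) and angular
#'   velocities (rad/s).
#' @param torque length-2 joint torques (N m).
#' @param arm an \code{\link{sample_arm_task}} result.
#' @param dt_physics integration step in seconds (default 1 ms).
#' @return the next state (length 4).
#' @export
arm_dynamics_step <- function(state, torque, arm, dt_physics = 1e-3) {
  if (!all(is.finite(state))) stop_cfg("non-finite arm state")
  k1 <- arm_accel(state, torque, arm)
  k2 <- arm_accel(state + dt_physics / 2 * k1, torque, arm)
  k3 <- arm_accel(state + dt_physics / 2 * k2, torque, arm)
  k4 <- arm_accel(state + dt_physics * k3, torque, arm)
  state + dt_physics / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Total mechanical energy of the arm
#'
#' Kinetic plus gravitational potential energy; conserved under zero torque.
#' @inheritParams arm_dynamics_step
#' @return scalar energy (J).
#' @export
arm_energy <- function(state, arm) {
  p1 <- state[1]; p2 <- state[2]; w1 <- state[3]; w2 <- state[4]
  m1 <- arm$m1; m2 <- arm$m2; l1 <- arm$l1; l2 <- arm$l2; g <- arm$g
  c2 <- cos(p2)
  M11 <- (m1 + m2) * l1^2 + m2 * l2^2 + 2 * m2 * l1 * l2 * c2
  M12 <- m2 * l2^2 + m2 * l1 * l2 * c2
  M22 <- m2 * l2^2
  ke <- 0.5 * (M11 * w1^2 + 2 * M12 * w1 * w2 + M22 * w2^2)
  pe <- -g * ((m1 + m2) * l1 * cos(p1) + m2 * l2 * cos(p1 + p2))
  ke + pe
}

#' Simulate an arm trajectory under a torque sequence
#'
#' @param arm an \code{\link{sample_arm_task}} result.
#' @param torques \code{2 x T} torque matrix (one column per ms).
#' @param state0 initial state (default: hanging at rest).
#' @param dt_physics integration step (s).
#' @return a \code{4 x T} matrix of states after each ms.
#' @export
arm_trajectory <- function(arm, torques, state0 = c(0, 0, 0, 0),
                           dt_physics = 1e-3) {
  TT <- ncol(torques)
  out <- matrix(0, 4, TT)
  st <- state0
  for (t in seq_len(TT)) {
    st <- arm_dynamics_step(st, torques[, t], arm, dt_physics)
    out[, t] <- st
  }
  out
}

#' Forward kinematics of the arm tip
#' @param phi \code{2 x T} joint angles.
#' @param arm the arm parameters.
#' @return \code{2 x T} tip positions (m).
#' @export
arm_tip_position <- function(phi, arm) {
  phi <- matrix(phi, nrow = 2)
  x <- arm$l1 * sin(phi[1, ]) + arm$l2 * sin(phi[1, ] + phi[2, ])
  y <- -arm$l1 * cos(phi[1, ]) - arm$l2 * cos(phi[1, ] + phi[2, ])
  rbind(x, y)
}

# -------------------------------------------------------------------- maze

#' Maze task geometry
#'
#' Circular arena of radius 1; the goal is a disk of radius 0.3 whose centre
#' is uniform on the circle of radius 0.85, fixed for the whole episode.
#'
#' @param seed integer seed.
#' @return an object of class \code{maze_task} with the goal centre.
#' @export
sample_maze_task <- function(seed = NULL) {
  with_seed(seed, {
    th <- stats::runif(1, 0, 2 * pi)
    structure(list(goal = 0.85 * c(cos(th), sin(th)), goal_radius = 0.3,
                   arena_radius = 1, a_scale = 0.02),
              class = "maze_task")
  })
}

#' Uniform position in the unit disk (by area)
#' @param seed integer seed.
#' @return length-2 position.
#' @export
maze_relocate <- function(seed = NULL) {
  with_seed(seed, {
    r <- sqrt(stats::runif(1))
    th <- stats::runif(1, 0, 2 * pi)
    r * c(cos(th), sin(th))
  })
}

#' One environment step of the water-maze task
#'
#' Moves the agent by the chosen velocity. If the segment would leave the
#' unit disk, the agent stops at the intersection with the border and pays
#' -0.02. If the resulting position lies inside the goal disk, the agent
#' collects +1 and is relocated uniformly in the arena (both rewards can
#' occur in one step; they add). Positions never leave the unit disk.
#'
#' @param position length-2 current position, \code{|position| <= 1}.
#' @param velocity length-2 step, norm at most \code{a_scale}.
#' @param task a \code{\link{sample_maze_task}} result.
#' @param relocate_seed seed for the relocation draw (NULL: current stream).
#' @return list with \code{position}, \code{reward}, \code{relocated},
#'   \code{wall_hit}, \code{goal_hit}.
#' @export
maze_step <- function(position, velocity, task, relocate_seed = NULL) {
  reward <- 0
  p2 <- position + velocity
  wall <- FALSE
  if (sum(p2^2) > 1) {
    # intersection of position + s * velocity with the unit circle, s in (0,1]
    a <- sum(velocity^2)
    bq <- 2 * sum(position * velocity)
    cq <- sum(position^2) - 1
    s <- (-bq + sqrt(bq^2 - 4 * a * cq)) / (2 * a)
    p2 <- position + s * velocity
    # guard against rounding pushing the point marginally outside
    nrm <- sqrt(sum(p2^2))
    if (nrm > 1) p2 <- p2 / nrm
    reward <- reward - 0.02
    wall <- TRUE
  }
  goal <- sqrt(sum((p2 - task$goal)^2)) <= task$goal_radius
  relocated <- FALSE
  if (goal) {
    reward <- reward + 1
    p2 <- maze_relocate(relocate_seed)
    relocated <- TRUE
  }
  list(position = p2, reward = reward, relocated = relocated,
       wall_hit = wall, goal_hit = goal)
}

# ------------------------------------------------------------------ patterns

#' Build a one-shot pattern store/complete/delete episode
#'
#' Phase A: three random 25-bit patterns, shown one after the other (100 ms
#' each), no targets. Phase B: partial versions (each 1-bit dropped to 0
#' with probability 0.4), targets are the full patterns. Phase C: a 3-bit
#' one-hot cue naming the pattern to delete. Phase D: the same partials
#' again; targets are the full patterns for the two kept indices, and for
#' the deleted index the kept pattern closest in Hamming distance (ties
#' broken toward the lower index).
#'
#' @param seed integer seed.
#' @param n_bits pattern width.
#' @param n_patterns number of stored patterns.
#' @param drop_prob probability that a 1-bit is zeroed in the partial cue.
#' @param item_ms presentation length per item and for the cue.
#' @return an object of class \code{pattern_task}: fields \code{patterns},
#'   \code{partials} (n_patterns x n_bits matrices), \code{delete_index},
#'   \code{targets_B}, \code{targets_D}, \code{phase_ms}.
#' @export
build_pattern_episode <- function(seed = NULL, n_bits = 25, n_patterns = 3,
                                  drop_prob = 0.4, item_ms = 100) {
  with_seed(seed, {
    pats <- matrix(stats::rbinom(n_patterns * n_bits, 1, 0.5),
                   n_patterns, n_bits)
    keep <- matrix(stats::rbinom(n_patterns * n_bits, 1, 1 - drop_prob),
                   n_patterns, n_bits)
    partials <- pats * keep
    del <- sample.int(n_patterns, 1)
    targets_D <- pats
    kept <- setdiff(seq_len(n_patterns), del)
    hd <- vapply(kept, function(j) sum(pats[del, ] != pats[j, ]), 0)
    targets_D[del, ] <- pats[kept[which.min(hd)], ]
    structure(list(patterns = pats, partials = partials, delete_index = del,
                   targets_B = pats, targets_D = targets_D,
                   n_bits = n_bits, n_patterns = n_patterns,
                   item_ms = item_ms),
              class = "pattern_task")
  })
}
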