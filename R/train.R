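#' Family-specific training configuration defaults
#'
#' Returns the per-task-family settings of the outer loop: episode
#' structure, input coding, loss coefficients and optimizer schedule. The
#' "paper" scale of each family is available through
#' \code{\link{rsnn_preset}}; these defaults are the structural choices
#' shared by all scales.
#' @param family one of "sinusoid", "arm", "pattern", "maze".
#' @return a named list of settings.
#' @export
family_defaults <- function(family = c("sinusoid", "arm", "pattern", "maze")) {
  family <- match.arg(family)
  switch(family,
    sinusoid = list(K = 500, step_ms = 20, lambda_reg = 30, f0 = 20,
                    lr = 1e-3, batch_size = 100, n_code = 100),
    arm = list(duration_ms = 30000, feedback_delay_ms = 100, tau_trace = 50,
               torque_max = 5, lr = 1e-3, batch_size = 80, n_code = 100),
    pattern = list(item_ms = 100, n_bits = 25, n_patterns = 3,
                   drop_prob = 0.4, tau_trace = 100, lambda_reg = 5,
                   f0 = 20, lr = 1e-3, batch_size = 100),
    maze = list(T = 2000, K_episodes = 10, eta = 0.99, epsilon = 0.2,
                mu_v = 1, mu_e = 0.001, mu_firing = 100, f0 = 10,
                a_scale = 0.02, tau_out = 20, nu_init = 0.03,
                lr = 0.01, lr_halve_every = 5000, adam_eps = 1e-5,
                r_max = 500, n_place = 40)
  )
}

# ------------------------------------------------------------ per-family steps

iterate_sinusoid <- function(net, cfg) {
  B <- cfg$batch_size
  tasks <- lapply(seq_len(B), function(i) sample_sinusoid_task())
  ep <- sinusoid_episode_batch(tasks, K = cfg$K, codes = cfg$codes,
                               step_ms = cfg$step_ms)
  fwd <- rsnn_forward(net, ep$x)
  dec <- mean_rate_decode(fwd$z, net$W_out, net$b_out, window = cfg$step_ms)
  y <- if (is.matrix(dec$y)) array(dec$y, c(1, 1, cfg$K)) else dec$y
  pred <- matrix(aperm(y, c(3, 2, 1)), cfg$K, B)             # K x B
  err <- pred - ep$targets
  per_ep <- colSums(err^2)
  f_ep <- apply(fwd$z, 2, avg_rate)
  loss <- mean(per_ep + cfg$lambda_reg * (f_ep - cfg$f0)^2)
  dY <- array(0, c(1, B, cfg$K))
  dY[1, , ] <- t(2 * err / B)
  adj <- mean_rate_adjoint(dY, fwd, net$W_out, window = cfg$step_ms)
  dZ <- adj$dZ + firing_reg_grad(fwd$z, cfg$f0, cfg$lambda_reg)
  core <- rsnn_backward(net, fwd, dZ)
  list(grads = list(W_in = core$dW_in, W_rec = core$dW_rec,
                    W_out = adj$dW_out, b_out = adj$db),
       metrics = c(loss = loss, mse = mean(err^2), f_avg = mean(f_ep)))
}

iterate_arm <- function(net, cfg) {
  B <- cfg$batch_size
  arms <- lapply(seq_len(B), function(i) sample_arm_task())
  ep <- arm_episode_batch(arms, duration_ms = cfg$duration_ms,
                          codes = cfg$codes,
                          feedback_delay_ms = cfg$feedback_delay_ms)
  fwd <- rsnn_forward(net, ep$x)
  dec <- trace_decode(fwd$z, cfg$tau_trace, net$W_out, net$b_out)
  y <- if (B == 1) array(dec$y, c(2, 1, cfg$duration_ms)) else dec$y
  err <- y - ep$targets
  per_ep <- apply(err^2, 2, sum)
  loss <- mean(per_ep)
  dY <- 2 * err / B
  adj <- trace_adjoint(dY, fwd, net$W_out, cfg$tau_trace)
  core <- rsnn_backward(net, fwd, adj$dZ)
  list(grads = list(W_in = core$dW_in, W_rec = core$dW_rec,
                    W_out = adj$dW_out, b_out = adj$db),
       metrics = c(loss = loss, rmse = sqrt(mean(err^2)),
                   f_avg = avg_rate(fwd$z)))
}

iterate_pattern <- function(net, cfg) {
  B <- cfg$batch_size
  eps <- lapply(seq_len(B), function(i)
    build_pattern_episode(n_bits = cfg$n_bits, n_patterns = cfg$n_patterns,
                          drop_prob = cfg$drop_prob, item_ms = cfg$item_ms))
  enc <- pattern_episode_batch(eps)
  fwd <- rsnn_forward(net, enc$x)
  dec <- trace_decode(fwd$z, cfg$tau_trace, net$W_out, net$b_out)
  y <- if (B == 1) array(dec$y, c(cfg$n_bits, 1, enc$T)) else dec$y
  K <- cfg$n_patterns; N <- cfg$n_bits; ms <- cfg$item_ms
  segs <- enc$windows
  dY <- array(0, dim(y))
  ce_sum <- 0; acc <- c(B = 0, D = 0)
  f_ep <- apply(fwd$z, 2, avg_rate)
  for (b in seq_len(B)) {
    for (phase in c("B", "D")) {
      tgt <- if (phase == "B") eps[[b]]$targets_B else eps[[b]]$targets_D
      rows <- which(segs$phase == phase)
      for (r in rows) {
        idx <- segs$t0[r]:segs$t1[r]
        m <- rowMeans(y[, b, idx, drop = FALSE][, 1, ])
        p <- 1 / (1 + exp(-m))
        yk <- tgt[segs$item[r], ]
        pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        ce_sum <- ce_sum + mean(-(yk * log(pc) + (1 - yk) * log(1 - pc))) / K
        acc[phase] <- acc[phase] + mean((p > 0.5) == (yk == 1)) / (K * B)
        g <- (p - yk) / (N * K * B * ms)
        dY[, b, idx] <- dY[, b, idx] + matrix(g, N, length(idx))
      }
    }
  }
  loss <- ce_sum / B + mean(cfg$lambda_reg * (f_ep - cfg$f0)^2)
  adj <- trace_adjoint(dY, fwd, net$W_out, cfg$tau_trace)
  dZ <- adj$dZ + firing_reg_grad(fwd$z, cfg$f0, cfg$lambda_reg)
  core <- rsnn_backward(net, fwd, dZ)
  list(grads = list(W_in = core$dW_in, W_rec = core$dW_rec,
                    W_out = adj$dW_out, b_out = adj$db),
       metrics = c(loss = loss, ce = ce_sum / B, acc_B = acc[["B"]],
                   acc_D = acc[["D"]], f_avg = mean(f_ep)))
}

#' Collect navigation episodes under the current policy
#'
#' Runs \code{K} closed-loop water-maze episodes in parallel with frozen
#' weights and the trainable exploration noise, recording everything the
#' clipped-surrogate update needs: input spikes, noise draws, actions and
#' their log-probabilities, rewards, value estimates.
#'
#' @param net the network (with \code{nu} set).
#' @param cfg maze configuration (see \code{\link{family_defaults}}).
#' @return a trajectory buffer (list).
#' @export
collect_maze_episodes <- function(net, cfg) {
  K <- cfg$K_episodes; TT <- cfg$T
  n <- net$n_rec; n_in <- net$n_in
  code <- maze_position_code(cfg$n_place, cfg$r_max)
  tasks <- lapply(seq_len(K), function(i) sample_maze_task())
  pos <- vapply(seq_len(K), function(i) maze_relocate(), numeric(2))
  state <- rsnn_state(net, K)
  yprev <- matrix(0, 5, K)
  kap <- exp(-net$params$delta_t / cfg$tau_out)
  x_all <- array(0, c(n_in, K, TT))
  eps_all <- array(0, c(n, K, TT))
  actions <- array(0, c(2, K, TT))
  rewards <- matrix(0, K, TT)
  logp <- matrix(0, K, TT)
  value <- matrix(0, K, TT)
  phi_all <- array(0, c(2, K, TT))
  positions <- array(0, c(2, K, TT))
  prev_reward <- numeric(K)
  nu_scale <- net$nu * net$w0
  for (t in seq_len(TT)) {
    xr <- rbind(population_rates(pos[1, ], code),
                population_rates(pos[2, ], code))
    xsp <- matrix(stats::runif(length(xr)) < pmin(xr / 1000, 1), nrow(xr)) + 0
    rsp <- vapply(prev_reward, reward_spikes, numeric(80))
    x_t <- rbind(xsp, rsp)
    eps_t <- matrix(stats::rnorm(n * K), n, K)
    res <- network_step(state, x_t, net,
                        extra_current = nu_scale * eps_t)
    state <- res$state
    drive <- net$W_out %*% res$z + net$b_out
    yprev <- kap * yprev + (1 - kap) * drive
    pol <- policy_decode(yprev, a_scale = cfg$a_scale, sample = TRUE)
    for (k in seq_len(K)) {
      stp <- maze_step(pos[, k], pol$velocity[, k], tasks[[k]])
      pos[, k] <- stp$position
      rewards[k, t] <- stp$reward
    }
    x_all[, , t] <- x_t
    eps_all[, , t] <- eps_t
    actions[, , t] <- pol$action
    logp[, t] <- pol$logp
    value[, t] <- pol$value
    phi_all[, , t] <- pol$phi
    positions[, , t] <- pos
    prev_reward <- rewards[, t]
  }
  returns <- t(apply(rewards, 1, discounted_return, eta = cfg$eta))
  list(x = x_all, noise = eps_all, actions = actions, rewards = rewards,
       logp_old = logp, value_old = value, returns = returns,
       advantage = returns - value, phi_old = phi_all, tasks = tasks,
       positions = positions, K = K, T = TT)
}

#' Clipped-surrogate loss and gradients for a collected trajectory buffer
#'
#' Re-simulates the network on the stored inputs and noise draws under the
#' given parameters (so that for identical parameters the spike trains are
#' identical to collection), evaluates the policy objective, and returns
#' the loss with its analytic readout gradient, ready for
#' \code{\link{rsnn_backward}}.
#'
#' @param net network with current parameters.
#' @param buffer from \code{\link{collect_maze_episodes}}.
#' @param cfg maze configuration.
#' @return list(loss, grads, metrics, ratio).
#' @export
maze_gradients <- function(net, buffer, cfg) {
  K <- buffer$K; TT <- buffer$T
  fwd <- rsnn_forward(net, buffer$x, noise = buffer$noise, record = TRUE)
  y <- leaky_readout(fwd$z, net$W_out, net$b_out, tau_out = cfg$tau_out)
  mu <- tanh(y[1:2, , , drop = FALSE])
  phi <- 1 / (1 + exp(-y[3:4, , , drop = FALSE]))
  V_est <- matrix(y[5, , ], K, TT)
  am <- buffer$actions - mu
  logp <- matrix(colSums(matrix(-0.5 * log(2 * pi * phi) - am^2 / (2 * phi),
                                2)), K, TT)
  ratio <- exp(logp - buffer$logp_old)
  adv <- buffer$advantage
  unclipped <- ratio * adv
  clipped <- pmax(pmin(ratio, 1 + cfg$epsilon), 1 - cfg$epsilon) * adv
  surr <- pmin(unclipped, clipped)
  use_unclipped <- unclipped <= clipped
  H <- 0.5 * log(2 * pi * exp(1) * phi[1, , ]) +
    0.5 * log(2 * pi * exp(1) * phi[2, , ])
  f_ep <- apply(fwd$z, 2, avg_rate)
  loss <- -mean(surr) + cfg$mu_v * mean((buffer$returns - V_est)^2) -
    cfg$mu_e * mean(H) + mean(cfg$mu_firing * (f_ep - cfg$f0)^2)

  M <- K * TT
  dlogp <- -(use_unclipped * ratio * adv) / M          # K x T
  dY <- array(0, c(5, K, TT))
  for (j in 1:2) {
    mj <- matrix(mu[j, , ], K, TT)
    pj <- matrix(phi[j, , ], K, TT)
    aj <- matrix(buffer$actions[j, , ], K, TT)
    # mean channel
    dY[j, , ] <- dlogp * ((aj - mj) / pj) * (1 - mj^2)
    # variance channel: log-prob and entropy terms
    dlp_dphi <- -1 / (2 * pj) + (aj - mj)^2 / (2 * pj^2)
    dH_dphi <- 1 / (2 * pj)
    dY[j + 2, , ] <- (dlogp * dlp_dphi - cfg$mu_e * dH_dphi / M) *
      pj * (1 - pj)
  }
  dY[5, , ] <- -2 * cfg$mu_v * (buffer$returns - V_est) / M
  adj <- leaky_readout_adjoint(dY, fwd, net$W_out, tau_out = cfg$tau_out)
  dZ <- adj$dZ + firing_reg_grad(fwd$z, cfg$f0, cfg$mu_firing)
  core <- rsnn_backward(net, fwd, dZ)
  grads <- list(W_in = core$dW_in, W_rec = core$dW_rec,
                W_out = adj$dW_out, b_out = adj$db, nu = core$dnu)
  list(loss = loss, grads = grads, ratio = ratio,
       metrics = c(loss = loss,
                   reward = mean(rowSums(buffer$rewards)),
                   goals = mean(rowSums(buffer$rewards > 0)),
                   f_avg = mean(f_ep)))
}

# -------------------------------------------------------------- main trainer

#' Train a recurrent spiking network across a task family (outer loop)
#'
#' The learning-to-learn outer loop: in each iteration a batch of task
#' instances is sampled, one inner-loop episode is simulated per task with
#' frozen weights, the family's loss is evaluated, and all synaptic weights
#' (and, for the navigation task, the per-neuron exploration-noise scales)
#' receive one Adam update from surrogate-gradient backpropagation through
#' time. There is no synaptic plasticity within an episode: adaptation to a
#' task instance happens purely through the network dynamics.
#'
#' @param family task family: "sinusoid", "arm", "pattern" or "maze".
#' @param network an \code{\link{rsnn_network}}; NULL builds a sensible
#'   default for the family at the requested size.
#' @param iterations number of outer-loop iterations.
#' @param batch_size episodes per iteration (defaults per family).
#' @param seed master seed; every random stream derives from it.
#' @param control named list overriding entries of
#'   \code{\link{family_defaults}} (episode length \code{K} /
#'   \code{duration_ms} / \code{T}, coefficients, learning rate, ...).
#' @param rewiring optional \code{\link{rewiring_config}}; when supplied
#'   the weights are trained under sparse sign-preserving rewiring.
#' @param continue_from a previous \code{rsnn_l2l} fit to resume (its
#'   weights, optimizer moments and RNG position are restored; the
#'   iteration counter keeps running).
#' @param verbose print progress every \code{verbose} iterations (0 = off).
#' @return an object of class \code{rsnn_l2l} with elements \code{network}
#'   (trained), \code{history} (per-iteration metrics data frame),
#'   \code{family}, \code{cfg}, \code{opt}, \code{seed}.
#' @export
rsnn_l2l <- function(family = c("sinusoid", "arm", "pattern", "maze"),
                     network = NULL, iterations = 100, batch_size = NULL,
                     seed = 1, control = list(), rewiring = NULL,
                     continue_from = NULL, verbose = 0) {
  family <- match.arg(family)
  cfg <- utils::modifyList(family_defaults(family), control)
  if (!is.null(batch_size)) cfg$batch_size <- batch_size

  if (!is.null(continue_from)) {
    stopifnot(inherits(continue_from, "rsnn_l2l"))
    net <- continue_from$network
    cfg <- continue_from$cfg
    opt <- continue_from$opt
    history <- continue_from$history
    assign(".Random.seed", continue_from$rng_state, envir = globalenv())
    iter0 <- nrow(history)
    rewiring <- continue_from$rewiring
  } else {
    net <- network %||% default_network(family, cfg, seed)
    if (family == "sinusoid") {
      cfg$codes <- cfg$codes %||% sinusoid_codes(cfg$n_code)
    }
    if (family == "arm") {
      cfg$codes <- cfg$codes %||% arm_codes(cfg$n_code, cfg$torque_max)
    }
    if (family == "maze" && is.null(net$nu)) {
      net <- set_weights(net, nu = rep(cfg$nu_init, net$n_rec))
    }
    params <- list(W_in = net$W_in, W_rec = net$W_rec, W_out = net$W_out,
                   b_out = net$b_out)
    if (family == "maze") params$nu <- net$nu
    opt <- adam_init(params, lr = cfg$lr,
                     eps = cfg$adam_eps %||% 1e-8)
    history <- NULL
    iter0 <- 0L
    set.seed(derive_seed(seed, "outer-loop"))
  }

  step_fn <- switch(family,
                    sinusoid = iterate_sinusoid,
                    arm = iterate_arm,
                    pattern = iterate_pattern,
                    maze = function(net, cfg) {
                      buf <- collect_maze_episodes(net, cfg)
                      res <- maze_gradients(net, buf, cfg)
                      res
                    })

  for (it in seq_len(iterations)) {
    res <- step_fn(net, cfg)
    lr_it <- cfg$lr
    if (!is.null(cfg$lr_halve_every)) {
      lr_it <- cfg$lr * 0.5^floor((iter0 + it - 1) / cfg$lr_halve_every)
    }
    # input/recurrent weights are trained in units of the scale w0 (the
    # voltage scale exists so that optimizer steps are well-conditioned);
    # readout weights live in task units and are trained as-is
    gr <- res$grads
    gr$W_in <- gr$W_in * net$w0
    gr$W_rec <- gr$W_rec * net$w0
    upd <- adam_step(opt, gr, lr = lr_it)
    opt <- upd$opt
    st <- upd$steps
    st$W_in <- st$W_in * net$w0
    st$W_rec <- st$W_rec * net$w0
    if (is.null(rewiring)) {
      net <- set_weights(net,
                         W_in = net$W_in - st$W_in,
                         W_rec = net$W_rec - st$W_rec,
                         W_out = net$W_out - st$W_out,
                         b_out = net$b_out - st$b_out,
                         nu = if (!is.null(st$nu)) net$nu - st$nu else NULL)
    } else {
      # L1 shrinkage folded into the step, scaled like each matrix's units
      dr <- deepr_step(
        weights = list(W_in = net$W_in, W_rec = net$W_rec,
                       W_out = net$W_out),
        mask = list(W_in = net$mask_in, W_rec = net$mask_rec,
                    W_out = net$mask_out),
        sign = list(W_in = net$sign_in, W_rec = net$sign_rec,
                    W_out = net$sign_out),
        grads = list(
          W_in = st$W_in + lr_it * rewiring$l1 * net$w0 * net$sign_in,
          W_rec = st$W_rec + lr_it * rewiring$l1 * net$w0 * net$sign_rec,
          W_out = st$W_out + lr_it * rewiring$l1 * net$sign_out),
        lr = 1,
        cfg = rewiring_config(rewiring$connectivity, l1 = 0,
                              temperature = rewiring$temperature),
        exclude_diag = list(W_in = FALSE, W_rec = TRUE, W_out = FALSE))
      net$mask_in <- dr$mask$W_in
      net$mask_rec <- dr$mask$W_rec
      net$mask_out <- dr$mask$W_out
      net <- set_weights(net,
                         W_in = dr$weights$W_in,
                         W_rec = dr$weights$W_rec,
                         W_out = dr$weights$W_out,
                         b_out = net$b_out - st$b_out,
                         nu = if (!is.null(st$nu)) net$nu - st$nu else NULL)
    }
    history <- rbind(history,
                     data.frame(iteration = iter0 + it,
                                t(res$metrics)))
    if (verbose > 0 && (it %% verbose == 0)) {
      message(sprintf("iter %d: %s", iter0 + it,
                      paste(sprintf("%s=%.4g", names(res$metrics),
                                    res$metrics), collapse = " ")))
    }
  }

  structure(list(network = net, history = history, family = family,
                 cfg = cfg, opt = opt, seed = seed, rewiring = rewiring,
                 rng_state = get(".Random.seed", envir = globalenv())),
            class = "rsnn_l2l")
}

#' @keywords internal
default_network <- function(family, cfg, seed) {
  switch(family,
    sinusoid = rsnn_network(100, n_in = 2 * cfg$n_code, n_out = 1,
                            sfa_fraction = 0.4, beta = 1.6,
                            tau_a_range = c(1, 3000), seed = seed),
    arm = rsnn_network(600, n_in = 4 * cfg$n_code, n_out = 2,
                       sfa_fraction = 0.5, beta = 1.7,
                       tau_a_range = c(1, 600), seed = seed),
    pattern = rsnn_network(300, n_in = 140, n_out = 25, sfa_fraction = 0.5,
                           beta = 1.7, tau_a_range = c(1, 1000),
                           seed = seed),
    maze = rsnn_network(400, n_in = 2 * cfg$n_place + 80, n_out = 5,
                        sfa_fraction = 0.3, beta = 1.7,
                        tau_a_range = c(1200, 1200), tau_m = c(15, 30),
                        tau_ref = 3, dale = TRUE, frac_excitatory = 0.8,
                        connectivity = 0.2, delay_range = c(1, 10),
                        seed = seed))
}

# ----------------------------------------------------------------- S3 methods

#' @export
print.rsnn_l2l <- function(x, ...) {
  cat(sprintf("Learning-to-learn fit: %s task family\n", x$family))
  print(x$network)
  n <- nrow(x$history)
  cat(sprintf("  %d outer-loop iterations; loss %.4g -> %.4g\n",
              n, x$history$loss[1], x$history$loss[n]))
  invisible(x)
}

#' @export
summary.rsnn_l2l <- function(object, smooth = 10, ...) {
  h <- object$history
  n <- nrow(h)
  w <- min(smooth, n)
  out <- list(
    family = object$family,
    iterations = n,
    loss_first = mean(h$loss[seq_len(w)]),
    loss_last = mean(h$loss[(n - w + 1):n]),
    f_avg_last = if ("f_avg" %in% names(h)) mean(h$f_avg[(n - w + 1):n])
                 else NA_real_,
    history = h
  )
  out$loss_ratio <- out$loss_last / out$loss_first
  class(out) <- "summary.rsnn_l2l"
  out
}

#' @export
print.summary.rsnn_l2l <- function(x, ...) {
  cat(sprintf("%s family, %d iterations\n", x$family, x$iterations))
  cat(sprintf("smoothed loss: %.4g (start) -> %.4g (end), ratio %.3f\n",
              x$loss_first, x$loss_last, x$loss_ratio))
  if (is.finite(x$f_avg_last))
    cat(sprintf("final average firing rate: %.2f Hz\n", x$f_avg_last))
  invisible(x)
}

#' @export
coef.rsnn_l2l <- function(object, ...) {
  net <- object$network
  out <- list(W_in = net$W_in, W_rec = net$W_rec, W_out = net$W_out,
              b_out = net$b_out)
  if (!is.null(net$nu)) out$nu <- net$nu
  out
}

#' @export
plot.rsnn_l2l <- function(x, which = "loss", ...) {
  h <- x$history
  stopifnot(which %in% names(h))
  graphics::plot(h$iteration, h[[which]], type = "l", xlab = "iteration",
                 ylab = which, log = if (which == "loss") "y" else "", ...)
  invisible(x)
}

#' Predict on fresh task instances with frozen weights
#'
#' Runs inner-loop episodes on newly sampled (held-out) tasks; weights are
#' not updated. For the sinusoid family returns per-step predictions,
#' targets and the episode MSE.
#'
#' @param object an \code{rsnn_l2l} fit.
#' @param n_tasks number of fresh tasks.
#' @param seed integer seed for the held-out draw.
#' @param ... unused.
#' @return a list; for "sinusoid": \code{predictions}, \code{targets}
#'   (K x n_tasks), \code{mse} (per-episode), \code{mse_mean}.
#' @export
predict.rsnn_l2l <- function(object, n_tasks = 10, seed = 1, ...) {
  net <- object$network; cfg <- object$cfg
  if (object$family != "sinusoid") {
    return(evaluate_task(object, n_eval = n_tasks, seed = seed))
  }
  with_seed(derive_seed(seed, "predict"), {
    tasks <- lapply(seq_len(n_tasks), function(i) sample_sinusoid_task())
    ep <- sinusoid_episode_batch(tasks, K = cfg$K, codes = cfg$codes,
                                 step_ms = cfg$step_ms)
    fwd <- rsnn_forward(net, ep$x, record = FALSE)
    dec <- mean_rate_decode(fwd$z, net$W_out, net$b_out,
                            window = cfg$step_ms)
    y <- if (n_tasks == 1) array(dec$y, c(1, 1, cfg$K)) else dec$y
    pred <- matrix(aperm(y, c(3, 2, 1)), cfg$K, n_tasks)
    err <- pred - ep$targets
    list(predictions = pred, targets = ep$targets, x = ep$xs,
         mse = colMeans(err^2), mse_mean = mean(err^2))
  })
}

#' Simulate inner-loop episodes from a fit
#'
#' Generates complete episode records (inputs, spikes, readouts, targets)
#' for fresh tasks with the fitted, frozen weights.
#'
#' @param object an \code{rsnn_l2l} fit.
#' @param nsim number of episodes.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of episode records.
#' @export
simulate.rsnn_l2l <- function(object, nsim = 1, seed = 1, ...) {
  net <- object$network; cfg <- object$cfg
  with_seed(derive_seed(seed, "simulate"), {
    if (object$family == "sinusoid") {
      tasks <- lapply(seq_len(nsim), function(i) sample_sinusoid_task())
      ep <- sinusoid_episode_batch(tasks, K = cfg$K, codes = cfg$codes,
                                   step_ms = cfg$step_ms)
      fwd <- rsnn_forward(net, ep$x)
      dec <- mean_rate_decode(fwd$z, net$W_out, net$b_out,
                              window = cfg$step_ms)
      lapply(seq_len(nsim), function(b) {
        list(task = tasks[[b]], x = ep$xs[, b], targets = ep$targets[, b],
             spikes = fwd$z[, b, ], inputs = ep$x[, b, ],
             readout = if (nsim == 1) dec$y else dec$y[, b, ])
      })
    } else if (object$family == "maze") {
      buf <- collect_maze_episodes(net, utils::modifyList(
        cfg, list(K_episodes = nsim)))
      lapply(seq_len(nsim), function(k) {
        list(task = buf$tasks[[k]], positions = buf$positions[, k, ],
             rewards = buf$rewards[k, ], inputs = buf$x[, k, ])
      })
    } else {
      stop_cfg("simulate() supports the sinusoid and maze families")
    }
  })
}

#' @export
residuals.rsnn_l2l <- function(object, n_tasks = 10, seed = 1, ...) {
  p <- predict(object, n_tasks = n_tasks, seed = seed)
  if (!is.null(p$predictions)) p$predictions - p$targets else
    stop_cfg("residuals are defined for the sinusoid family")
}
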