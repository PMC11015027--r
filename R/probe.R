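#' Probe the internal model of a frozen network state
#'
#' For each value on a grid of hypothetical inputs, simulates one 20 ms
#' input presentation from a copy of a stored mid-episode snapshot and
#' records the decoded output; the original state is untouched, so probing
#' has no effect on the episode the snapshot came from. The resulting curve
#' is the network's current internal model of the target function: before
#' any example it shows the prior engraved in the weights, and it sharpens
#' as within-episode examples arrive.
#'
#' @param state an \code{\link{rsnn_state}} snapshot (batch 1), e.g. from
#'   \code{\link{rsnn_snapshot}}.
#' @param net the network.
#' @param x_grid probe input values (default 101 points over [-5, 5]).
#' @param codes input codes (\code{\link{sinusoid_codes}}).
#' @param step_ms presentation length.
#' @param seed integer seed for the probe spike encoding (same seed, same
#'   curve).
#' @return an object of class \code{probe_result}: data frame with
#'   \code{x} and \code{y} (decoded output per grid point); attribute
#'   \code{snapshot_t} records the snapshot time.
#' @export
internal_model_probe <- function(state, net, x_grid = seq(-5, 5, length.out = 101),
                                 codes = sinusoid_codes(), step_ms = 20,
                                 seed = 1) {
  stopifnot(inherits(state, "rsnn_state"), ncol(state$V) == 1)
  y <- vapply(seq_along(x_grid), function(i) {
    st <- state  # R copy semantics isolate the probe from the caller's state
    xin <- sinusoid_probe_input(x_grid[i], codes, step_ms,
                                seed = derive_seed(seed, i))
    zs <- matrix(0, net$n_rec, step_ms)
    for (t in seq_len(step_ms)) {
      res <- network_step(st, xin[, t], net)
      st <- res$state
      zs[, t] <- res$z
    }
    feat <- rowSums(zs) / step_ms
    as.numeric(net$W_out %*% feat + net$b_out)[1]
  }, numeric(1))
  structure(data.frame(x = x_grid, y = y),
            snapshot_t = state$t, class = c("probe_result", "data.frame"))
}

#' Per-episode linear regression baseline for the sinusoid family
#'
#' For each episode, fits ordinary least squares (slope and intercept) on
#' the analog input/target values of the first half (250 of 500 points) and
#' evaluates the mean squared error on the second half; returns the average
#' over episodes. This is the analog-value baseline the spiking network is
#' compared against.
#'
#' @param n_episodes number of episodes to average over.
#' @param seed integer seed.
#' @param K points per episode (half fit, half test).
#' @return mean test MSE; attributes \code{se} (standard error) and
#'   \code{per_episode}.
#' @export
linear_baseline <- function(n_episodes = 5000, seed = 1, K = 500) {
  half <- K %/% 2
  with_seed(derive_seed(seed, "baseline"), {
    mse <- numeric(n_episodes)
    kept <- logical(n_episodes)
    for (i in seq_len(n_episodes)) {
      task <- sample_sinusoid_task()
      ep <- regression_episode(task, K = K)
      xf <- ep$x[seq_len(half)]; yf <- ep$target[seq_len(half)]
      vx <- stats::var(xf)
      if (vx < .Machine$double.eps) {
        warning("degenerate episode (constant inputs) skipped")
        next
      }
      b <- stats::cov(xf, yf) / vx
      a <- mean(yf) - b * mean(xf)
      xt <- ep$x[(half + 1):K]; yt <- ep$target[(half + 1):K]
      mse[i] <- mean((yt - (a + b * xt))^2)
      kept[i] <- TRUE
    }
    m <- mse[kept]
    structure(mean(m), se = stats::sd(m) / sqrt(length(m)), per_episode = m)
  })
}

#' Evaluate a fit on held-out task instances
#'
#' Family-appropriate test metrics computed on freshly sampled tasks with
#' frozen weights: sinusoid, mean test MSE; arm, joint-angle and tip-position
#' RMSE; maze, goals reached and accumulated reward per episode; pattern,
#' bitwise accuracy in the completion phases.
#'
#' @param fit an \code{rsnn_l2l} object.
#' @param n_eval number of held-out episodes.
#' @param seed integer seed (fixed seed, reproducible metrics).
#' @return named list of metrics.
#' @export
evaluate_task <- function(fit, n_eval = 20, seed = 1) {
  net <- fit$network; cfg <- fit$cfg
  with_seed(derive_seed(seed, "evaluate"), {
    switch(fit$family,
      sinusoid = {
        tasks <- lapply(seq_len(n_eval), function(i) sample_sinusoid_task())
        ep <- sinusoid_episode_batch(tasks, K = cfg$K, codes = cfg$codes,
                                     step_ms = cfg$step_ms)
        fwd <- rsnn_forward(net, ep$x, record = FALSE)
        dec <- mean_rate_decode(fwd$z, net$W_out, net$b_out,
                                window = cfg$step_ms)
        y <- if (is.matrix(dec$y)) array(dec$y, c(1, 1, cfg$K)) else dec$y
        pred <- matrix(aperm(y, c(3, 2, 1)), cfg$K, n_eval)
        err <- pred - ep$targets
        half <- cfg$K %/% 2
        list(mse = mean(err^2),
             mse_second_half = mean(err[(half + 1):cfg$K, ]^2),
             f_avg = avg_rate(fwd$z))
      },
      arm = {
        arms <- lapply(seq_len(n_eval), function(i) sample_arm_task())
        ep <- arm_episode_batch(arms, duration_ms = cfg$duration_ms,
                                codes = cfg$codes,
                                feedback_delay_ms = cfg$feedback_delay_ms)
        fwd <- rsnn_forward(net, ep$x, record = FALSE)
        dec <- trace_decode(fwd$z, cfg$tau_trace, net$W_out, net$b_out)
        y <- if (is.matrix(dec$y)) array(dec$y, c(2, 1, cfg$duration_ms))
             else dec$y
        err <- y - ep$targets
        tip_err <- vapply(seq_len(n_eval), function(b) {
          tp <- arm_tip_position(matrix(y[, b, ], 2), arms[[b]])
          tt <- arm_tip_position(matrix(ep$targets[, b, ], 2), arms[[b]])
          sqrt(mean((tp - tt)^2))
        }, numeric(1))
        err_t <- sqrt(apply(err^2, 3, mean))
        list(rmse_angle = sqrt(mean(err^2)), rmse_tip = mean(tip_err),
             error_vs_time = err_t, f_avg = avg_rate(fwd$z))
      },
      maze = {
        buf <- collect_maze_episodes(net, utils::modifyList(
          cfg, list(K_episodes = n_eval)))
        list(reward = mean(rowSums(buf$rewards)),
             goals = mean(rowSums(buf$rewards > 0)))
      },
      pattern = {
        eps <- lapply(seq_len(n_eval), function(i)
          build_pattern_episode(n_bits = cfg$n_bits,
                                n_patterns = cfg$n_patterns,
                                drop_prob = cfg$drop_prob,
                                item_ms = cfg$item_ms))
        enc <- pattern_episode_batch(eps)
        fwd <- rsnn_forward(net, enc$x, record = FALSE)
        dec <- trace_decode(fwd$z, cfg$tau_trace, net$W_out, net$b_out)
        y <- if (is.matrix(dec$y)) array(dec$y, c(cfg$n_bits, 1, enc$T))
             else dec$y
        segs <- enc$windows
        acc <- c(B = 0, D = 0); cnt <- c(B = 0, D = 0)
        for (b in seq_len(n_eval)) {
          for (phase in c("B", "D")) {
            tgt <- if (phase == "B") eps[[b]]$targets_B else
              eps[[b]]$targets_D
            for (r in which(segs$phase == phase)) {
              idx <- segs$t0[r]:segs$t1[r]
              m <- rowMeans(matrix(y[, b, idx], cfg$n_bits))
              p <- 1 / (1 + exp(-m))
              acc[phase] <- acc[phase] +
                mean((p > 0.5) == (tgt[segs$item[r], ] == 1))
              cnt[phase] <- cnt[phase] + 1
            }
          }
        }
        acc <- acc / cnt
        list(accuracy_B = acc[["B"]], accuracy_D = acc[["D"]],
             accuracy_mean = mean(acc))
      })
  })
}
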