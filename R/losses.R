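#' Firing-rate regularizer
#'
#' Quadratic penalty \code{coefficient * (f_avg - f0)^2} pulling the
#' episode-average firing rate toward the target \code{f0}, inducing sparse
#' firing. \code{f_avg} is total spikes divided by (neurons x episode
#' duration in seconds), in Hz.
#'
#' @param spikes binary spike matrix/array for one episode.
#' @param f0 target rate (Hz).
#' @param coefficient penalty weight.
#' @param delta_t step in ms.
#' @return scalar penalty; attribute \code{f_avg} carries the rate.
#' @export
firing_regularizer <- function(spikes, f0 = 20, coefficient = 30,
                               delta_t = 1) {
  n <- dim(spikes)[1]
  TT <- length(spikes) / n
  f_avg <- sum(spikes) / (n * TT * delta_t / 1000)
  structure(coefficient * (f_avg - f0)^2, f_avg = f_avg)
}

#' Episode-average firing rate in Hz
#' @keywords internal
avg_rate <- function(spikes, delta_t = 1) {
  n <- dim(spikes)[1]
  TT <- length(spikes) / n
  sum(spikes) / (n * TT * delta_t / 1000)
}

#' Sinusoid regression loss
#'
#' Sum of squared prediction errors over the K steps of an episode plus the
#' firing regularizer; averaged over the batch.
#'
#' @param predictions K x B matrix (or vector) of predictions.
#' @param targets same shape.
#' @param spikes spike array \code{(n, B, T)} of the episode batch.
#' @param lambda_reg regularizer coefficient.
#' @param f0 target rate (Hz).
#' @return scalar loss; attributes \code{mse} (per-step mean squared error)
#'   and \code{f_avg}.
#' @export
regression_loss <- function(predictions, targets, spikes = NULL,
                            lambda_reg = 30, f0 = 20) {
  predictions <- as.matrix(predictions); targets <- as.matrix(targets)
  B <- ncol(predictions)
  sq <- colSums((targets - predictions)^2)
  reg <- 0; f_avg <- NA_real_
  if (!is.null(spikes) && lambda_reg > 0) {
    if (is.matrix(spikes)) spikes <- array(spikes, c(nrow(spikes), 1, ncol(spikes)))
    f_ep <- apply(spikes, 2, avg_rate)
    reg <- lambda_reg * (f_ep - f0)^2
    f_avg <- mean(f_ep)
  }
  structure(mean(sq + reg),
            mse = mean((targets - predictions)^2), f_avg = f_avg)
}

#' Arm forward-model loss
#'
#' Time-summed squared error between predicted and true joint angles over
#' the episode (1 ms steps), averaged over the batch.
#'
#' @param predicted array \code{(2, B, T)} (or 2 x T).
#' @param true same shape.
#' @return scalar loss; attribute \code{rmse} (per-angle-step RMSE, rad).
#' @export
arm_loss <- function(predicted, true) {
  if (is.matrix(predicted)) {
    predicted <- array(predicted, c(nrow(predicted), 1, ncol(predicted)))
    true <- array(true, c(nrow(true), 1, ncol(true)))
  }
  B <- dim(predicted)[2]
  err <- (predicted - true)^2
  per_ep <- apply(err, 2, sum)
  structure(mean(per_ep), rmse = sqrt(mean(err)))
}

#' Bit-wise cross-entropy pattern loss
#'
#' Mean over phases B and D of the per-item bitwise binary cross-entropy
#' \code{-(1/N) sum_n [y log p + (1 - y) log(1 - p)]}, plus the firing
#' regularizer. Predicted probabilities are clipped away from 0/1 for
#' numerical safety.
#'
#' @param p_B,p_D predicted probability matrices (items x bits) for phases B
#'   and D.
#' @param y_B,y_D target bit matrices, same shapes.
#' @param spikes optional episode spike array for the firing term.
#' @param lambda_reg regularizer coefficient.
#' @param f0 target rate (Hz).
#' @return scalar loss; attribute \code{ce} (cross-entropy part).
#' @export
pattern_loss <- function(p_B, y_B, p_D, y_D, spikes = NULL, lambda_reg = 5,
                         f0 = 20) {
  ce_item <- function(p, y) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -rowMeans(y * log(p) + (1 - y) * log(1 - p))
  }
  K <- nrow(p_B)
  ce <- mean(ce_item(p_B, y_B)) + mean(ce_item(p_D, y_D))
  reg <- 0
  if (!is.null(spikes) && lambda_reg > 0) {
    reg <- as.numeric(firing_regularizer(spikes, f0, lambda_reg))
  }
  structure(ce + reg, ce = ce)
}

#' Discounted return
#'
#' \code{R(t) = sum_{t' > t} eta^(t' - t) r(t')}: the finite-horizon
#' discounted sum of strictly future rewards, computed by a reverse scan.
#'
#' @param rewards reward vector over an episode.
#' @param eta discount factor in (0, 1).
#' @return vector of returns, same length.
#' @export
discounted_return <- function(rewards, eta = 0.99) {
  stopifnot(eta > 0, eta < 1)
  TT <- length(rewards)
  R <- numeric(TT)
  acc <- 0
  for (t in rev(seq_len(TT))) {
    R[t] <- acc
    acc <- eta * (acc + rewards[t])
  }
  R
}

#' Exploration noise applied to the synaptic current
#'
#' Adds zero-mean Gaussian noise with per-neuron standard deviation
#' \code{nu_j} (in units of the weight scale \code{w0}) to the
#' voltage-equivalent drive; \code{nu} is a trainable parameter
#' (initialised at 0.03 in the navigation task).
#'
#' @param I current (voltage-equivalent) vector or matrix (neurons in rows).
#' @param nu per-neuron noise scale.
#' @param w0 weight scale the noise is expressed in.
#' @param seed integer seed.
#' @return \code{I} plus noise, same shape.
#' @export
noisy_current <- function(I, nu, w0 = 1, seed = NULL) {
  if (all(nu == 0)) return(I)
  I <- as.matrix(I)
  with_seed(seed,
            I + (nu * w0) * matrix(stats::rnorm(length(I)), nrow(I)))
}

#' Clipped-surrogate policy-optimization loss
#'
#' Standard clipped probability-ratio objective with a value-error term,
#' an entropy bonus and the firing regularizer:
#' \deqn{L = -mean[min(r A, clip(r, 1-eps, 1+eps) A)]
#'        + mu_v mean[(R - V)^2] - mu_e mean[H] + mu_f (f_avg - f0)^2}
#' with ratio \code{r = pi_theta / pi_theta_old} and advantage
#' \code{A = R - V_old}. At \code{theta = theta_old} the ratio is exactly 1
#' for every step.
#'
#' @param logp log-probabilities of the stored actions under the current
#'   parameters (vector over all (k, t)).
#' @param logp_old log-probabilities recorded at collection time.
#' @param advantage \code{R - V_old} per step.
#' @param returns discounted returns per step.
#' @param value current value estimates per step.
#' @param phi current per-step 2 x m variance matrix (for the entropy term).
#' @param spikes episode spike array (firing term), or NULL.
#' @param epsilon clip parameter.
#' @param mu_v,mu_e,mu_firing regularization coefficients.
#' @param f0 target rate (Hz).
#' @return scalar loss; attributes \code{surrogate}, \code{value_loss},
#'   \code{entropy}, \code{f_avg}, and \code{ratio} (the per-step ratios).
#' @export
ppo_loss <- function(logp, logp_old, advantage, returns, value, phi,
                     spikes = NULL, epsilon = 0.2, mu_v = 1, mu_e = 0.001,
                     mu_firing = 100, f0 = 10) {
  if (is.null(logp_old)) stop_cfg("collection log-probabilities missing")
  ratio <- exp(logp - logp_old)
  surr <- pmin(ratio * advantage,
               pmax(pmin(ratio, 1 + epsilon), 1 - epsilon) * advantage)
  vloss <- mean((returns - value)^2)
  H <- mean(gaussian_entropy(phi))
  f_avg <- if (is.null(spikes)) f0 else avg_rate(spikes)
  total <- -mean(surr) + mu_v * vloss - mu_e * H +
    mu_firing * (f_avg - f0)^2
  structure(total, surrogate = mean(surr), value_loss = vloss, entropy = H,
            f_avg = f_avg, ratio = ratio)
}

# ------------------------------------------------------------------- Adam

#' Initialise Adam optimizer state
#'
#' @param params named list of numeric arrays (the trainable parameters).
#' @param lr learning rate.
#' @param beta1,beta2 moment decay rates.
#' @param eps numerical stabilizer.
#' @return an object of class \code{adam_state}.
#' @export
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  structure(list(
    m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
    t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps
  ), class = "adam_state")
}

#' One Adam update
#'
#' Returns the update direction (to be subtracted from the parameters) for
#' each parameter, with bias-corrected first and second moments.
#'
#' @param opt an \code{\link{adam_init}} state.
#' @param grads named list of gradients matching the parameters.
#' @param lr optional learning-rate override for this step.
#' @return list with updated \code{opt} and \code{steps} (named list of
#'   updates; new parameter = old - step).
#' @export
adam_step <- function(opt, grads, lr = NULL) {
  lr <- lr %||% opt$lr
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  steps <- vector("list", length(grads)); names(steps) <- names(grads)
  for (k in names(grads)) {
    g <- grads[[k]]
    opt$m[[k]] <- opt$beta1 * opt$m[[k]] + (1 - opt$beta1) * g
    opt$v[[k]] <- opt$beta2 * opt$v[[k]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[k]] / bc1
    vhat <- opt$v[[k]] / bc2
    steps[[k]] <- lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(opt = opt, steps = steps)
}
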