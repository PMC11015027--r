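# Independent oracles used across the test files. These re-derive expected
# values by a different route than the implementation under test.

# Forward-mode tangent propagation through the surrogate computation graph:
# propagates the directional derivative of a single weight coordinate
# through the identical graph (same pseudo-derivative at the spike node,
# exact adaptation recursion) and accumulates the loss tangent. Written as
# a naive scalar/step recursion, independent of the package's vectorised
# reverse-mode pass. Assumes all delays are 1 ms and batch 1.
tangent_grad_oracle <- function(net, x, dZdir, dVdir, which, i, j) {
  n <- net$n_rec; TT <- dim(x)[3]
  alpha <- net$params$alpha; rho <- net$adapt$rho
  beta <- net$adapt$beta; vth <- net$params$v_th; gam <- net$gamma
  V <- numeric(n); a <- numeric(n); refrac <- integer(n)
  tV <- numeric(n); ta <- numeric(n)
  Z <- matrix(0, n, TT); tZ <- matrix(0, n, TT)
  g <- 0
  for (t in seq_len(TT)) {
    A <- vth + beta * a
    vnorm <- (V - A) / A
    gate <- (refrac == 0)
    z <- (V > A & gate) + 0
    pd <- gate * gam * pmax(0, 1 - abs(vnorm))
    tA <- beta * ta
    tvn <- tV / A - V * tA / A^2
    tz <- pd * tvn
    g <- g + sum(dZdir[, t] * tz) + sum(dVdir[, t] * tV)
    I <- numeric(n); tI <- numeric(n)
    if (t - 1 >= 1) {
      I <- net$W_in %*% x[, 1, t - 1] + net$W_rec %*% Z[, t - 1]
      tI <- net$W_rec %*% tZ[, t - 1]
      if (which == "W_in") tI[i] <- tI[i] + x[j, 1, t - 1]
      if (which == "W_rec") tI[i] <- tI[i] + Z[j, t - 1]
    }
    Vn <- alpha * V + (1 - alpha) * I - vth * z
    tVn <- alpha * tV + (1 - alpha) * tI - vth * tz
    an <- rho * a + (1 - rho) * z
    tan_ <- rho * ta + (1 - rho) * tz
    refrac <- ifelse(z > 0, net$params$n_ref, pmax(refrac - 1L, 0L))
    Z[, t] <- z; tZ[, t] <- tz
    V <- c(Vn); a <- c(an); tV <- c(tVn); ta <- c(tan_)
  }
  g
}

# The trainable weight set of a network, for freeze/identity checks.
coef_net <- function(net) {
  list(net$W_in, net$W_rec, net$W_out, net$b_out, net$nu)
}

# Small lively test network: some spikes, mixed LIF/SFA.
toy_net <- function(n = 3, n_in = 2, seed = 5, scale = 0.6,
                    sfa_fraction = 2/3) {
  net <- rsnn_network(n, n_in, n_out = 1, sfa_fraction = sfa_fraction,
                      beta = 1.7, tau_a_range = c(30, 200), seed = seed)
  set_weights(net, W_in = net$W_in * scale, W_rec = net$W_rec * scale)
}

# Closed-form membrane trajectory for zero input and no spikes.
decay_oracle <- function(V0, alpha, TT) V0 * alpha^seq_len(TT)

# Closed-form adaptation variable from a spike train:
# a(t) = sum over spikes s <= t of (1 - rho) rho^(t - s), with spikes
# applied after the decay of their own step (a(t+1) = rho a(t) + (1-rho) z(t)).
adaptation_oracle <- function(spikes, rho) {
  TT <- length(spikes)
  a <- numeric(TT)
  for (t in seq_len(TT)) {
    s <- seq_len(t - 1)
    a[t] <- if (t == 1) 0 else sum((1 - rho) * rho^(t - 1 - s) * spikes[s])
  }
  a
}

# Hand-rolled Adam recursion for a scalar parameter (independent of
# adam_init/adam_step).
adam_oracle <- function(grads, lr = 1e-3, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  th <- 0; m <- 0; v <- 0
  out <- numeric(length(grads))
  for (t in seq_along(grads)) {
    g <- grads[t]
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    th <- th - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
    out[t] <- th
  }
  out
}
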