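test_that("membrane step follows the leaky-integrate recursion exactly", {
  np <- neuron_params(1, tau_m = 20, v_th = 30, delta_t = 1)
  # fixed point at rest
  expect_identical(membrane_step(0, 0, np, 0), 0)
  # pure exponential decay (oracle: evaluate alpha)
  expect_equal(membrane_step(20, 0, np, 0), 20 * exp(-1 / 20),
               tolerance = 1e-15)
  # subtractive reset by the fixed baseline threshold
  expect_equal(membrane_step(31, 0, np, 1), 31 * exp(-1 / 20) - 30,
               tolerance = 1e-15)
  # drive term enters through (1 - alpha) R_m I
  a <- exp(-1 / 20)
  expect_equal(membrane_step(5, 2, np, 0), a * 5 + (1 - a) * 2,
               tolerance = 1e-15)
  expect_error(membrane_step(Inf, 0, np, 0), "non-finite")
})

test_that("zero-input decay matches V0 * alpha^t over long horizons", {
  set.seed(42)
  np <- neuron_params(1, tau_m = 20)
  for (rep in 1:25) {
    V0 <- runif(1, -25, 25)   # subthreshold, no spikes ever
    TT <- 40
    v <- V0
    traj <- numeric(TT)
    for (t in seq_len(TT)) {
      v <- membrane_step(v, 0, np, 0)
      traj[t] <- v
    }
    expect_equal(traj, decay_oracle(V0, np$alpha, TT), tolerance = 1e-12)
  }
})

test_that("adaptive threshold updates and decays as a geometric sum", {
  ad <- adaptation_params(1, beta = 1.7, tau_a = 1000)
  # resting neuron
  r <- threshold_step(0, 0, ad, 30)
  expect_identical(r$a, 0)
  expect_identical(r$A, 30)
  # pure geometric decay toward 0
  expect_equal(threshold_step(1, 0, ad, 30)$a, ad$rho, tolerance = 1e-15)
  # spike increment is (1 - rho)
  expect_equal(threshold_step(0, 1, ad, 30)$a, 1 - exp(-1 / 1000),
               tolerance = 1e-15)
  # beta = 0 keeps the threshold at v_th whatever the adaptation state
  ad0 <- adaptation_params(1, beta = 0, tau_a = 50)
  expect_identical(threshold_step(5, 1, ad0, 30)$A, 30)

  # closed-form spike-sum oracle on random spike trains
  set.seed(7)
  ad2 <- adaptation_params(1, beta = 1, tau_a = 120)
  for (rep in 1:10) {
    z <- rbinom(60, 1, 0.2)
    a <- 0
    traj <- numeric(60)
    for (t in 1:60) {
      traj[t] <- a
      a <- threshold_step(a, z[t], ad2, 30)$a
    }
    expect_equal(traj, adaptation_oracle(z, ad2$rho), tolerance = 1e-12)
  }
})

test_that("spiking requires strict threshold crossing and an open gate", {
  np <- neuron_params(1, tau_ref = 5)
  # V = A exactly: H(0) = 0
  expect_identical(spike_and_refractory(30, 30, 0L, np)$z, 0)
  r <- spike_and_refractory(31, 30, 0L, np)
  expect_identical(r$z, 1)
  expect_identical(r$refrac, 5L)
  # refractory gate wins over arbitrarily large potentials, counter decrements
  r2 <- spike_and_refractory(40, 30, 2L, np)
  expect_identical(r2$z, 0)
  expect_identical(r2$refrac, 1L)
})

test_that("synaptic currents sum delayed weighted spikes", {
  net <- rsnn_network(2, n_in = 2, delay_range = c(1, 1), seed = 1)
  st <- rsnn_state(net)
  # empty buffers: zero current
  expect_true(all(synaptic_current(st, net) == 0))
  # one input spike through delay 1 contributes exactly its weight
  st$in_buffer[1, 1, 1] <- 1
  expect_equal(as.numeric(synaptic_current(st, net)), net$W_in[, 1],
               tolerance = 1e-15)
  # two arrivals through different delays add (direct evaluation of the sum)
  net3 <- rsnn_network(1, n_in = 2, delay_range = c(1, 3), seed = 4)
  st3 <- rsnn_state(net3)
  st3$in_buffer[1, 1, net3$d_in[1, 1]] <- 1
  st3$in_buffer[2, 1, net3$d_in[1, 2]] <- 1
  expect_equal(as.numeric(synaptic_current(st3, net3)),
               net3$W_in[1, 1] + net3$W_in[1, 2], tolerance = 1e-15)
})

test_that("batched forward pass and stepwise simulation agree bit for bit", {
  set.seed(7)
  net <- rsnn_network(12, n_in = 6, n_out = 1, sfa_fraction = 0.5,
                      beta = 1.7, tau_a_range = c(20, 300), seed = 3)
  TT <- 80; B <- 3
  x <- array(rbinom(6 * B * TT, 1, 0.25), c(6, B, TT))
  fwd <- rsnn_forward(net, x)
  st <- rsnn_state(net, B)
  Z2 <- array(0, c(12, B, TT))
  for (t in seq_len(TT)) {
    r <- network_step(st, x[, , t], net)
    st <- r$state
    Z2[, , t] <- r$z
  }
  expect_identical(fwd$z, Z2)
  expect_identical(fwd$state$V, st$V)
  expect_identical(fwd$state$a, st$a)
  expect_identical(fwd$state$refrac, st$refrac)

  # delays > 1 exercise the ring buffers on both paths
  netd <- rsnn_network(10, n_in = 5, sfa_fraction = 0.4,
                       delay_range = c(1, 4), seed = 9)
  xd <- array(rbinom(5 * TT, 1, 0.3), c(5, 1, TT))
  fwdd <- rsnn_forward(netd, xd)
  std <- rsnn_state(netd, 1)
  Zd <- array(0, c(10, 1, TT))
  for (t in seq_len(TT)) {
    r <- network_step(std, xd[, , t], netd)
    std <- r$state
    Zd[, , t] <- r$z
  }
  expect_identical(fwdd$z, Zd)
})

test_that("an unstimulated network stays silent indefinitely", {
  net <- rsnn_network(1, n_in = 1, seed = 2)
  x <- array(0, c(1, 1, 200))
  fwd <- rsnn_forward(net, x)
  expect_identical(sum(fwd$z), 0)
  expect_true(all(fwd$V == 0))
})

test_that("constant suprathreshold drive gives the closed-form period", {
  # drive arrives as an input spike every step through one weight
  w <- 45; vth <- 30
  net <- rsnn_network(1, n_in = 1, sfa_fraction = 0, tau_ref = 5, seed = 1)
  net <- set_weights(net, W_in = matrix(w, 1, 1), W_rec = matrix(0, 1, 1))
  TT <- 400
  x <- array(1, c(1, 1, TT))
  fwd <- rsnn_forward(net, x)
  sim_spikes <- which(fwd$z[1, 1, ] > 0)

  # oracle: iterate the scalar closed-form map V <- alpha V + (1-alpha) w,
  # spike when V > vth (gate closed for n_ref steps), subtract vth
  alpha <- net$params$alpha
  V <- 0; refrac <- 0L; oracle_spikes <- integer(0)
  for (t in seq_len(TT)) {
    I <- if (t >= 2) w else 0   # delay-1 arrival
    z <- (refrac == 0L && V > vth)
    if (z) oracle_spikes <- c(oracle_spikes, t)
    V <- alpha * V + (1 - alpha) * I - vth * z
    refrac <- if (z) net$params$n_ref else max(refrac - 1L, 0L)
  }
  expect_identical(sim_spikes, oracle_spikes)
  # periodic: inter-spike intervals settle to a constant
  isi <- diff(sim_spikes)
  expect_true(length(unique(isi[-1])) == 1)
  expect_gte(isi[2], net$params$n_ref + 1)
})

test_that("spike-frequency adaptation stretches inter-spike intervals", {
  w <- 100
  net <- rsnn_network(1, n_in = 1, sfa_fraction = 1, beta = 30,
                      tau_a_range = c(3000, 3000), tau_ref = 2, seed = 1)
  net <- set_weights(net, W_in = matrix(w, 1, 1), W_rec = matrix(0, 1, 1))
  x <- array(1, c(1, 1, 4000))
  fwd <- rsnn_forward(net, x)
  isi <- diff(which(fwd$z[1, 1, ] > 0))
  expect_gte(length(isi), 100)
  # intervals lengthen toward a limit; on the 1 ms grid they quantise, so
  # the trend is read from window means and the rising threshold variable
  expect_gt(mean(tail(isi, 50)), mean(head(isi, 50)))
  expect_gt(sum(fwd$z[1, 1, 1:2000]), sum(fwd$z[1, 1, 2001:4000]))
  expect_true(all(diff(isi) >= -1))  # no systematic re-acceleration
  a <- fwd$a[1, 1, ]
  expect_true(a[100] < a[1000] && a[1000] < a[3500])
})

test_that("refractory spacing holds in every generated raster", {
  set.seed(11)
  net <- rsnn_network(20, n_in = 10, sfa_fraction = 0.5, tau_ref = 5,
                      seed = 8)
  x <- array(rbinom(10 * 2 * 300, 1, 0.5), c(10, 2, 300))
  fwd <- rsnn_forward(net, x)
  min_gap <- net$params$tau_ref / net$params$delta_t
  for (b in 1:2) for (j in 1:20) {
    tt <- which(fwd$z[j, b, ] > 0)
    if (length(tt) > 1) expect_true(all(diff(tt) >= min_gap))
  }
  expect_gt(sum(fwd$z), 0)  # the check is not vacuous
})

test_that("beta = 0 adaptive neurons reproduce plain LIF spikes bit-exactly", {
  set.seed(3)
  TT <- 150
  x <- array(rbinom(8 * TT, 1, 0.4), c(8, 1, TT))
  lif <- rsnn_network(15, n_in = 8, sfa_fraction = 0, seed = 21)
  sfa0 <- rsnn_network(15, n_in = 8, sfa_fraction = 1, beta = 0,
                       tau_a_range = c(5, 2000), seed = 21)
  f1 <- rsnn_forward(lif, x)
  f2 <- rsnn_forward(sfa0, x)
  expect_identical(f1$z, f2$z)
  expect_identical(f1$state$V, f2$state$V)
})

test_that("halving the time step converges to the same membrane trajectory", {
  # subthreshold drive; compare V at common times across delta_t = 1 and 0.5
  drive_fn <- function(t_ms) 8 * sin(t_ms / 15) + 4    # smooth drive, mV
  run <- function(dt) {
    np <- neuron_params(1, tau_m = 20, delta_t = dt)
    steps <- round(60 / dt)
    V <- 0; out <- numeric(steps)
    for (s in seq_len(steps)) {
      V <- membrane_step(V, drive_fn(s * dt), np, 0)
      out[s] <- V
    }
    out
  }
  v1 <- run(1)
  v05 <- run(0.5)[seq(2, 120, by = 2)]
  v025 <- run(0.25)[seq(4, 240, by = 4)]
  err1 <- max(abs(v1 - v025))
  err05 <- max(abs(v05 - v025))
  expect_lt(err05, err1)          # O(delta_t) convergence
  expect_lt(err1, 1.5)            # already close on the coarse grid
})
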