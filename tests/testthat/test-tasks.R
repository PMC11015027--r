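test_that("sinusoid tasks sample uniformly within the stated ranges", {
  set.seed(1)
  n <- 1e5
  A <- numeric(n); phi <- numeric(n)
  for (i in seq_len(n)) {
    tk <- sample_sinusoid_task()
    A[i] <- tk$A; phi[i] <- tk$phi
  }
  expect_true(all(A >= 0.1 & A <= 5))
  expect_true(all(phi >= 0 & phi <= pi))
  # uniform means within 4 standard errors
  expect_lt(abs(mean(A) - 2.55), 4 * sd(A) / sqrt(n))
  expect_lt(abs(mean(phi) - pi / 2), 4 * sd(phi) / sqrt(n))
  expect_identical(sample_sinusoid_task(seed = 9)$A,
                   sample_sinusoid_task(seed = 9)$A)
})

test_that("regression episodes deliver one-step-delayed feedback", {
  tk <- sample_sinusoid_task(seed = 3)
  ep <- regression_episode(tk, K = 100, seed = 4)
  expect_identical(ep$feedback[1], 0)
  expect_equal(ep$feedback[-1], ep$target[-100], tolerance = 1e-15)
  expect_equal(ep$target, tk$A * sin(tk$phi + ep$x), tolerance = 1e-15)
  # spot values of the target map (oracle: evaluate the formula)
  expect_equal(1 * sin(0 + pi / 2), 1)
  expect_equal(2 * sin(0.3 + pi / 4), 1.768979, tolerance = 1e-6)
})

test_that("arm dynamics respect equilibria and conserve energy", {
  arm <- sample_arm_task(seed = 5)
  # hanging at rest with no torque and no gravity: nothing moves
  arm0 <- arm; arm0$g <- 0
  st <- c(0.3, -0.2, 0, 0)
  expect_equal(arm_dynamics_step(st, c(0, 0), arm0), st, tolerance = 1e-12)
  # hanging straight down is an equilibrium under gravity
  acc <- arm_dynamics_step(c(0, 0, 0, 0), c(0, 0), arm)
  expect_equal(acc, c(0, 0, 0, 0), tolerance = 1e-12)
  # energy drift under zero torque < 1e-6 relative over 1 s
  st <- c(1.2, 0.5, 0, 0)
  E0 <- arm_energy(st, arm)
  traj <- arm_trajectory(arm, matrix(0, 2, 1000), state0 = st)
  E1 <- arm_energy(traj[, 1000], arm)
  # reference scale: energy above the hanging minimum
  Emin <- arm_energy(c(0, 0, 0, 0), arm)
  expect_lt(abs(E1 - E0) / abs(E0 - Emin), 1e-6)
})

test_that("arm integration converges at RK4 order", {
  arm <- sample_arm_task(seed = 7)
  tq <- torque_sequence(200, seed = 8)
  run_dt <- function(dt) {
    sub <- round(1e-3 / dt)
    st <- c(0, 0, 0, 0)
    for (t in 1:200) for (s in 1:sub) {
      st <- arm_dynamics_step(st, tq[, t], arm, dt)
    }
    st
  }
  s1 <- run_dt(1e-3)
  s05 <- run_dt(5e-4)
  expect_lt(max(abs(s1[1:2] - s05[1:2])), 1e-4)
})

test_that("torque sequences are blockwise constant and bounded", {
  tq <- torque_sequence(100, block_ms = 10, torque_max = 5, seed = 2)
  expect_equal(dim(tq), c(2, 100))
  expect_true(all(abs(tq) <= 5))
  for (b in 0:9) {
    blk <- tq[, (10 * b + 1):(10 * b + 10)]
    expect_true(all(blk == blk[, 1]))
  }
  # same torques, different arms: different trajectories
  a1 <- sample_arm_task(seed = 11); a2 <- sample_arm_task(seed = 12)
  t1 <- arm_trajectory(a1, tq); t2 <- arm_trajectory(a2, tq)
  expect_gt(max(abs(t1 - t2)), 1e-3)
})

test_that("maze steps keep the agent inside the arena and pay rewards", {
  task <- sample_maze_task(seed = 1)
  # free move in the interior
  r <- maze_step(c(0, 0), c(0.01, 0), task)
  expect_equal(r$position, c(0.01, 0))
  expect_identical(r$reward, 0)
  # wall hit: border projection and penalty
  task2 <- sample_maze_task(seed = 2)
  task2$goal <- c(-0.85, 0)   # keep the goal away from the impact point
  r2 <- maze_step(c(0.999, 0), c(0.02, 0), task2)
  expect_equal(sqrt(sum(r2$position^2)), 1, tolerance = 1e-12)
  expect_identical(r2$reward, -0.02)
  expect_true(r2$wall_hit)
  # goal hit: +1 and relocation inside the arena
  r3 <- maze_step(task$goal + c(0.25, 0), c(0.02, 0), task,
                  relocate_seed = 5)
  expect_identical(r3$reward, 1)
  expect_true(r3$relocated)
  expect_lte(sqrt(sum(r3$position^2)), 1)

  # random walks never escape the unit disk
  set.seed(9)
  pos <- c(0.5, 0.5)
  for (i in 1:2000) {
    v <- stats::rnorm(2); v <- 0.02 * v / max(1, sqrt(sum(v^2)) / 1)
    v <- v / max(1, sqrt(sum(v^2)) / 0.02)
    r <- maze_step(pos, v, task)
    pos <- r$position
    expect_lte(sqrt(sum(pos^2)), 1 + 1e-12)
  }
})

test_that("goal centres lie on the 0.85 circle, relocations fill the disk", {
  set.seed(4)
  for (i in 1:50) {
    tk <- sample_maze_task()
    expect_equal(sqrt(sum(tk$goal^2)), 0.85, tolerance = 1e-12)
  }
  pts <- replicate(4000, maze_relocate())
  rr <- sqrt(colSums(pts^2))
  expect_true(all(rr <= 1))
  # area-uniform: E[r^2] = 1/2
  expect_lt(abs(mean(rr^2) - 0.5), 4 * sd(rr^2) / sqrt(4000))
})

test_that("pattern episodes corrupt, cue and re-target correctly", {
  set.seed(6)
  eps <- lapply(1:300, function(i) build_pattern_episode())
  for (ep in eps[1:50]) {
    # partials never invent a 1
    expect_true(all(ep$partials <= ep$patterns))
    expect_true(ep$delete_index %in% 1:3)
    kept <- setdiff(1:3, ep$delete_index)
    # phase-D targets: kept indices unchanged
    expect_identical(ep$targets_D[kept, ], ep$patterns[kept, ])
    # deleted index: nearest kept pattern by Hamming distance (brute force)
    hd <- vapply(kept, function(j)
      sum(ep$patterns[ep$delete_index, ] != ep$patterns[j, ]), 0)
    best <- kept[which.min(hd)]
    expect_identical(ep$targets_D[ep$delete_index, ], ep$patterns[best, ])
  }
  # Bernoulli thinning: ~60% of source 1-bits survive
  ones <- sum(vapply(eps, function(e) sum(e$patterns), 0))
  kept1 <- sum(vapply(eps, function(e) sum(e$partials), 0))
  p <- kept1 / ones
  expect_lt(abs(p - 0.6), 4 * sqrt(0.6 * 0.4 / ones))

  # all-zero pattern has an all-zero partial
  ep0 <- build_pattern_episode(seed = 1)
  ep0$patterns[1, ] <- 0
  expect_true(all(ep0$patterns[1, ] * ep0$partials[1, ] == 0))
})

test_that("phase-D fallback ties break toward the lower kept index", {
  # construct an equidistant triple and check determinism by symmetry
  found_tie <- 0
  for (s in 1:400) {
    ep <- build_pattern_episode(seed = s)
    kept <- setdiff(1:3, ep$delete_index)
    hd <- vapply(kept, function(j)
      sum(ep$patterns[ep$delete_index, ] != ep$patterns[j, ]), 0)
    if (hd[1] == hd[2]) {
      found_tie <- found_tie + 1
      expect_identical(ep$targets_D[ep$delete_index, ],
                       ep$patterns[kept[1], ])
    }
  }
  expect_gt(found_tie, 0)
})

test_that("episode encoders produce well-formed spike tensors", {
  tasks <- lapply(1:3, function(i) sample_sinusoid_task(seed = i))
  ep <- sinusoid_episode_batch(tasks, K = 5, step_ms = 20, seed = 2)
  expect_equal(dim(ep$x), c(200, 3, 100))
  expect_true(all(ep$x %in% c(0, 1)))
  expect_equal(ep$feedback[1, ], c(0, 0, 0))
  expect_equal(ep$feedback[-1, ], ep$targets[-5, ], tolerance = 1e-15)

  pe <- pattern_episode_batch(list(build_pattern_episode(seed = 3)), seed = 4)
  expect_equal(dim(pe$x), c(140, 1, 1000))
  expect_equal(nrow(pe$windows), 10)
  expect_identical(pe$windows$phase,
                   c("A", "A", "A", "B", "B", "B", "C", "D", "D", "D"))
})
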