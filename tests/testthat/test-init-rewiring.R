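test_that("unconstrained init has the 1/sqrt(n_in) scale and is seeded", {
  w1 <- init_unconstrained(10, 1, w0 = 1, seed = 3)
  expect_equal(dim(w1), c(10, 1))
  big <- init_unconstrained(1000, 100, w0 = 1, seed = 4)
  # Monte-Carlo: sd should be 0.1 within 3 standard errors over 1e5 draws
  se <- 0.1 / sqrt(2 * length(big))
  expect_lt(abs(sd(big) - 0.1), 3 * se)
  expect_identical(init_unconstrained(50, 20, 1000, seed = 7),
                   init_unconstrained(50, 20, 1000, seed = 7))
  expect_false(identical(init_unconstrained(50, 20, 1000, seed = 7),
                         init_unconstrained(50, 20, 1000, seed = 8)))
})

test_that("Dale init: column signs, zero row sums, unit spectral radius", {
  res <- init_dale(60, 60, frac_excitatory = 0.7, w0 = 1, seed = 5)
  W <- res$W
  # every nonzero entry of column i carries sign kappa_i
  for (i in seq_len(60)) {
    nz <- W[, i][W[, i] != 0]
    expect_true(all(sign(nz) == res$sign[i]))
  }
  # rows with both signs present sum to zero (relative to row magnitude)
  rs <- rowSums(W)
  expect_lt(max(abs(rs)) / max(abs(W)), 1e-10)
  # spectral radius of the pre-w0 matrix is <= 1 (+ rounding)
  lam <- max(Mod(eigen(W, only.values = TRUE)$values))
  expect_lte(lam, 1 + 1e-9)

  # non-square shapes subselect from a larger square matrix
  rect <- init_dale(40, 25, frac_excitatory = 0.8, w0 = 2, seed = 6)
  expect_equal(dim(rect$W), c(40, 25))
  expect_length(rect$sign, 25)
  for (i in seq_len(25)) {
    nz <- rect$W[, i][rect$W[, i] != 0]
    expect_true(all(sign(nz) == rect$sign[i]))
  }

  # single-sign edge case: balancing impossible, warn and continue
  expect_warning(init_dale(10, 10, frac_excitatory = 0.999, seed = 1,
                           sign = rep(1, 10)),
                 "one sign")
})

test_that("disabling balance and normalization recovers signed Gaussians", {
  res <- init_dale(400, 400, frac_excitatory = 0.5, w0 = 1, seed = 11,
                   balance = FALSE, normalize = FALSE)
  vals <- abs(res$W)
  # |N(0,1)| has mean sqrt(2/pi)
  expect_equal(mean(vals), sqrt(2 / pi), tolerance = 0.01)
})

test_that("sparsify activates exactly the rounded count at random coords", {
  m <- sparsify(400, 400, 0.2, exclude_diag = TRUE, seed = 2)
  expect_identical(sum(m), as.integer(round(0.2 * 400 * 399)))
  expect_true(all(!diag(m)))
  # full connectivity keeps everything except the excluded diagonal
  full <- sparsify(5, 5, 1, exclude_diag = TRUE, seed = 1)
  expect_identical(sum(full), 20L)
  # different seeds, different masks, same count
  m2 <- sparsify(400, 400, 0.2, exclude_diag = TRUE, seed = 3)
  expect_false(identical(m, m2))
  expect_identical(sum(m), sum(m2))
})

test_that("rewiring conserves the active count and never flips a sign", {
  set.seed(99)
  n <- 30
  sign <- matrix(rep(ifelse(runif(n) < 0.8, 1, -1), each = n), n, n,
                 byrow = TRUE)
  mask <- sparsify(n, n, 0.2, exclude_diag = TRUE, seed = 5)
  W <- abs(matrix(rnorm(n, sd = 0.3), n, n)) * sign
  W[!mask] <- 0
  k0 <- sum(mask)
  cfg <- rewiring_config(0.2, l1 = 0.01)
  for (step in 1:1000) {
    G <- matrix(rnorm(n * n, sd = 0.5), n, n)
    r <- deepr_step(W, mask, sign, G, lr = 0.01, cfg = cfg,
                    exclude_diag = TRUE, seed = step)
    W <- r$weights; mask <- r$mask
    if (step %% 50 == 0) {
      expect_identical(sum(mask), k0)
      expect_true(all(W[!mask] == 0))
      expect_true(all(diag(mask) == FALSE))
      nz <- W != 0
      expect_true(all((sign[nz] * W[nz]) >= 0))
    }
  }
  expect_identical(sum(mask), k0)
})

test_that("rewiring step is inert for zero gradient and zero shrinkage", {
  set.seed(1)
  n <- 10
  sign <- matrix(1, n, n)
  mask <- sparsify(n, n, 0.3, seed = 2)
  W <- matrix(runif(n * n), n, n) * mask
  r <- deepr_step(W, mask, sign, matrix(0, n, n), lr = 0.1,
                  cfg = rewiring_config(0.3, l1 = 0), seed = 3)
  expect_identical(r$weights, W)
  expect_identical(r$mask, mask)
})

test_that("a sign-flipping update deactivates and reconnects elsewhere", {
  # 2x2 toy: one active excitatory weight barely positive, big gradient
  W <- matrix(c(0.001, 0, 0, 0), 2, 2)
  mask <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  sign <- matrix(1, 2, 2)
  G <- matrix(c(10, 0, 0, 0), 2, 2)   # descent pushes w negative
  r <- deepr_step(W, mask, sign, G, lr = 0.01,
                  cfg = rewiring_config(0.25, l1 = 0), seed = 4)
  expect_false(r$mask[1, 1])
  expect_identical(sum(r$mask), 1L)
  expect_identical(r$weights[r$mask], 0)     # reactivated at magnitude 0
})

test_that("a shared global budget rewires across matrices", {
  set.seed(8)
  Ws <- list(A = matrix(c(0.001, 0.5), 1, 2), B = matrix(c(0.4, 0), 1, 2))
  masks <- list(A = matrix(c(TRUE, TRUE), 1), B = matrix(c(TRUE, FALSE), 1))
  signs <- list(A = matrix(1, 1, 2), B = matrix(1, 1, 2))
  grads <- list(A = matrix(c(10, 0), 1, 2), B = matrix(0, 1, 2))
  r <- deepr_step(Ws, masks, signs, grads, lr = 0.01,
                  cfg = rewiring_config(0.5, l1 = 0), seed = 2)
  # the sign-flipped connection is severed; the replacement is drawn from
  # the shared pool across both matrices (it may land on either)
  expect_identical(sum(r$mask$A) + sum(r$mask$B), 3L)
  expect_true(all(unlist(r$weights)[!unlist(r$mask)] == 0))
  # the surviving original weights were updated, not reset
  expect_equal(r$weights$A[1, 2], 0.5, tolerance = 1e-12)
})

test_that("network construction is a pure function of its seed", {
  a <- rsnn_network(30, n_in = 10, sfa_fraction = 0.4, dale = TRUE,
                    connectivity = 0.2, delay_range = c(1, 5), seed = 42)
  b <- rsnn_network(30, n_in = 10, sfa_fraction = 0.4, dale = TRUE,
                    connectivity = 0.2, delay_range = c(1, 5), seed = 42)
  expect_identical(a$W_rec, b$W_rec)
  expect_identical(a$d_rec, b$d_rec)
  expect_identical(a$sign, b$sign)
  expect_true(all(a$W_rec[!a$mask_rec] == 0))
  expect_true(all(diag(a$mask_rec) == FALSE))
  expect_true(all(a$d_in >= 1))
})
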