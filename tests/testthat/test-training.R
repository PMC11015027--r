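# Small-scale outer-loop contracts. Networks and episodes are tiny; the
# learning-signature run lives with the acceptance checks.

small_control <- list(K = 5, step_ms = 20, n_code = 10,
                      codes = sinusoid_codes(10))

test_that("a zero learning rate leaves the weights unchanged but logs", {
  net <- rsnn_network(8, n_in = 20, n_out = 1, sfa_fraction = 0.5, seed = 2)
  h0 <- rsnn_hash(coef_net(net))
  fit <- rsnn_l2l("sinusoid", network = net, iterations = 3, batch_size = 2,
                  seed = 1, control = c(small_control, list(lr = 0)))
  expect_identical(rsnn_hash(coef_net(fit$network)), h0)
  expect_equal(nrow(fit$history), 3)
  expect_true(all(is.finite(fit$history$loss)))
})

test_that("weights stay frozen across every inner-loop episode", {
  net <- rsnn_network(8, n_in = 20, n_out = 1, sfa_fraction = 0.5, seed = 3)
  h0 <- rsnn_hash(coef_net(net))
  tasks <- lapply(1:4, function(i) sample_sinusoid_task(seed = i))
  ep <- sinusoid_episode_batch(tasks, K = 5, codes = sinusoid_codes(10),
                               seed = 5)
  fwd <- rsnn_forward(net, ep$x)
  expect_identical(rsnn_hash(coef_net(net)), h0)
  # simulation consumed the episode; the weight set is untouched bitwise
  expect_gt(sum(fwd$z) + 1, 0)
})

test_that("training reduces loss and is reproducible given the seed", {
  run <- function() {
    net <- rsnn_network(10, n_in = 20, n_out = 1, sfa_fraction = 0.4,
                        seed = 4)
    rsnn_l2l("sinusoid", network = net, iterations = 4, batch_size = 3,
             seed = 7, control = small_control)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$network$W_rec, f2$network$W_rec)
})

test_that("resuming a fit reproduces the uninterrupted run exactly", {
  net <- rsnn_network(10, n_in = 20, n_out = 1, sfa_fraction = 0.4, seed = 6)
  full <- rsnn_l2l("sinusoid", network = net, iterations = 6, batch_size = 2,
                   seed = 11, control = small_control)
  part <- rsnn_l2l("sinusoid", network = net, iterations = 3, batch_size = 2,
                   seed = 11, control = small_control)
  resumed <- rsnn_l2l("sinusoid", iterations = 3, continue_from = part)
  expect_equal(resumed$history, full$history, tolerance = 1e-15)
  expect_identical(resumed$network$W_rec, full$network$W_rec)
  expect_identical(resumed$network$b_out, full$network$b_out)
})

test_that("checkpoints round-trip through JSON with full precision", {
  skip_if_not_installed("jsonlite")
  net <- rsnn_network(6, n_in = 20, n_out = 1, seed = 8)
  fit <- rsnn_l2l("sinusoid", network = net, iterations = 2, batch_size = 2,
                  seed = 13, control = small_control)
  f <- tempfile(fileext = ".json")
  save_checkpoint(fit, f)
  fit2 <- load_checkpoint(f)
  expect_identical(fit2$network$W_rec, fit$network$W_rec)
  expect_identical(fit2$rng_state, fit$rng_state)
  # resuming from the file equals resuming in memory
  a <- rsnn_l2l("sinusoid", iterations = 2, continue_from = fit)
  b <- rsnn_l2l("sinusoid", iterations = 2, continue_from = fit2)
  expect_identical(a$network$W_rec, b$network$W_rec)
  unlink(f)
})

test_that("the fit object answers the standard modelling verbs", {
  net <- rsnn_network(10, n_in = 20, n_out = 1, sfa_fraction = 0.4, seed = 9)
  fit <- rsnn_l2l("sinusoid", network = net, iterations = 3, batch_size = 2,
                  seed = 17, control = small_control)
  expect_s3_class(fit, "rsnn_l2l")
  expect_output(print(fit), "task family")
  s <- summary(fit)
  expect_s3_class(s, "summary.rsnn_l2l")
  expect_true(is.finite(s$loss_ratio))
  cf <- coef(fit)
  expect_named(cf, c("W_in", "W_rec", "W_out", "b_out"))
  p <- predict(fit, n_tasks = 2, seed = 3)
  expect_equal(dim(p$predictions), c(5, 2))
  expect_identical(predict(fit, n_tasks = 2, seed = 3)$mse, p$mse)
  r <- residuals(fit, n_tasks = 2, seed = 3)
  expect_equal(r, p$predictions - p$targets, tolerance = 1e-15)
  sim <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sim, 2)
  expect_equal(dim(sim[[1]]$spikes), c(10, 100))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("arm and pattern families train end to end at toy scale", {
  arm_net <- rsnn_network(10, n_in = 40, n_out = 2, sfa_fraction = 0.5,
                          seed = 10)
  fa <- rsnn_l2l("arm", network = arm_net, iterations = 2, batch_size = 2,
                 seed = 19,
                 control = list(duration_ms = 300, n_code = 10,
                                codes = arm_codes(10)))
  expect_equal(nrow(fa$history), 2)
  expect_true(all(is.finite(fa$history$loss)))

  pat_net <- rsnn_network(12, n_in = 140, n_out = 25, sfa_fraction = 0.5,
                          seed = 11)
  fp <- rsnn_l2l("pattern", network = pat_net, iterations = 2,
                 batch_size = 2, seed = 23, control = list(item_ms = 20))
  expect_true(all(is.finite(fp$history$loss)))
  expect_true(all(fp$history$acc_B >= 0 & fp$history$acc_B <= 1))
})

test_that("the policy-gradient loop trains the maze family at toy scale", {
  net <- rsnn_network(12, n_in = 160, n_out = 5, sfa_fraction = 0.3,
                      beta = 1.7, tau_a_range = c(1200, 1200),
                      tau_m = c(15, 30), tau_ref = 3, dale = TRUE,
                      connectivity = 0.3, delay_range = c(1, 10), seed = 12)
  fit <- rsnn_l2l("maze", network = net, iterations = 2, seed = 29,
                  control = list(T = 60, K_episodes = 2),
                  rewiring = rewiring_config(0.3, l1 = 0.01))
  expect_equal(nrow(fit$history), 2)
  expect_true(all(is.finite(fit$history$loss)))
  # rewiring respected Dale's law throughout
  nz <- fit$network$W_rec != 0
  expect_true(all(fit$network$sign_rec[nz] * fit$network$W_rec[nz] >= 0))
  expect_identical(sum(fit$network$mask_in) + sum(fit$network$mask_rec) +
                     sum(fit$network$mask_out),
                   sum(net$mask_in) + sum(net$mask_rec) + sum(net$mask_out))
  # exploration noise is trainable
  expect_false(identical(fit$network$nu, rep(0.03, 12)))
})

test_that("probability ratios are exactly one when re-evaluated in place", {
  net <- rsnn_network(10, n_in = 160, n_out = 5, sfa_fraction = 0.3,
                      tau_m = c(15, 30), tau_ref = 3,
                      delay_range = c(1, 10), seed = 13)
  net <- set_weights(net, nu = rep(0.03, 10))
  cfg <- utils::modifyList(family_defaults("maze"),
                           list(T = 50, K_episodes = 2))
  set.seed(31)
  buf <- collect_maze_episodes(net, cfg)
  res <- maze_gradients(net, buf, cfg)
  expect_equal(max(abs(res$ratio - 1)), 0, tolerance = 1e-12)
  expect_true(all(is.finite(res$grads$nu)))
})

test_that("preset configurations validate and rebuild identically", {
  for (nm in c("sinusoid-paper", "arm-paper", "maze-paper", "pattern-paper",
               "sinusoid-desk", "maze-desk")) {
    cfg <- rsnn_preset(nm)
    expect_s3_class(validate_config(cfg), "rsnn_config")
  }
  # config -> network is pure
  cfg <- rsnn_preset("sinusoid-desk")
  n1 <- network_from_config(cfg, seed = 5)
  n2 <- network_from_config(cfg, seed = 5)
  expect_identical(n1$W_rec, n2$W_rec)
})

test_that("configured runs write metrics and resumable checkpoints", {
  skip_if_not_installed("jsonlite")
  cfg <- rsnn_preset("sinusoid-desk")
  cfg$network$n_rec <- 8
  cfg$training$K <- 5
  cfg$training$batch_size <- 2
  td <- tempfile()
  fit <- rsnn_run(cfg, seed = 3, out_dir = td, iterations = 4)
  expect_true(file.exists(file.path(td, "metrics.csv")))
  expect_true(file.exists(file.path(td, "checkpoint.json")))
  # run 2 + resume 2 == run 4
  td2 <- tempfile()
  f2 <- rsnn_run(cfg, seed = 3, out_dir = td2, iterations = 2)
  f2b <- rsnn_run(cfg, seed = 3, iterations = 2,
                  resume_from = file.path(td2, "checkpoint.json"))
  expect_identical(f2b$network$W_rec, fit$network$W_rec)
  unlink(td, recursive = TRUE); unlink(td2, recursive = TRUE)
})
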