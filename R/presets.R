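#' Shipped run configurations
#'
#' Complete run configurations for the four task families at two scales:
#' \code{*-paper} presets carry the published full-scale hyperparameters
#' (network size, SFA fraction, adaptation time constants, thresholds,
#' schedules); \code{*-desk} presets are small versions of the same
#' structure for interactive use and testing (see the methods vignette for
#' the choice of desk sizes).
#'
#' @param name preset name: one of
#'   "sinusoid-paper", "arm-paper", "maze-paper", "pattern-paper",
#'   "sinusoid-desk", "arm-desk", "maze-desk", "pattern-desk".
#' @return a run-configuration list (class \code{rsnn_config}) accepted by
#'   \code{\link{rsnn_run}}.
#' @export
rsnn_preset <- function(name) {
  presets <- list(
    "sinusoid-paper" = list(
      family = "sinusoid",
      network = list(n_rec = 100, n_in = 200, n_out = 1, sfa_fraction = 0.4,
                     beta = 1.6, tau_a_range = c(1, 3000), tau_m = 20,
                     v_th = 30, tau_ref = 5, delay_range = c(1, 1),
                     gamma = 0.3),
      training = list(iterations = 5000, batch_size = 100, lr = 1e-3,
                      K = 500, step_ms = 20, lambda_reg = 30, f0 = 20)
    ),
    "arm-paper" = list(
      family = "arm",
      network = list(n_rec = 600, n_in = 400, n_out = 2, sfa_fraction = 0.5,
                     beta = 1.7, tau_a_range = c(1, 600), tau_m = 20,
                     v_th = 30, tau_ref = 5, delay_range = c(1, 1),
                     gamma = 0.3),
      training = list(iterations = 5000, batch_size = 80, lr = 1e-3,
                      duration_ms = 30000, feedback_delay_ms = 100,
                      tau_trace = 50)
    ),
    "maze-paper" = list(
      family = "maze",
      network = list(n_rec = 400, n_in = 160, n_out = 5,
                     n_excitatory_lif = 200, n_inhibitory_lif = 80,
                     n_excitatory_sfa = 120,
                     sfa_fraction = 0.3, beta = 1.7,
                     tau_a_range = c(1200, 1200), tau_m = c(15, 30),
                     v_th = 30, tau_ref = 3, delay_range = c(1, 10),
                     dale = TRUE, connectivity = 0.2, gamma = 0.3),
      training = list(iterations = 20000, K_episodes = 10, T = 2000,
                      eta = 0.99, epsilon = 0.2, mu_v = 1, mu_e = 0.001,
                      mu_firing = 100, f0 = 10, nu_init = 0.03,
                      a_scale = 0.02, lr = 0.01, lr_halve_every = 5000,
                      adam_eps = 1e-5, l1 = 0.01, temperature = 0)
    ),
    "pattern-paper" = list(
      family = "pattern",
      network = list(n_rec = 300, n_in = 140, n_out = 25,
                     sfa_fraction = 0.5, beta = 1.7,
                     tau_a_range = c(1, 1000), tau_m = 20, v_th = 30,
                     tau_ref = 5, delay_range = c(1, 1), gamma = 0.3),
      training = list(iterations = 100000, batch_size = 100, lr = 1e-3,
                      item_ms = 100, tau_trace = 100, lambda_reg = 5,
                      f0 = 20)
    ),
    "sinusoid-desk" = list(
      family = "sinusoid",
      network = list(n_rec = 80, n_in = 200, n_out = 1, sfa_fraction = 0.4,
                     beta = 1.6, tau_a_range = c(1, 3000), tau_m = 20,
                     v_th = 30, tau_ref = 5, delay_range = c(1, 1),
                     gamma = 0.3),
      training = list(iterations = 200, batch_size = 20, lr = 1e-2,
                      lr_halve_every = 100, K = 100, step_ms = 20,
                      lambda_reg = 6, f0 = 20)
    ),
    "arm-desk" = list(
      family = "arm",
      network = list(n_rec = 60, n_in = 400, n_out = 2, sfa_fraction = 0.5,
                     beta = 1.7, tau_a_range = c(1, 600), tau_m = 20,
                     v_th = 30, tau_ref = 5, delay_range = c(1, 1),
                     gamma = 0.3),
      training = list(iterations = 20, batch_size = 5, lr = 1e-3,
                      duration_ms = 1000, feedback_delay_ms = 100,
                      tau_trace = 50)
    ),
    "maze-desk" = list(
      family = "maze",
      network = list(n_rec = 40, n_in = 160, n_out = 5, sfa_fraction = 0.3,
                     beta = 1.7, tau_a_range = c(1200, 1200),
                     tau_m = c(15, 30), v_th = 30, tau_ref = 3,
                     delay_range = c(1, 10), dale = TRUE,
                     connectivity = 0.2, gamma = 0.3),
      training = list(iterations = 3, K_episodes = 3, T = 200,
                      eta = 0.99, epsilon = 0.2, mu_v = 1, mu_e = 0.001,
                      mu_firing = 100, f0 = 10, nu_init = 0.03,
                      a_scale = 0.02, lr = 0.01, lr_halve_every = 5000,
                      adam_eps = 1e-5, l1 = 0.01, temperature = 0)
    ),
    "pattern-desk" = list(
      family = "pattern",
      network = list(n_rec = 60, n_in = 140, n_out = 25,
                     sfa_fraction = 0.5, beta = 1.7,
                     tau_a_range = c(1, 1000), tau_m = 20, v_th = 30,
                     tau_ref = 5, delay_range = c(1, 1), gamma = 0.3),
      training = list(iterations = 10, batch_size = 10, lr = 1e-3,
                      item_ms = 50, tau_trace = 100, lambda_reg = 5,
                      f0 = 20)
    )
  )
  if (!name %in% names(presets)) {
    stop_cfg("unknown preset '%s'; available: %s", name,
             paste(names(presets), collapse = ", "))
  }
  cfg <- presets[[name]]
  cfg$preset <- name
  cfg$seed <- 1L
  class(cfg) <- "rsnn_config"
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' Schema check applied before any compute: required sections and fields,
#' value ranges, and family-consistent dimensions.
#'
#' @param cfg a config list.
#' @return the config, invisibly classed \code{rsnn_config}.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$family), !is.null(cfg$network),
            !is.null(cfg$training))
  stopifnot(cfg$family %in% c("sinusoid", "arm", "pattern", "maze"))
  nw <- cfg$network
  stopifnot(nw$n_rec >= 1, nw$n_in >= 1, nw$n_out >= 1,
            nw$sfa_fraction >= 0, nw$sfa_fraction <= 1,
            nw$v_th > 0, nw$tau_ref >= 0, nw$gamma > 0, nw$gamma < 1)
  tr <- cfg$training
  stopifnot((tr$iterations %||% 1) >= 1, (tr$lr %||% 1e-3) > 0)
  if (!is.null(tr$eta)) stopifnot(tr$eta > 0, tr$eta < 1)
  class(cfg) <- "rsnn_config"
  invisible(cfg)
}

#' Build the network described by a run configuration
#' @param cfg an \code{rsnn_config}.
#' @param seed overrides the config seed if given.
#' @return an \code{\link{rsnn_network}}.
#' @export
network_from_config <- function(cfg, seed = NULL) {
  nw <- cfg$network
  rsnn_network(n_rec = nw$n_rec, n_in = nw$n_in, n_out = nw$n_out,
               sfa_fraction = nw$sfa_fraction, beta = nw$beta,
               tau_a_range = nw$tau_a_range, tau_m = nw$tau_m,
               v_th = nw$v_th, tau_ref = nw$tau_ref,
               dale = isTRUE(nw$dale),
               frac_excitatory = nw$frac_excitatory %||% 0.8,
               connectivity = nw$connectivity %||% 1,
               delay_range = nw$delay_range, gamma = nw$gamma,
               seed = seed %||% cfg$seed)
}

#' Execute a configured run
#'
#' Deterministic given config and seed: builds the network, trains for the
#' configured number of iterations (optionally resuming from a checkpoint)
#' and writes text artifacts (metrics CSV, JSON checkpoint) to
#' \code{out_dir}.
#'
#' @param cfg an \code{rsnn_config} (e.g. from \code{\link{rsnn_preset}}).
#' @param seed master seed (overrides the config's).
#' @param out_dir output directory, or NULL for no files.
#' @param iterations optional override.
#' @param resume_from path to a checkpoint JSON written by a previous run.
#' @param verbose passed to \code{\link{rsnn_l2l}}.
#' @return the \code{rsnn_l2l} fit, invisibly.
#' @export
rsnn_run <- function(cfg, seed = NULL, out_dir = NULL, iterations = NULL,
                     resume_from = NULL, verbose = 0) {
  cfg <- validate_config(cfg)
  seed <- seed %||% cfg$seed
  tr <- cfg$training
  iters <- iterations %||% tr$iterations
  control <- tr[setdiff(names(tr), c("iterations", "batch_size"))]
  rewiring <- NULL
  if (isTRUE(cfg$network$dale)) {
    rewiring <- rewiring_config(cfg$network$connectivity %||% 0.2,
                                l1 = tr$l1 %||% 0.01,
                                temperature = tr$temperature %||% 0)
    control <- control[setdiff(names(control), c("l1", "temperature"))]
  }
  continue <- NULL
  if (!is.null(resume_from)) {
    continue <- load_checkpoint(resume_from)
  }
  fit <- rsnn_l2l(cfg$family,
                  network = if (is.null(continue))
                    network_from_config(cfg, seed) else NULL,
                  iterations = iters,
                  batch_size = tr$batch_size,
                  seed = seed, control = control, rewiring = rewiring,
                  continue_from = continue, verbose = verbose)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fit$history,
                     file.path(out_dir, "metrics.csv"), row.names = FALSE)
    save_checkpoint(fit, file.path(out_dir, "checkpoint.json"))
  }
  invisible(fit)
}
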