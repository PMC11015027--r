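#' Construct a recurrent spiking network
#'
#' Builds the full weight set (input, recurrent, readout), integer synaptic
#' delays, optional Dale's-law sign structure and sparse connectivity masks,
#' together with the per-neuron membrane and adaptation parameters. A fixed
#' fraction of neurons carries spike-frequency adaptation (SFA); their
#' adaptation time constants are spread evenly over \code{tau_a_range},
#' which lets different neurons forget on different time scales.
#'
#' Voltages are in mV. The weight scale defaults to \code{w0 = 1000} mV
#' (i.e. 1 Volt): with the membrane update's \code{(1 - alpha)} factor a
#' single spike through a typical weight moves the potential by a few mV
#' against the 30 mV threshold, which produces realistic sparse firing at
#' initialisation.
#'
#' @param n_rec number of recurrent neurons.
#' @param n_in number of input channels.
#' @param n_out number of readout channels.
#' @param sfa_fraction fraction of neurons with SFA (placed at the end of
#'   the index range).
#' @param beta SFA threshold amplitude in mV (applied to the SFA subset).
#' @param tau_a_range range (or single value) of adaptation time constants
#'   in ms, spread evenly across the SFA neurons.
#' @param tau_m membrane time constant in ms; a length-2 vector is read as a
#'   range sampled uniformly per neuron.
#' @param v_th baseline threshold (mV).
#' @param tau_ref refractory period (ms).
#' @param delta_t simulation step (ms).
#' @param dale constrain signs by Dale's law (excitatory/inhibitory neurons).
#' @param frac_excitatory fraction of excitatory neurons in Dale mode.
#' @param connectivity fraction of active connections (1 = dense). Applied
#'   globally to input, recurrent and readout matrices.
#' @param delay_range integer delay range in ms for input and recurrent
#'   synapses, sampled uniformly; \code{c(1, 1)} gives fixed 1 ms delays.
#' @param w0 weight scale (mV).
#' @param gamma surrogate-derivative dampening factor used when the network
#'   is trained (0 < gamma < 1).
#' @param seed integer seed; construction is a pure function of the
#'   arguments and the seed.
#' @return an object of class \code{rsnn_network}.
#' @export
rsnn_network <- function(n_rec, n_in, n_out = 1, sfa_fraction = 0,
                         beta = 1.7, tau_a_range = c(1, 1000), tau_m = 20,
                         v_th = 30, tau_ref = 5, delta_t = 1, dale = FALSE,
                         frac_excitatory = 0.8, connectivity = 1,
                         delay_range = c(1, 1), w0 = 1000, gamma = 0.3,
                         seed = 1) {
  stopifnot(n_rec >= 1, n_in >= 1, n_out >= 1,
            sfa_fraction >= 0, sfa_fraction <= 1, gamma > 0, gamma < 1)
  n_sfa <- round(sfa_fraction * n_rec)
  beta_vec <- c(rep(0, n_rec - n_sfa), rep(beta, n_sfa))
  tau_a_range <- rep_len(tau_a_range, 2)
  tau_a_vec <- rep(1000, n_rec)
  if (n_sfa > 0) {
    tau_a_vec[(n_rec - n_sfa + 1):n_rec] <-
      if (n_sfa == 1) mean(tau_a_range) else
        seq(tau_a_range[1], tau_a_range[2], length.out = n_sfa)
  }
  tm <- if (length(tau_m) == 2 && tau_m[1] != tau_m[2]) {
    with_seed(derive_seed(seed, "tau_m"),
              stats::runif(n_rec, tau_m[1], tau_m[2]))
  } else rep(tau_m[1], n_rec)

  params <- neuron_params(n_rec, tau_m = tm, v_th = v_th, tau_ref = tau_ref,
                          delta_t = delta_t)
  adapt <- adaptation_params(n_rec, beta = beta_vec, tau_a = tau_a_vec,
                             delta_t = delta_t)

  if (dale) {
    kap_seed <- derive_seed(seed, "dale")
    rec <- init_dale(n_rec, n_rec, frac_excitatory, w0, seed = kap_seed)
    kappa <- rec$sign
    W_rec <- rec$W
    inres <- init_dale(n_rec, n_in, frac_excitatory, w0,
                       seed = derive_seed(seed, "w_in"))
    W_in <- inres$W
    kappa_in <- inres$sign
    W_out <- init_dale(n_out, n_rec, frac_excitatory, w0 / 1000,
                       seed = derive_seed(seed, "w_out"), sign = kappa)$W
  } else {
    kappa <- NULL
    W_in <- init_unconstrained(n_rec, n_in, w0, derive_seed(seed, "w_in"))
    W_rec <- init_unconstrained(n_rec, n_rec, w0, derive_seed(seed, "w_rec"))
    W_out <- init_unconstrained(n_out, n_rec, w0 / 1000,
                                derive_seed(seed, "w_out"))
  }
  diag(W_rec) <- 0

  # sign matrices: per-column kappa where Dale-constrained, else the sign at
  # initialisation (inherited by any rewired connection at that coordinate)
  sgn <- function(W) ifelse(W >= 0, 1, -1)
  sign_rec <- if (dale) matrix(kappa, n_rec, n_rec, byrow = TRUE) else sgn(W_rec)
  sign_out <- if (dale) matrix(kappa, n_out, n_rec, byrow = TRUE) else sgn(W_out)
  sign_in <- if (dale) matrix(kappa_in, n_rec, n_in, byrow = TRUE) else sgn(W_in)

  mask_in <- matrix(TRUE, n_rec, n_in)
  mask_rec <- matrix(TRUE, n_rec, n_rec); diag(mask_rec) <- FALSE
  mask_out <- matrix(TRUE, n_out, n_rec)
  if (connectivity < 1) {
    mask_in <- sparsify(n_rec, n_in, connectivity,
                        seed = derive_seed(seed, "mask_in"))
    mask_rec <- sparsify(n_rec, n_rec, connectivity, exclude_diag = TRUE,
                         seed = derive_seed(seed, "mask_rec"))
    mask_out <- sparsify(n_out, n_rec, connectivity,
                         seed = derive_seed(seed, "mask_out"))
    W_in[!mask_in] <- 0
    W_rec[!mask_rec] <- 0
    W_out[!mask_out] <- 0
  }

  delay_range <- as.integer(rep_len(delay_range, 2))
  stopifnot(delay_range[1] >= 1, delay_range[2] >= delay_range[1])
  samp_d <- function(nr, nc, label) {
    if (delay_range[1] == delay_range[2]) {
      matrix(delay_range[1], nr, nc)
    } else {
      with_seed(derive_seed(seed, label),
                matrix(sample(delay_range[1]:delay_range[2], nr * nc,
                              replace = TRUE), nr, nc))
    }
  }
  d_in <- samp_d(n_rec, n_in, "d_in")
  d_rec <- samp_d(n_rec, n_rec, "d_rec")

  net <- structure(list(
    n_rec = as.integer(n_rec), n_in = as.integer(n_in),
    n_out = as.integer(n_out), n_sfa = as.integer(n_sfa),
    params = params, adapt = adapt,
    W_in = W_in, W_rec = W_rec, W_out = W_out,
    b_out = rep(0, n_out),
    d_in = d_in, d_rec = d_rec,
    sign = kappa, sign_in = sign_in, sign_rec = sign_rec,
    sign_out = sign_out,
    mask_in = mask_in, mask_rec = mask_rec, mask_out = mask_out,
    dale = dale, connectivity = connectivity,
    w0 = w0, gamma = gamma, nu = NULL, seed = seed
  ), class = "rsnn_network")
  refresh_delay_groups(net)
}

#' @keywords internal
refresh_delay_groups <- function(net) {
  mk <- function(W, D) {
    lapply(sort(unique(as.vector(D))), function(d) {
      list(d = d, sel = D == d, W = W * (D == d))
    })
  }
  net$in_groups <- mk(net$W_in, net$d_in)
  net$rec_groups <- mk(net$W_rec, net$d_rec)
  net
}

#' Set the weights of a network
#'
#' Replaces weight matrices (keeping masks/delays) and refreshes the cached
#' per-delay weight groups used by the simulator.
#' @param net an \code{\link{rsnn_network}}.
#' @param W_in,W_rec,W_out,b_out,nu replacement values (NULL = keep).
#' @return the updated network.
#' @export
set_weights <- function(net, W_in = NULL, W_rec = NULL, W_out = NULL,
                        b_out = NULL, nu = NULL) {
  if (!is.null(W_in)) net$W_in <- W_in
  if (!is.null(W_rec)) { diag(W_rec) <- 0; net$W_rec <- W_rec }
  if (!is.null(W_out)) net$W_out <- matrix(W_out, net$n_out, net$n_rec)
  if (!is.null(b_out)) net$b_out <- as.numeric(b_out)
  if (!is.null(nu)) net$nu <- as.numeric(nu)
  refresh_delay_groups(net)
}

#' @export
print.rsnn_network <- function(x, ...) {
  cat(sprintf("Recurrent spiking network: %d neurons (%d with SFA), %d inputs, %d outputs\n",
              x$n_rec, x$n_sfa, x$n_in, x$n_out))
  cat(sprintf("  v_th %.1f mV, tau_ref %.0f ms, delta_t %.2g ms, gamma %.2f\n",
              x$params$v_th, x$params$tau_ref, x$params$delta_t, x$gamma))
  if (x$dale) cat(sprintf("  Dale's law: %d excitatory / %d inhibitory neurons\n",
                          sum(x$sign > 0), sum(x$sign < 0)))
  if (x$connectivity < 1)
    cat(sprintf("  sparse connectivity: %.0f%% of connections active\n",
                100 * x$connectivity))
  invisible(x)
}
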