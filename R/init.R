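#' Gaussian weight initialisation
#'
#' Entries are i.i.d. \code{N(0, (w0 / sqrt(n_in))^2)} where \code{n_in} is
#' the number of afferents of the matrix, i.e. its number of columns. This
#' scaling yields realistic firing rates at initialisation and keeps the
#' unrolled network trainable.
#'
#' @param n_rows,n_cols matrix shape (columns = afferents).
#' @param w0 weight scale (voltage-equivalent, mV).
#' @param seed integer seed; same seed gives a bit-identical matrix.
#' @return an \code{n_rows x n_cols} weight matrix.
#' @export
init_unconstrained <- function(n_rows, n_cols, w0 = 1000, seed = NULL) {
  stopifnot(n_cols >= 1, n_rows >= 1)
  with_seed(seed, matrix(stats::rnorm(n_rows * n_cols, sd = w0 / sqrt(n_cols)),
                         n_rows, n_cols))
}

#' Signed (Dale's law) weight initialisation
#'
#' Every outgoing weight of neuron i carries the neuron's sign
#' \code{kappa_i}. Construction: (1) signs sampled Bernoulli with
#' \code{P(+1) = frac_excitatory} (or supplied); (2) entries
#' \code{kappa_i * |N(0,1)|} column-wise; (3) each row is balanced so
#' excitatory and inhibitory input cancel exactly (rows lacking either sign
#' are left alone; the balancing rescales the inhibitory group, which
#' preserves every entry's sign -- see the methods vignette); (4) the matrix
#' is divided by the modulus of its largest eigenvalue, so the spectral
#' radius is 1; for non-square shapes a large enough square matrix is built
#' first and rows/columns are subselected uniformly; (5) scaled by
#' \code{w0}.
#'
#' @param n_rows,n_cols matrix shape (columns = presynaptic neurons).
#' @param frac_excitatory probability of a +1 (excitatory) sign.
#' @param w0 weight scale (mV).
#' @param seed integer seed.
#' @param sign optional pre-assigned length-\code{n_cols} sign vector in
#'   \{-1, +1\} (shared across the matrices of one network).
#' @param balance,normalize test hooks; disabling both reduces the
#'   statistics to column-signed Gaussian magnitudes.
#' @return list with \code{W} (n_rows x n_cols) and \code{sign}
#'   (length n_cols).
#' @export
init_dale <- function(n_rows, n_cols, frac_excitatory = 0.8, w0 = 1000,
                      seed = NULL, sign = NULL, balance = TRUE,
                      normalize = TRUE) {
  stopifnot(frac_excitatory > 0, frac_excitatory < 1)
  with_seed(seed, {
    m <- max(n_rows, n_cols)
    kappa <- if (is.null(sign)) {
      ifelse(stats::runif(m) < frac_excitatory, 1, -1)
    } else {
      stopifnot(length(sign) == n_cols, all(sign %in% c(-1, 1)))
      if (m > n_cols) c(sign, ifelse(stats::runif(m - n_cols) < frac_excitatory, 1, -1))
      else sign
    }
    W <- abs(matrix(stats::rnorm(m * m), m, m)) *
      matrix(kappa, m, m, byrow = TRUE)
    if (balance) {
      pos <- kappa > 0
      if (all(pos) || !any(pos)) {
        warning("all neurons share one sign; row balancing skipped")
      } else {
        se <- rowSums(W[, pos, drop = FALSE])
        si <- rowSums(W[, !pos, drop = FALSE])  # negative
        ok <- se > 0 & si < 0
        scale <- ifelse(ok, -se / si, 1)
        W[, !pos] <- W[, !pos, drop = FALSE] * scale
      }
    }
    if (normalize) {
      lam <- max(Mod(eigen(W, only.values = TRUE)$values))
      if (lam > 0) W <- W / lam
    }
    rows <- if (m > n_rows) sort(sample.int(m, n_rows)) else seq_len(n_rows)
    cols <- if (m > n_cols) sort(sample.int(m, n_cols)) else seq_len(n_cols)
    list(W = w0 * W[rows, cols, drop = FALSE], sign = kappa[cols])
  })
}

#' Sparse connectivity mask
#'
#' Samples a binary mask with exactly
#' \code{round(connectivity * n_eligible)} active coordinates drawn
#' uniformly; for a recurrent matrix the diagonal is excluded from the
#' eligible set (no self-connections).
#'
#' @param n_rows,n_cols mask shape.
#' @param connectivity target fraction of active connections in (0, 1].
#' @param exclude_diag exclude the diagonal (use for recurrent matrices).
#' @param seed integer seed.
#' @return a logical \code{n_rows x n_cols} matrix.
#' @export
sparsify <- function(n_rows, n_cols, connectivity, exclude_diag = FALSE,
                     seed = NULL) {
  stopifnot(connectivity > 0, connectivity <= 1)
  with_seed(seed, {
    eligible <- matrix(TRUE, n_rows, n_cols)
    if (exclude_diag) diag(eligible) <- FALSE
    idx <- which(eligible)
    k <- round(connectivity * length(idx))
    mask <- matrix(FALSE, n_rows, n_cols)
    mask[sample(idx, k)] <- TRUE
    mask
  })
}

#' Rewiring configuration
#'
#' @param connectivity target fraction of active connections in (0, 1].
#' @param l1 L1 shrinkage coefficient applied to active weights.
#' @param temperature rewiring noise scale (0 disables the noise term).
#' @return an object of class \code{rewiring_config}.
#' @export
rewiring_config <- function(connectivity = 0.2, l1 = 0.01, temperature = 0) {
  stopifnot(connectivity > 0, connectivity <= 1, l1 >= 0, temperature >= 0)
  structure(list(connectivity = connectivity, l1 = l1,
                 temperature = temperature), class = "rewiring_config")
}

#' One sparse-rewiring training step
#'
#' Applies a gradient step with L1 shrinkage to the active weights, then
#' enforces sign constraints by rewiring: any active weight whose update
#' would flip it against its sign is disconnected (set to 0, dropped from
#' the mask) and, for each disconnection, one currently inactive coordinate
#' is drawn uniformly and activated at magnitude 0 with its stored sign.
#' The number of active connections is conserved exactly and no sign ever
#' changes. With \code{temperature = 0} the update is deterministic apart
#' from the reconnection draw.
#'
#' Matrices may be passed as a named list sharing one global reconnection
#' budget (the pool of inactive coordinates spans all of them), matching a
#' single global connectivity level.
#'
#' @param weights weight matrix, or named list of matrices.
#' @param mask logical mask (or list), same shapes as \code{weights}.
#' @param sign sign matrix in \{-1,+1\} (or list). For column-signed (Dale)
#'   matrices every entry of column i is \code{kappa_i}.
#' @param grads loss gradients (or list), same shapes.
#' @param lr learning-rate / step-size multiplier.
#' @param cfg a \code{\link{rewiring_config}}.
#' @param exclude_diag logical (or list): diagonal never eligible.
#' @param seed integer seed for the reconnection draw.
#' @return list with updated \code{weights} and \code{mask} (lists iff the
#'   input was a list).
#' @export
deepr_step <- function(weights, mask, sign, grads, lr, cfg = rewiring_config(),
                       exclude_diag = FALSE, seed = NULL) {
  single <- is.matrix(weights)
  if (single) {
    weights <- list(W = weights); mask <- list(W = mask)
    sign <- list(W = sign); grads <- list(W = grads)
    exclude_diag <- list(W = exclude_diag)
  }
  if (!is.list(exclude_diag)) {
    exclude_diag <- as.list(rep(exclude_diag, length(weights)))
  }
  nm <- names(weights)
  with_seed(seed, {
    removed <- 0L
    eligible_pool <- list()
    for (k in seq_along(weights)) {
      W <- weights[[k]]; M <- mask[[k]]; S <- sign[[k]]; G <- grads[[k]]
      act <- which(M)
      w_new <- W[act] - lr * G[act] - lr * cfg$l1 * S[act]
      if (cfg$temperature > 0) {
        w_new <- w_new + sqrt(2 * lr * cfg$temperature) *
          stats::rnorm(length(act))
      }
      flip <- S[act] * w_new < 0
      W[act] <- ifelse(flip, 0, w_new)
      M[act[flip]] <- FALSE
      removed <- removed + sum(flip)
      inact <- matrix(TRUE, nrow(M), ncol(M))
      inact[M] <- FALSE
      if (isTRUE(exclude_diag[[k]])) diag(inact) <- FALSE
      eligible_pool[[k]] <- which(inact)
      weights[[k]] <- W; mask[[k]] <- M
    }
    if (removed > 0L) {
      pool <- do.call(rbind, lapply(seq_along(weights), function(k) {
        if (length(eligible_pool[[k]]) == 0) return(NULL)
        cbind(k, eligible_pool[[k]])
      }))
      if (is.null(pool) || nrow(pool) < removed) {
        warning("no inactive coordinates available; reconnection skipped")
        take <- if (is.null(pool)) integer(0) else seq_len(nrow(pool))
      } else {
        take <- sample.int(nrow(pool), removed)
      }
      for (r in take) {
        k <- pool[r, 1]; idx <- pool[r, 2]
        mask[[k]][idx] <- TRUE
        weights[[k]][idx] <- 0
      }
    }
  })
  if (single) list(weights = weights$W, mask = mask$W)
  else list(weights = weights, mask = mask)
}
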