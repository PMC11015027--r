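# Text-based external interfaces: spike-raster event lists (CSV), weight
# summaries and run checkpoints (JSON).

#' Convert a spike matrix to an event list
#'
#' @param z binary spike matrix \code{n x T} (neurons x steps).
#' @param delta_t step in ms.
#' @return data frame with \code{time_ms} and \code{neuron_id}, ordered by
#'   time then neuron.
#' @export
spikes_to_events <- function(z, delta_t = 1) {
  idx <- which(z != 0, arr.ind = TRUE)
  out <- data.frame(time_ms = idx[, 2] * delta_t, neuron_id = idx[, 1])
  out[order(out$time_ms, out$neuron_id), , drop = FALSE]
}

#' Write a spike raster to CSV
#' @param z binary spike matrix \code{n x T}.
#' @param path output file.
#' @param delta_t step in ms.
#' @export
write_raster_csv <- function(z, path, delta_t = 1) {
  utils::write.csv(spikes_to_events(z, delta_t), path, row.names = FALSE)
  invisible(path)
}

#' Read a spike raster from a CSV event list
#' @param path CSV written by \code{\link{write_raster_csv}}.
#' @param n_neurons,n_steps raster dimensions.
#' @param delta_t step in ms.
#' @return binary spike matrix \code{n_neurons x n_steps}.
#' @export
read_raster_csv <- function(path, n_neurons, n_steps, delta_t = 1) {
  ev <- utils::read.csv(path)
  z <- matrix(0, n_neurons, n_steps)
  z[cbind(ev$neuron_id, round(ev$time_ms / delta_t))] <- 1
  z
}

#' Human-readable summary of a weight set
#'
#' @param net an \code{\link{rsnn_network}}.
#' @return list with shapes, active-connection fractions and the recurrent
#'   spectral radius (in units of w0).
#' @export
weight_summary <- function(net) {
  list(
    shapes = list(W_in = dim(net$W_in), W_rec = dim(net$W_rec),
                  W_out = dim(net$W_out)),
    connectivity = list(
      W_in = mean(net$mask_in), W_rec = mean(net$mask_rec),
      W_out = mean(net$mask_out)),
    spectral_radius_rec = max(Mod(eigen(net$W_rec / net$w0,
                                        only.values = TRUE)$values)),
    w0 = net$w0, dale = net$dale, seed = net$seed
  )
}

#' Save a fit checkpoint as JSON
#'
#' Full-precision JSON serialisation of the fit (weights, delays, signs,
#' masks, optimizer moments, RNG position, history), suitable for exact
#' resumption with \code{\link{rsnn_run}}.
#'
#' @param fit an \code{rsnn_l2l} object.
#' @param path output file.
#' @export
save_checkpoint <- function(fit, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop_cfg("checkpointing requires the jsonlite package")
  }
  writeLines(jsonlite::serializeJSON(fit, digits = I(17)), path)
  invisible(path)
}

#' Load a fit checkpoint
#' @param path JSON written by \code{\link{save_checkpoint}}.
#' @return the restored \code{rsnn_l2l} object.
#' @export
load_checkpoint <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop_cfg("checkpointing requires the jsonlite package")
  }
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}
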