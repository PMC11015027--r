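#' Derive a named sub-seed from a master seed
#'
#' Every stochastic component of a run (initialisation, data sampling,
#' exploration noise, ...) consumes its own stream, derived deterministically
#' from the master seed and a stream label by a counter-based mixing scheme.
#' Keeps results below 2^31 so the value is a valid R integer seed.
#'
#' @param master integer master seed.
#' @param stream character label or integer counter for the stream.
#' @return an integer seed.
#' @export
derive_seed <- function(master, stream) {
  stopifnot(length(master) == 1, is.finite(master))
  if (is.character(stream)) {
    stream <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  }
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  x <- (as.double(master) %% m)
  x <- (x * 48271 + as.double(stream) * 16807 + 12345) %% m
  x <- (x * 69621 + 7) %% m
  as.integer(x)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores \code{.Random.seed} so seeded helpers do not disturb
#' the caller's random stream.
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Hash a numeric object (weights, states) for identity checks
#'
#' Used by the frozen-weight and probe-isolation contracts: two objects hash
#' equal iff their serialised bytes are identical.
#' @param x an R object.
#' @return a character digest.
#' @export
rsnn_hash <- function(x) {
  bytes <- as.double(serialize(x, NULL, version = 2))
  n <- length(bytes)
  w <- c(1, 31, 961, 29791, 923521, 28629151, 887503681, 27512614111)
  term <- bytes * w[(seq_len(n) - 1L) %% 8L + 1L]
  # chunked modular reduction keeps every partial sum below 2^53 (exact)
  fold <- function(v, mult) {
    idx <- ceiling(seq_along(v) / 256)
    parts <- vapply(split(v, idx), sum, 0)
    h <- 0
    for (p in parts) h <- (h * mult + p) %% 2147483647
    h
  }
  h1 <- fold(term, 48271)
  h2 <- fold(term, 69621)
  sprintf("%d-%d-%d", as.integer(h1), as.integer(h2), n)
}

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
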