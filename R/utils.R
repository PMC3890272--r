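#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a named random stream seed from a run seed
#'
#' All randomness in the framework flows from explicit integer seeds through
#' named streams (one per module), so that e.g. every management strategy run
#' on the same scenario member experiences identical ecological noise — the
#' paired-comparison design required for strategy contrasts.
#'
#' @param seed Integer run seed.
#' @param stream Character stream name (e.g. "ecology", "fleet", "observation").
#' @return An integer seed in [0, 2^31).
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # small string hash (polynomial, mod a prime below 2^31)
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483563
  as.integer((abs(seed) %% 2147483563 * 31 + h) %% 2147483563)
}

#' Create a reproducible RNG for a named stream
#' @param seed Integer run seed.
#' @param stream Stream name.
#' @return A function-free environment wrapping a seed: use with `with_stream`.
#' @keywords internal
make_rng <- function(seed, stream) {
  s <- stream_seed(seed, stream)
  e <- new.env(parent = emptyenv())
  e$seed <- s
  e$n <- 0L
  class(e) <- "mse_rng"
  e
}

# Draw from a stream without disturbing the global RNG more than needed:
# each call reseeds from (stream seed, draw counter) so draws are a pure
# function of the stream state, independent of interleaving elsewhere.
rng_draw <- function(rng, fn, ...) {
  if (is.null(rng)) stop("rng is NULL but random draws were requested")
  rng$n <- rng$n + 1L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed((rng$seed + 97L * rng$n) %% 2147483563L)
  out <- fn(...)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv())
  out
}

softmax <- function(x, temperature = 1) {
  if (temperature <= 0) {
    out <- numeric(length(x))
    out[which.max(x)] <- 1
    return(out)
  }
  z <- (x - max(x)) / temperature
  e <- exp(z)
  e / sum(e)
}

# Quantile with the linear-interpolation (inclusive) rule, fixed for
# cross-platform reproducibility of ensemble bands (type 7).
band_quantile <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))
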