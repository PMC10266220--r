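#' Derive a sub-stream seed from a master seed
#'
#' All randomness in the package flows from one master seed. Independent
#' stages (probe baselines, cell mixtures, noise, phenotypes, genotypes, ...)
#' draw from sub-streams so that, e.g., changing the number of SNPs does not
#' perturb the beta matrix. The rule is a fixed affine map modulo the largest
#' 32-bit prime, kept below 2^31 so the result is always a valid R seed.
#'
#' @param seed integer master seed.
#' @param stream small non-negative integer identifying the stage.
#' @return an integer seed for `set.seed()`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  s <- abs(as.numeric(seed)) %% 2147483647
  as.integer((s * 48271 + abs(stream)) %% 2147483647)
}

#' Draw rows from a Dirichlet distribution
#'
#' @param n number of draws.
#' @param alpha positive concentration parameters, optionally named.
#' @return an `n x length(alpha)` matrix whose rows sum to one.
#' @export
rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0), n >= 0)
  k <- length(alpha)
  m <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  colnames(m) <- names(alpha)
  m / rowSums(m)
}

# stop() with a consistent prefix so pipeline stage failures are attributable
abort <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
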