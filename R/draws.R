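halton_primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47,
                   53, 59, 61, 67, 71)

# Radical inverse of integer indices in base p with an optional digit
# permutation (perm[1] corresponds to digit 0 and must equal 0).
radical_inverse <- function(idx, p, perm = NULL) {
  f <- numeric(length(idx))
  denom <- 1 / p
  while (any(idx > 0)) {
    digit <- idx %% p
    if (!is.null(perm)) digit <- perm[digit + 1]
    f <- f + digit * denom
    idx <- idx %/% p
    denom <- denom / p
  }
  f
}

#' Scrambled Halton draws in per-individual blocks
#'
#' Generates a multidimensional Halton sequence (prime bases 2, 3, 5, ...),
#' optionally randomized by (i) a seeded random permutation of the digits of
#' each base above 2 (the zero digit is kept fixed so points stay in (0, 1))
#' and (ii) an independent Cranley-Patterson rotation — a uniform shift
#' modulo 1 — per individual and dimension, which makes each individual's
#' integration error independent with mean zero while preserving the
#' low-discrepancy structure of their block. Optionally transformed to
#' standard normal by the inverse CDF. Individual `i` receives the
#' contiguous block of rows `((i-1) n_draws + 1) : (i n_draws)`, so blocks
#' are disjoint across individuals. Deterministic given `seed`.
#'
#' @param n_individuals Number of individuals.
#' @param dimensions Number of dimensions (at most 20).
#' @param n_draws Draws per individual.
#' @param seed Integer seed for the scrambling permutations and rotations.
#' @param scramble Apply the digit permutations and rotations?
#'   (default `TRUE`).
#' @param normal Transform to standard normal? (default `TRUE`).
#' @param drop Number of initial sequence points to discard (default 0).
#' @return Matrix `(n_individuals * n_draws) x dimensions`.
#' @export
halton_sequence <- function(n_individuals, dimensions, n_draws, seed = 1L,
                            scramble = TRUE, normal = TRUE, drop = 0L) {
  if (dimensions > length(halton_primes)) stop("at most 20 dimensions supported")
  total <- n_individuals * n_draws
  rs <- local_rng(seed)
  perms <- lapply(seq_len(dimensions), function(d) {
    p <- halton_primes[d]
    if (scramble && p > 2) c(0L, rs$sample(seq_len(p - 1L), p - 1L)) else integer(0)
  })
  out <- halton_engine(as.integer(total), as.integer(drop),
                       as.integer(halton_primes[seq_len(dimensions)]), perms)
  if (scramble) {
    shifts <- matrix(rs$runif(n_individuals * dimensions),
                     n_individuals, dimensions)
    blk <- rep(seq_len(n_individuals), each = n_draws)
    out <- (out + shifts[blk, , drop = FALSE]) %% 1
  }
  if (normal) out <- qnorm(pmin(pmax(out, 1e-12), 1 - 1e-12))
  out
}

#' Modified Latin hypercube sampling draws
#'
#' One stratified permuted uniform sample per individual and dimension,
#' transformed to standard normal.
#'
#' @inheritParams halton_sequence
#' @return Matrix `(n_individuals * n_draws) x dimensions`.
#' @export
mlhs_draws <- function(n_individuals, dimensions, n_draws, seed = 1L) {
  rs <- local_rng(seed)
  out <- matrix(0, n_individuals * n_draws, dimensions)
  for (i in seq_len(n_individuals)) {
    rows <- (i - 1L) * n_draws + seq_len(n_draws)
    for (d in seq_len(dimensions)) {
      out[rows, d] <- (rs$sample(seq_len(n_draws), n_draws) - 1 + rs$runif(n_draws)) / n_draws
    }
  }
  qnorm(pmin(pmax(out, 1e-12), 1 - 1e-12))
}

#' Simulation draw configuration
#'
#' @param scheme `"halton"` (scrambled Halton, the default), `"mlhs"` or
#'   `"random"` (pseudo-random).
#' @param n_draws Draws per individual (default 500).
#' @param seed Integer seed.
#' @return Object of class `draw_config`.
#' @export
draw_config <- function(scheme = c("halton", "mlhs", "random"), n_draws = 500L,
                        seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(n_draws >= 1)
  structure(list(scheme = scheme, n_draws = as.integer(n_draws),
                 seed = as.integer(seed)), class = "draw_config")
}

#' @export
print.draw_config <- function(x, ...) {
  cat("Draws:", x$n_draws, "per individual,", x$scheme, "scheme, seed", x$seed, "\n")
  invisible(x)
}

# Standard-normal draw matrix for N individuals in `dimensions` dims.
make_draws <- function(config, n_individuals, dimensions) {
  if (dimensions == 0L) return(matrix(0, n_individuals * config$n_draws, 0))
  switch(config$scheme,
    halton = halton_sequence(n_individuals, dimensions, config$n_draws,
                             seed = config$seed),
    mlhs = mlhs_draws(n_individuals, dimensions, config$n_draws,
                      seed = config$seed),
    random = {
      rs <- local_rng(config$seed)
      matrix(rs$rnorm(n_individuals * config$n_draws * dimensions),
             n_individuals * config$n_draws, dimensions)
    })
}
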