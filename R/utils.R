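# Physical constants (SI)
.eps0 <- 8.8541878128e-12
.c0 <- 299792458

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded operations are pure
#' functions of their inputs and do not disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a named sub-stream seed from a root seed
#'
#' A fixed LCG-style mix keeps derived seeds deterministic, spread out, and
#' inside the 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed Root integer seed.
#' @param k Integer offset identifying the sub-stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, k) {
  # multiplier kept small enough that 69069 * (2^31 - 1) stays exactly
  # representable in a double: the mix must not lose the low-order bits
  # that distinguish neighbouring sub-streams
  s <- (as.double(seed) %% 2147483646) + 1
  k <- as.double(k)
  for (i in seq_len(3)) s <- (69069 * s + 12345 + k) %% 2147483647
  as.integer(s)
}

#' Voxel edge length in millimetres
#'
#' The configuration arithmetic of the imaging domain: a cubic domain of
#' interest of side `domain_side_m` discretized into `n` voxels per axis.
#' At the reference configuration, 0.24 m over 256 voxels gives 0.94 mm and
#' over 512 voxels gives 0.47 mm.
#'
#' @param domain_side_m Side of the cubic imaging domain in metres.
#' @param n Number of voxels per axis.
#' @param digits Decimal digits to round the millimetre value to.
#' @return Voxel size in mm, rounded.
#' @examples
#' voxel_size_mm(0.24, 256)
#' voxel_size_mm(0.24, 512)
#' @export
voxel_size_mm <- function(domain_side_m, n, digits = 2) {
  stopifnot(domain_side_m > 0, n >= 1)
  round(domain_side_m / n * 1000, digits)
}

# Voxel-centre coordinates along one axis for an origin-centred domain.
voxel_centers <- function(n, domain_side_m) {
  h <- domain_side_m / n
  -domain_side_m / 2 + (seq_len(n) - 0.5) * h
}

# n^3 x 3 matrix of voxel-centre coordinates, x fastest (column-major).
voxel_grid <- function(n, domain_side_m) {
  v <- voxel_centers(n, domain_side_m)
  cbind(
    x = rep(v, times = n * n),
    y = rep(rep(v, each = n), times = n),
    z = rep(v, each = n * n)
  )
}

`%||%` <- rlang::`%||%`
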