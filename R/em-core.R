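# Electromagnetic primitives. Time convention e^{+j omega t}: outgoing waves
# carry e^{-jkR} and lossy media have a negative imaginary permittivity.

#' Complex relative permittivity at angular frequency omega
#'
#' Combines relative permittivity and conductivity into the complex relative
#' permittivity eps_r + sigma / (j omega eps0), whose imaginary part is
#' negative for any lossy medium under the e^{+j omega t} convention.
#'
#' @param eps_r Relative permittivity (>= 1).
#' @param sigma Conductivity (S/m, >= 0).
#' @param omega Angular frequency (rad/s, > 0).
#' @return Complex relative permittivity (vectorized).
#' @examples
#' complex_permittivity(90, 1.038, 2 * pi * 3e8)
#' @export
complex_permittivity <- function(eps_r, sigma, omega) {
  if (any(omega <= 0)) abort("omega must be positive")
  stopifnot(all(eps_r >= 1), all(sigma >= 0))
  complex(real = eps_r, imaginary = -sigma / (omega * .eps0))
}

# Scalar free-space Green's function g = e^{-jkR} / (4 pi R).
scalar_green <- function(R, k0) exp(-1i * k0 * R) / (4 * pi * R)

# Dyadic Green's function components for displacement vectors (vectorized).
# G = g(R) * (A I + B Rhat Rhat), A = 1 - j/(kR) - 1/(kR)^2,
# B = -1 + 3j/(kR) + 3/(kR)^2.
dyadic_components <- function(dx, dy, dz, k0) {
  R <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(R < 1e-14)) abort("coincident points: the Green's dyadic is singular")
  ikr <- 1 / (k0 * R)
  g <- scalar_green(R, k0)
  A <- g * (1 - 1i * ikr - ikr^2)
  B <- g * (-1 + 3i * ikr + 3 * ikr^2)
  ux <- dx / R; uy <- dy / R; uz <- dz / R
  list(
    xx = A + B * ux * ux, xy = B * ux * uy, xz = B * ux * uz,
    yy = A + B * uy * uy, yz = B * uy * uz, zz = A + B * uz * uz
  )
}

#' Free-space dyadic Green's function between two points
#'
#' Returns the 3x3 tensor G(r1, r2) propagating a point current source at
#' `r2` to the field point `r1` in free space, including all near-field
#' terms. Reciprocity holds: `G(r1, r2) == t(G(r2, r1))`.
#'
#' @param r1,r2 Length-3 positions (m); must differ.
#' @param k0 Background wavenumber (rad/m).
#' @return A 3x3 complex matrix.
#' @export
greens_interaction <- function(r1, r2, k0) {
  d <- as.numeric(r1) - as.numeric(r2)
  cc <- dyadic_components(d[1], d[2], d[3], k0)
  matrix(
    c(cc$xx, cc$xy, cc$xz,
      cc$xy, cc$yy, cc$yz,
      cc$xz, cc$yz, cc$zz),
    nrow = 3, byrow = TRUE
  )
}

#' Incident field of one transmitting dipole at a set of points
#'
#' Analytic near+far field of an infinitesimal electric dipole in the
#' homogeneous background, evaluated from the textbook expansion
#' E = e^{-jkR}/(4 pi) \[ k^2 (rhat x p) x rhat / R +
#' (3 rhat (rhat.p) - p) (1/R^3 + jk/R^2) \] with unit dipole moment `p`
#' along the element's orientation.
#'
#' @param array An [build_array()] antenna array.
#' @param tx Transmitter index.
#' @param points N x 3 matrix of field points (m), none at the dipole.
#' @param background_eps_r Relative permittivity of the homogeneous
#'   background (1 = free space; > 1 emulates a lossless matching fluid).
#' @return N x 3 complex matrix of E-field components.
#' @export
incident_field <- function(array, tx, points, background_eps_r = 1) {
  points <- rbind(points)
  r0 <- array$positions[tx, ]
  p <- array$orientations[tx, ]
  k0 <- 2 * pi * array$frequency_hz / .c0 * sqrt(background_eps_r)
  d <- sweep(points, 2, r0)
  R <- sqrt(rowSums(d^2))
  if (any(R < 1e-14)) abort("incident field requested at the source point")
  u <- d / R
  up <- as.vector(u %*% p)
  ph <- exp(-1i * k0 * R) / (4 * pi)
  near <- (1 / R^3 + 1i * k0 / R^2)
  # (rhat x p) x rhat = p - rhat (rhat . p)
  E <- matrix(0i, nrow = nrow(points), ncol = 3)
  for (c_ in 1:3) {
    E[, c_] <- ph * (k0^2 * (p[c_] - u[, c_] * up) / R +
                       (3 * u[, c_] * up - p[c_]) * near)
  }
  colnames(E) <- c("x", "y", "z")
  E
}
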