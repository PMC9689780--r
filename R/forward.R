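# Volume-integral-equation forward solver (Born and coupled-dipole modes).
#
# The domain is discretized on the phantom's voxel grid; each voxel is a
# polarizable cell with contrast chi = eps_tilde - 1 against the free-space
# background. The discretized VIE reads, per voxel j,
#   (1 + chi_j / 3) E_j - k0^2 dV sum_{i != j} G(r_j, r_i) chi_i E_i = Einc_j
# (static depolarization self-term). Born mode replaces E by Einc on the
# right; full mode solves the coupled system by BiCGSTAB with an
# FFT-accelerated block-Toeplitz matrix-vector product. Receivers record all
# three Cartesian components of the re-radiated field.

# Field vectors are stacked component-major: c(Ex, Ey, Ez), each length Nv.

#' Precompute the forward operator for a fixed array and grid
#'
#' Builds the incident-field matrix (all transmitters at all voxel centres),
#' the radiation matrix (all voxels to all receiver components), and, for the
#' full coupled-dipole mode, the FFT of the block-Toeplitz Green's kernel.
#' Reuse this across phantoms that share the array and grid: it dominates
#' the setup cost of batch dataset generation.
#'
#' @param array An [build_array()] array.
#' @param grid_n Voxels per axis of the phantom grid.
#' @param domain_side_m Domain side (m).
#' @param method `"born"` or `"full"` (the latter also precomputes the FFT
#'   kernel).
#' @param background_eps_r Relative permittivity of the homogeneous
#'   background medium (1 = free space; > 1 emulates a matching fluid).
#' @return A `forward_operator` list.
#' @export
build_forward_operator <- function(array, grid_n, domain_side_m,
                                   method = c("born", "full"),
                                   background_eps_r = 1) {
  method <- match.arg(method)
  stopifnot(background_eps_r >= 1)
  k0 <- 2 * pi * array$frequency_hz / .c0 * sqrt(background_eps_r)
  h <- domain_side_m / grid_n
  dV <- h^3
  coords <- voxel_grid(grid_n, domain_side_m)
  nv <- nrow(coords)
  ntx <- nrow(array$positions)

  einc <- matrix(0i, nrow = 3 * nv, ncol = ntx)
  for (t in seq_len(ntx)) {
    E <- incident_field(array, t, coords, background_eps_r)
    einc[, t] <- c(E[, 1], E[, 2], E[, 3])
  }

  # radiation matrix: rows (rx fastest within component blocks), columns
  # (voxel fastest within component blocks); includes the k0^2 dV factor
  rad <- matrix(0i, nrow = 3 * ntx, ncol = 3 * nv)
  for (r in seq_len(ntx)) {
    d1 <- array$positions[r, 1] - coords[, 1]
    d2 <- array$positions[r, 2] - coords[, 2]
    d3 <- array$positions[r, 3] - coords[, 3]
    cc <- dyadic_components(d1, d2, d3, k0)
    blk <- list(c(cc$xx, cc$xy, cc$xz), c(cc$xy, cc$yy, cc$yz),
                c(cc$xz, cc$yz, cc$zz))
    for (c_ in 1:3) rad[(c_ - 1) * ntx + r, ] <- k0^2 * dV * blk[[c_]]
  }

  gfft <- if (method == "full") green_kernel_fft(grid_n, h, k0, dV) else NULL

  structure(
    list(array = array, grid_n = grid_n, domain_side_m = domain_side_m,
         k0 = k0, dV = dV, coords = coords, einc = einc, rad = rad,
         gfft = gfft, method = method, background_eps_r = background_eps_r),
    class = "forward_operator"
  )
}

# FFT of the k0^2 dV-scaled dyadic kernel on the 2n-periodized offset grid.
green_kernel_fft <- function(n, h, k0, dV) {
  m <- 2L * n
  off <- c(0:(n - 1), (n - m):(-1)) * h
  dx <- array(rep(off, times = m * m), dim = c(m, m, m))
  dy <- array(rep(rep(off, each = m), times = m), dim = c(m, m, m))
  dz <- array(rep(off, each = m * m), dim = c(m, m, m))
  R <- sqrt(dx^2 + dy^2 + dz^2)
  R[1, 1, 1] <- 1 # self-term excluded; overwritten below
  ikr <- 1 / (k0 * R)
  g <- exp(-1i * k0 * R) / (4 * pi * R)
  A <- g * (1 - 1i * ikr - ikr^2)
  B <- g * (-1 + 3i * ikr + 3 * ikr^2)
  ux <- dx / R; uy <- dy / R; uz <- dz / R
  comp <- list(
    xx = A + B * ux^2, xy = B * ux * uy, xz = B * ux * uz,
    yy = A + B * uy^2, yz = B * uy * uz, zz = A + B * uz^2
  )
  lapply(comp, function(a) {
    a[1, 1, 1] <- 0i
    fft(a * (k0^2 * dV))
  })
}

# y = sum_{i != j} k0^2 dV G(r_j - r_i) x_i for all grid voxels, via FFT.
green_convolve <- function(gfft, x, n) {
  m <- 2L * n
  nv <- n^3
  xs <- vector("list", 3)
  for (c_ in 1:3) {
    a <- array(0i, dim = c(m, m, m))
    a[1:n, 1:n, 1:n] <- array(x[((c_ - 1) * nv + 1):(c_ * nv)], dim = c(n, n, n))
    xs[[c_]] <- fft(a)
  }
  rows <- list(c("xx", "xy", "xz"), c("xy", "yy", "yz"), c("xz", "yz", "zz"))
  out <- complex(length.out = 3 * nv)
  for (c_ in 1:3) {
    acc <- gfft[[rows[[c_]][1]]] * xs[[1]] +
      gfft[[rows[[c_]][2]]] * xs[[2]] +
      gfft[[rows[[c_]][3]]] * xs[[3]]
    y <- fft(acc, inverse = TRUE) / (m^3)
    out[((c_ - 1) * nv + 1):(c_ * nv)] <- as.vector(y[1:n, 1:n, 1:n])
  }
  out
}

# Unpreconditioned BiCGSTAB for a complex linear operator.
bicgstab <- function(amul, b, tol = 1e-6, maxit = 400) {
  cdot <- function(a, b) sum(Conj(a) * b)
  nb <- sqrt(Re(cdot(b, b)))
  if (nb == 0) return(list(x = b, iters = 0, relres = 0))
  x <- complex(length.out = length(b))
  r <- b
  rhat <- r
  rho <- alpha <- omega <- 1 + 0i
  v <- p <- complex(length.out = length(b))
  for (it in seq_len(maxit)) {
    rho1 <- cdot(rhat, r)
    beta <- (rho1 / rho) * (alpha / omega)
    rho <- rho1
    p <- r + beta * (p - omega * v)
    v <- amul(p)
    alpha <- rho / cdot(rhat, v)
    s <- r - alpha * v
    t <- amul(s)
    omega <- cdot(t, s) / cdot(t, t)
    x <- x + alpha * p + omega * s
    r <- s - omega * t
    relres <- sqrt(Re(cdot(r, r))) / nb
    if (relres <= tol) return(list(x = x, iters = it, relres = relres))
  }
  abort(sprintf(
    "coupled-dipole solver did not converge in %d iterations (relative residual %.3g)",
    maxit, relres
  ), class = "braintomo_solver_error")
}

# Per-voxel complex contrast vector from property volumes, against a
# (lossless) background of relative permittivity eps_b.
contrast_vector <- function(eps, sigma, omega, eps_b = 1) {
  et <- complex(real = as.vector(eps),
                imaginary = -as.vector(sigma) / (omega * .eps0))
  et / eps_b - 1
}

#' Solve the scattered field of a phantom under an antenna array
#'
#' Computes the complex scattered electric field at every ordered
#' (transmitter, receiver) pair of the array, excluding self-pairs, with x,
#' y and z components: 3 x 60 x 59 = 10,620 raw values for the default
#' array. `"born"` mode is the single-scattering linearization (exact in the
#' weak-contrast limit and linear in the contrast); `"full"` mode solves the
#' coupled-dipole volume integral equation to the requested residual.
#'
#' @param p A `brain_phantom`, or a `list(eps=, sigma=)` of property volumes
#'   (then `operator` must be supplied to define the grid).
#' @param array Antenna array (ignored if `operator` given).
#' @param method `"born"` or `"full"`.
#' @param solver_tol Relative residual target of the full-mode solve.
#' @param operator Optional precomputed [build_forward_operator()].
#' @param maxit Full-mode iteration cap.
#' @param max_grid_full Guard: refuse full mode above this grid size.
#' @return A `scatter_record` with `e_scat` (ntx x (ntx-1) x 3) and the
#'   aggregated length-360 `input_vec`.
#' @export
solve_scattered_field <- function(p, array = build_array(),
                                  method = c("born", "full"),
                                  solver_tol = 1e-6, operator = NULL,
                                  maxit = 400, max_grid_full = 48) {
  method <- match.arg(method)
  if (inherits(p, "brain_phantom")) {
    vols <- phantom_volumes(p)
    grid_n <- p$grid_n
    side <- p$domain_side_m
  } else {
    vols <- p
    if (is.null(operator)) abort("property volumes need a precomputed operator")
    grid_n <- operator$grid_n
    side <- operator$domain_side_m
  }
  if (method == "full" && grid_n > max_grid_full)
    abort(sprintf("full mode is guarded to grids <= %d^3", max_grid_full))
  if (is.null(operator) ||
      (method == "full" && is.null(operator$gfft))) {
    operator <- build_forward_operator(array, grid_n, side, method)
  }
  op <- operator
  omega <- 2 * pi * op$array$frequency_hz
  chi <- contrast_vector(vols$eps, vols$sigma, omega, op$background_eps_r %||% 1)
  chi3 <- rep(chi, times = 3)
  ntx <- nrow(op$array$positions)

  if (method == "born" || all(chi == 0)) {
    X <- op$einc * chi3
  } else {
    dinv <- 1 / (1 + chi3 / 3)
    X <- matrix(0i, nrow = 3 * op$grid_n^3, ncol = ntx)
    amul <- function(x) x - dinv * green_convolve(op$gfft, chi3 * x, op$grid_n)
    for (t in seq_len(ntx)) {
      sol <- bicgstab(amul, dinv * op$einc[, t], tol = solver_tol, maxit = maxit)
      X[, t] <- chi3 * sol$x
    }
  }
  S <- op$rad %*% X # (3*ntx) x ntx: rows (rx fastest per component), cols tx
  e_full <- array(0i, dim = c(ntx, ntx, 3))
  for (c_ in 1:3) e_full[, , c_] <- t(S[((c_ - 1) * ntx + 1):(c_ * ntx), ])
  e_scat <- array(0i, dim = c(ntx, ntx - 1, 3))
  for (t in seq_len(ntx)) e_scat[t, , ] <- e_full[t, -t, ]
  new_scatter_record(e_scat, op$array)
}

# Dense direct solve of the same discretized operator, restricted to the
# contrast-carrying voxels. Independent oracle for the iterative full mode.
solve_scattered_field_dense <- function(p, array = build_array(),
                                        operator = NULL, max_unknowns = 4500) {
  if (inherits(p, "brain_phantom")) {
    vols <- phantom_volumes(p); grid_n <- p$grid_n; side <- p$domain_side_m
  } else {
    vols <- p
    if (is.null(operator)) abort("property volumes need a precomputed operator")
    grid_n <- operator$grid_n; side <- operator$domain_side_m
  }
  if (is.null(operator)) operator <- build_forward_operator(array, grid_n, side, "born")
  op <- operator
  omega <- 2 * pi * op$array$frequency_hz
  chi <- contrast_vector(vols$eps, vols$sigma, omega,
                         op$background_eps_r %||% 1)
  idx <- which(Mod(chi) > 0)
  nc <- length(idx)
  ntx <- nrow(op$array$positions)
  nv <- op$grid_n^3
  if (3 * nc > max_unknowns)
    abort(sprintf("dense oracle limited to %d unknowns (requested %d)",
                  max_unknowns, 3 * nc))
  Xfull <- matrix(0i, nrow = 3 * nv, ncol = ntx)
  if (nc > 0) {
    co <- op$coords[idx, , drop = FALSE]
    G <- matrix(0i, 3 * nc, 3 * nc)
    if (nc > 1) {
      dx <- outer(co[, 1], co[, 1], "-")
      dy <- outer(co[, 2], co[, 2], "-")
      dz <- outer(co[, 3], co[, 3], "-")
      diag(dx) <- diag(dy) <- 1e9; diag(dz) <- 0 # dummy, zeroed below
      cc <- dyadic_components(dx, dy, dz, op$k0)
      zd <- function(m) { diag(m) <- 0i; m }
      G[1:nc, 1:nc] <- zd(cc$xx); G[1:nc, nc + 1:nc] <- zd(cc$xy)
      G[1:nc, 2 * nc + 1:nc] <- zd(cc$xz)
      G[nc + 1:nc, 1:nc] <- zd(cc$xy); G[nc + 1:nc, nc + 1:nc] <- zd(cc$yy)
      G[nc + 1:nc, 2 * nc + 1:nc] <- zd(cc$yz)
      G[2 * nc + 1:nc, 1:nc] <- zd(cc$xz); G[2 * nc + 1:nc, nc + 1:nc] <- zd(cc$yz)
      G[2 * nc + 1:nc, 2 * nc + 1:nc] <- zd(cc$zz)
    }
    chi_s <- rep(chi[idx], times = 3)
    M <- diag(1 + chi_s / 3) - op$k0^2 * op$dV * G %*% diag(chi_s)
    sel <- c(idx, nv + idx, 2 * nv + idx)
    E <- solve(M, op$einc[sel, , drop = FALSE])
    Xfull[sel, ] <- chi_s * E
  }
  S <- op$rad %*% Xfull
  e_full <- array(0i, dim = c(ntx, ntx, 3))
  for (c_ in 1:3) e_full[, , c_] <- t(S[((c_ - 1) * ntx + 1):(c_ * ntx), ])
  e_scat <- array(0i, dim = c(ntx, ntx - 1, 3))
  for (t in seq_len(ntx)) e_scat[t, , ] <- e_full[t, -t, ]
  new_scatter_record(e_scat, op$array)
}

new_scatter_record <- function(e_scat, array, noise_level_db = NULL) {
  rec <- structure(
    list(e_scat = e_scat, array = array, noise_level_db = noise_level_db,
         input_vec = NULL),
    class = "scatter_record"
  )
  rec$input_vec <- aggregate_inputs(rec)
  rec
}

#' Aggregate raw measurements into the network input vector
#'
#' For each of the 60 receivers and each Cartesian component, the complex
#' scattered fields of the 59 other transmitters are summed, yielding
#' M = 60 x 3 = 180 complex values; the returned vector concatenates their
#' 180 real parts followed by their 180 imaginary parts (length 2M = 360).
#' Within each half the receiver index runs fastest, components x, y, z in
#' blocks.
#'
#' @param rec A `scatter_record`.
#' @return Numeric vector of length `2 * ntx * 3`.
#' @export
aggregate_inputs <- function(rec) {
  e <- rec$e_scat
  if (anyNA(e)) abort("scatter record has missing entries")
  ntx <- dim(e)[1]
  agg <- matrix(0i, nrow = ntx, ncol = 3)
  for (t in seq_len(ntx)) {
    rx <- seq_len(ntx)[-t]
    agg[rx, ] <- agg[rx, ] + e[t, , ]
  }
  c(Re(as.vector(agg)), Im(as.vector(agg)))
}

#' Add relative white Gaussian noise to the raw measurements
#'
#' Adds circular complex Gaussian noise whose total power is
#' `10^(level_db/10)` times the total signal power of the full raw
#' measurement array (the conventional reading of a relative noise level in
#' dB), then re-runs the aggregation. Noise is applied to the raw
#' per-(transmitter, receiver, component) measurements before the
#' 59-transmitter summation by default; `where = "aggregated"` perturbs the
#' summed values instead.
#'
#' @param rec A `scatter_record`.
#' @param level_db Relative noise level in dB (`NULL` or `-Inf`: no noise).
#' @param seed Seed for the noise realization.
#' @param where `"raw"` or `"aggregated"`.
#' @return A new `scatter_record` with noisy fields and input vector.
#' @export
add_noise <- function(rec, level_db, seed = 1, where = c("raw", "aggregated")) {
  where <- match.arg(where)
  if (is.null(level_db) || identical(level_db, -Inf)) return(rec)
  e <- rec$e_scat
  psig <- sum(Mod(e)^2)
  if (psig == 0) abort("cannot define a relative noise level for a zero-signal record")
  if (where == "raw") {
    s2 <- 10^(level_db / 10) * psig / length(e)
    noise <- with_seed(seed, complex(
      real = rnorm(length(e), 0, sqrt(s2 / 2)),
      imaginary = rnorm(length(e), 0, sqrt(s2 / 2))
    ))
    out <- new_scatter_record(e + array(noise, dim = dim(e)), rec$array,
                              noise_level_db = level_db)
  } else {
    out <- rec
    ntx <- dim(e)[1]
    agg <- complex(real = rec$input_vec[1:(3 * ntx)],
                   imaginary = rec$input_vec[3 * ntx + 1:(3 * ntx)])
    pa <- sum(Mod(agg)^2)
    s2 <- 10^(level_db / 10) * pa / length(agg)
    noise <- with_seed(seed, complex(
      real = rnorm(length(agg), 0, sqrt(s2 / 2)),
      imaginary = rnorm(length(agg), 0, sqrt(s2 / 2))
    ))
    agg <- agg + noise
    out$input_vec <- c(Re(agg), Im(agg))
    out$noise_level_db <- level_db
  }
  out
}

#' @export
print.scatter_record <- function(x, ...) {
  d <- dim(x$e_scat)
  cat(sprintf(
    "<scatter_record> %d tx x %d rx x %d components = %d raw measurements; input length %d%s\n",
    d[1], d[2], d[3], prod(d), length(x$input_vec),
    if (is.null(x$noise_level_db)) "" else sprintf("; noise %g dB", x$noise_level_db)
  ))
  invisible(x)
}
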