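# Procedural nested-tissue brain phantoms.
#
# Each tissue boundary is a closed star-shaped surface stored as a radial
# function r(theta, phi) sampled on a fixed control grid over the sphere.
# Nesting is the structural invariant: surface t+1 lies strictly inside
# surface t at every control point, so a voxel's label is simply the number
# of surfaces containing it (0 = air, deepest tissue otherwise).

.ctrl_n_theta <- 25L
.ctrl_n_phi <- 48L
.nest_margin_m <- 2e-4 # minimum radial gap preserved between adjacent surfaces

# Bilinear interpolation of a radial control grid at unit directions (N x 3).
surface_interp <- function(surf, u) {
  nt <- nrow(surf); np <- ncol(surf)
  z <- pmin(pmax(u[, 3], -1), 1)
  theta <- acos(z)
  phi <- atan2(u[, 2], u[, 1]) %% (2 * pi)
  ti <- theta / pi * (nt - 1) + 1
  pj <- phi / (2 * pi) * np + 1 # phi wraps: column np+1 == column 1
  t0 <- pmin(floor(ti), nt - 1); tw <- ti - t0
  p0 <- floor(pj); pw <- pj - p0
  p0w <- ((p0 - 1) %% np) + 1
  p1w <- (p0 %% np) + 1
  s00 <- surf[cbind(t0, p0w)]; s01 <- surf[cbind(t0, p1w)]
  s10 <- surf[cbind(t0 + 1, p0w)]; s11 <- surf[cbind(t0 + 1, p1w)]
  (1 - tw) * ((1 - pw) * s00 + pw * s01) + tw * ((1 - pw) * s10 + pw * s11)
}

# Unit directions of the control grid, as an (n_theta*n_phi) x 3 matrix.
ctrl_directions <- function(nt = .ctrl_n_theta, np = .ctrl_n_phi) {
  theta <- seq(0, pi, length.out = nt)
  phi <- seq(0, 2 * pi, length.out = np + 1)[seq_len(np)]
  st <- sin(theta)
  cbind(
    x = as.vector(outer(st, cos(phi))),
    y = as.vector(outer(st, sin(phi))),
    z = rep(cos(theta), times = np)
  )
}

# Head-like base shape (radius per control direction): a superellipsoid
# modulated by a small seeded low-order harmonic perturbation.
base_shape_grid <- function(seed, nt = .ctrl_n_theta, np = .ctrl_n_phi) {
  u <- ctrl_directions(nt, np)
  p <- 2.4
  se <- (abs(u[, 1] / 1.0)^p + abs(u[, 2] / 0.85)^p + abs(u[, 3] / 0.92)^p)^(-1 / p)
  cf <- with_seed(seed, rnorm(6))
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  pert <- cf[1] * x * y + cf[2] * y * z + cf[3] * z * x +
    cf[4] * (x^2 - y^2) / 2 + cf[5] * (3 * z^2 - 1) / 4 + cf[6] * x * y * z
  shape <- se * (1 + 0.04 * pert / sqrt(sum(cf^2) / 6 + 1e-12))
  matrix(shape, nrow = nt, ncol = np)
}

new_brain_phantom <- function(surfaces, table, grid_n, domain_side_m, provenance) {
  p <- structure(
    list(
      surfaces = surfaces, table = table,
      grid_n = as.integer(grid_n), domain_side_m = domain_side_m,
      voxel_size_m = domain_side_m / grid_n,
      provenance = provenance,
      label_grid = NULL, eps_grid = NULL, sigma_grid = NULL
    ),
    class = "brain_phantom"
  )
  voxelize_phantom(p)
}

# Rasterize the surface stack (and any recorded anomalies) onto the voxel grid.
voxelize_phantom <- function(p, check_labels = TRUE) {
  n <- p$grid_n
  ntis <- nrow(p$table)
  if (any(apply(p$surfaces, c(2, 3), diff) >= 0))
    abort("tissue surfaces are not strictly nested")
  g <- voxel_grid(n, p$domain_side_m)
  rho <- sqrt(rowSums(g^2))
  u <- g / pmax(rho, 1e-15)
  u[rho < 1e-15, ] <- rep(c(0, 0, 1), each = sum(rho < 1e-15))
  label <- integer(n^3)
  for (t in seq_len(ntis)) {
    rt <- surface_interp(p$surfaces[t, , ], u)
    label <- label + as.integer(rho <= rt) # nested => counts give deepest tissue
  }
  eps <- c(1, p$table$eps_r)[label + 1L]
  sig <- c(0, p$table$sigma)[label + 1L]
  for (a in p$provenance$anomalies) {
    d2 <- (g[, 1] - a$center_m[1])^2 + (g[, 2] - a$center_m[2])^2 +
      (g[, 3] - a$center_m[3])^2
    sel <- d2 <= a$radius_m^2
    if (!any(sel)) sel <- seq_along(d2) == which.min(d2) # centre-voxel rule
    if (any(label[sel] == 0L))
      abort("anomaly sphere intersects air outside the brain")
    label[sel] <- ntis + 1L
    eps[sel] <- a$eps_r
    sig[sel] <- a$sigma
  }
  if (check_labels) {
    present <- tabulate(label, nbins = ntis)
    if (any(present == 0)) {
      worst <- which(present == 0)[which.min(present[present == 0])]
      abort(sprintf(
        "grid too coarse to realize all tissues: tissue '%s' (layer %d) has no voxels at grid %d",
        p$table$tissue[worst], worst, n
      ))
    }
  }
  p$label_grid <- array(label, dim = c(n, n, n))
  p$eps_grid <- array(eps, dim = c(n, n, n))
  p$sigma_grid <- array(sig, dim = c(n, n, n))
  p
}

#' Build the base nested-tissue brain phantom
#'
#' Constructs the generic head model: 16 nested smooth closed surfaces
#' (a superellipsoid with a seeded low-order harmonic perturbation, shrunk by
#' a fixed fraction per tissue layer) assigned tissue properties outermost to
#' innermost, rasterized onto a cubic voxel grid centred on the imaging
#' domain. Voxels outside the outermost surface are air (eps_r = 1,
#' sigma = 0).
#'
#' @param table Tissue property table, see [default_tissue_table()].
#' @param grid_n Voxels per axis (>= 16; all 16 tissues are realizable from
#'   grid 32 up).
#' @param domain_side_m Side of the cubic imaging domain (m).
#' @param seed Seed controlling the base shape perturbation.
#' @return A `brain_phantom` with label, permittivity and conductivity grids.
#' @examples
#' p <- build_base_phantom(grid_n = 32)
#' table(p$label_grid == 0)
#' @export
build_base_phantom <- function(table = default_tissue_table(), grid_n = 64,
                               domain_side_m = 0.24, seed = 7) {
  stopifnot(grid_n >= 16, domain_side_m > 0)
  ntis <- nrow(table)
  shape <- base_shape_grid(seed)
  s0 <- 0.325 * domain_side_m
  # innermost-layer fraction: 16 thin shells need a small core, while reduced
  # stacks keep a larger core so every layer survives coarse rasterization
  f_in <- max(0.16, 0.5 - 0.05 * ntis)
  fr <- seq(1, f_in, length.out = max(ntis, 2))[seq_len(ntis)]
  surfaces <- array(0, dim = c(ntis, .ctrl_n_theta, .ctrl_n_phi))
  for (t in seq_len(ntis)) surfaces[t, , ] <- fr[t] * s0 * shape
  new_brain_phantom(
    surfaces, table, grid_n, domain_side_m,
    provenance = list(
      base_seed = seed, scale_factor = 1, deformation_seed = NULL,
      anomalies = list()
    )
  )
}

#' Scale a phantom's geometry and electrical properties
#'
#' Linearly scales the brain about the domain centre by `factor` and
#' multiplies every tissue's relative permittivity and conductivity by the
#' same factor (permittivity floored at 1, the value of air; air itself is
#' untouched). The generation strategy draws `factor` from
#' \{0.8, 0.9, 1.0, 1.1, 1.2\}; any positive factor is accepted directly.
#'
#' @param p A `brain_phantom`.
#' @param factor Positive scale factor.
#' @return The scaled phantom, re-rasterized.
#' @export
scale_phantom <- function(p, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1, factor > 0)
  surf <- p$surfaces * factor
  if (max(surf) > p$domain_side_m / 2)
    abort(sprintf(
      "scaled brain (max radius %.4f m) exceeds the imaging domain half-side %.4f m",
      max(surf), p$domain_side_m / 2
    ))
  tb <- p$table
  tb$eps_r <- pmax(1, tb$eps_r * factor)
  tb$sigma <- tb$sigma * factor
  p$surfaces <- surf
  p$table <- tb
  p$provenance$scale_factor <- p$provenance$scale_factor * factor
  p$provenance$anomalies <- lapply(p$provenance$anomalies, function(a) {
    a$center_m <- a$center_m * factor
    a$radius_m <- a$radius_m * factor
    a
  })
  voxelize_phantom(p)
}

#' Deform tissue boundaries with Gaussian control-point displacements
#'
#' Emulates inter-individual anatomical variability: in a seeded random
#' tissue order, every boundary control point is displaced by an i.i.d.
#' Normal(0, `sigma_disp_m`^2) vector per axis, the displaced point's radius
#' is re-sampled onto the control grid, and the surface is smoothly
#' re-interpolated. Displacements that would cross a neighbouring surface are
#' clipped so the nesting invariant survives.
#'
#' @param p A `brain_phantom`.
#' @param sigma_disp_m Displacement standard deviation (m) per axis.
#' @param seed Seed for the tissue order and displacements.
#' @return The deformed phantom, re-rasterized.
#' @export
deform_tissue_boundaries <- function(p, sigma_disp_m = 0.002, seed = 1) {
  stopifnot(sigma_disp_m >= 0)
  ntis <- nrow(p$table)
  u <- ctrl_directions()
  surf <- p$surfaces
  n_clip <- 0L
  n_pts <- 0L
  with_seed(seed, {
    order_t <- sample(ntis)
    for (t in order_t) {
      r <- as.vector(surf[t, , ]) # theta-fastest, matching ctrl_directions() rows
      d <- matrix(rnorm(length(r) * 3, 0, sigma_disp_m), ncol = 3)
      pt <- r * u + d
      newr <- sqrt(rowSums(pt^2))
      upper <- if (t == 1) rep(0.49 * p$domain_side_m, length(r))
               else as.vector(surf[t - 1, , ]) - .nest_margin_m
      lower <- if (t == ntis) rep(.nest_margin_m, length(r))
               else as.vector(surf[t + 1, , ]) + .nest_margin_m
      clipped <- pmin(pmax(newr, lower), upper)
      n_clip <- n_clip + sum(clipped != newr)
      n_pts <- n_pts + length(newr)
      surf[t, , ] <- matrix(clipped, nrow = .ctrl_n_theta)
    }
  })
  # When most control points hit a neighbouring surface, the realized field
  # is no longer the requested Normal displacement: refuse rather than return
  # a silently different deformation.
  if (sigma_disp_m > 0 && n_clip > 0.5 * n_pts)
    abort(sprintf(
      "boundary deformation too large: %.0f%% of control points clipped to preserve nesting",
      100 * n_clip / n_pts
    ))
  p$surfaces <- surf
  p$provenance$deformation_seed <- seed
  voxelize_phantom(p)
}

#' Specify a spherical anomalous scatterer
#'
#' Emulates a lesion, bleed or tumour: a sphere of elevated permittivity and
#' conductivity. When drawn by the generation strategy, the radius comes from
#' \{4, 7, 10\} mm, eps_r from \{90, 120, 150\} and sigma from
#' \{1.038, 1.384, 1.73\} S/m.
#'
#' @param center_m Length-3 centre (m).
#' @param radius_m Radius (m).
#' @param eps_r Relative permittivity of the inclusion.
#' @param sigma Conductivity (S/m).
#' @return An `anomaly_spec` list.
#' @export
anomaly_spec <- function(center_m, radius_m, eps_r, sigma) {
  stopifnot(length(center_m) == 3, radius_m > 0, eps_r >= 1, sigma >= 0)
  structure(
    list(center_m = as.numeric(center_m), radius_m = radius_m,
         eps_r = eps_r, sigma = sigma),
    class = "anomaly_spec"
  )
}

#' Insert a spherical anomaly into a phantom
#'
#' Voxels whose centres lie within the sphere are relabelled to the anomaly
#' class and given the anomaly's properties; all other voxels are untouched.
#' A sphere smaller than the voxel pitch still claims the voxel containing
#' its centre. The sphere must lie entirely within the brain: touching air
#' is an error.
#'
#' @param p A `brain_phantom`.
#' @param a An [anomaly_spec()].
#' @return The phantom with the anomaly applied and recorded in provenance.
#' @export
insert_anomaly <- function(p, a) {
  stopifnot(inherits(a, "anomaly_spec"))
  p$provenance$anomalies <- c(p$provenance$anomalies, list(a))
  voxelize_phantom(p)
}

#' Draw the generation-strategy parameters
#'
#' One row per training case: a geometric/property scale factor uniform over
#' \{0.8, 0.9, 1.0, 1.1, 1.2\}, a uniformly shuffled tissue deformation
#' order, and (optionally) anomaly attributes drawn uniformly from the
#' three-value menus (radius 4/7/10 mm; eps_r 90/120/150; sigma
#' 1.038/1.384/1.73 S/m).
#'
#' @param n Number of draws.
#' @param seed Seed.
#' @param with_anomaly Draw anomaly attributes? If `FALSE` they are `NA`.
#' @param n_tissues Number of tissues the deformation order permutes.
#' @param sigma_disp_m Boundary displacement scale carried along (not drawn).
#' @return A tibble with columns `factor`, `sigma_disp_m`, `order`
#'   (list-column of permutations), `radius_m`, `eps_r`, `sigma`.
#' @export
sample_strategy_params <- function(n = 1, seed = 1, with_anomaly = TRUE,
                                   n_tissues = 16, sigma_disp_m = 0.002) {
  with_seed(seed, {
    factor <- sample(c(0.8, 0.9, 1.0, 1.1, 1.2), n, replace = TRUE)
    order <- replicate(n, sample(n_tissues), simplify = FALSE)
    if (with_anomaly) {
      radius_m <- sample(c(0.004, 0.007, 0.010), n, replace = TRUE)
      eps_r <- sample(c(90, 120, 150), n, replace = TRUE)
      sigma <- sample(c(1.038, 1.384, 1.73), n, replace = TRUE)
    } else {
      radius_m <- rep(NA_real_, n); eps_r <- rep(NA_real_, n)
      sigma <- rep(NA_real_, n)
    }
    tibble::tibble(
      factor = factor, sigma_disp_m = sigma_disp_m, order = order,
      radius_m = radius_m, eps_r = eps_r, sigma = sigma
    )
  })
}

# Place an anomaly of given size fully inside the (possibly deformed) brain.
place_anomaly <- function(p, radius_m, eps_r, sigma, seed, max_tries = 50) {
  outer_surf <- p$surfaces[1, , ]
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      rmax <- surface_interp(outer_surf, matrix(u, 1)) - radius_m - p$voxel_size_m
      if (rmax <= 0) next
      ctr <- runif(1, 0, rmax) * u
      res <- tryCatch(
        insert_anomaly(p, anomaly_spec(ctr, radius_m, eps_r, sigma)),
        error = function(e) NULL
      )
      if (!is.null(res)) return(res)
    }
    abort("could not place anomaly inside the brain after repeated tries")
  })
}

#' Generate one phantom by the full strategy chain
#'
#' Base model, random scaling, boundary deformation in random order, and
#' optional anomaly insertion, all driven by one seed.
#'
#' @param seed Per-sample seed.
#' @param table Tissue table for the base model.
#' @param grid_n,domain_side_m Grid resolution and domain size.
#' @param with_anomaly Insert a menu-drawn spherical anomaly?
#' @param base_seed Seed of the shared base model shape.
#' @param sigma_disp_m Boundary deformation scale (m).
#' @return A `brain_phantom`.
#' @export
random_phantom <- function(seed, table = default_tissue_table(), grid_n = 24,
                           domain_side_m = 0.24, with_anomaly = FALSE,
                           base_seed = 7, sigma_disp_m = 0.002) {
  par <- sample_strategy_params(1, derive_seed(seed, 1), with_anomaly,
                                n_tissues = nrow(table),
                                sigma_disp_m = sigma_disp_m)
  p <- build_base_phantom(table, grid_n, domain_side_m, base_seed)
  p <- scale_phantom(p, par$factor[1])
  p <- deform_tissue_boundaries(p, par$sigma_disp_m[1], derive_seed(seed, 2))
  if (with_anomaly)
    p <- place_anomaly(p, par$radius_m[1], par$eps_r[1], par$sigma[1],
                       derive_seed(seed, 3))
  p
}

#' Extract the property volumes of a phantom
#'
#' @param p A `brain_phantom`.
#' @return `list(eps = <n^3 array>, sigma = <n^3 array>)`.
#' @export
phantom_volumes <- function(p) list(eps = p$eps_grid, sigma = p$sigma_grid)

#' @export
print.brain_phantom <- function(x, ...) {
  n <- x$grid_n
  cat(sprintf(
    "<brain_phantom> %d^3 voxels, %.3g mm pitch, %d tissues, %d anomaly(ies)\n",
    n, x$voxel_size_m * 1000, nrow(x$table), length(x$provenance$anomalies)
  ))
  cat(sprintf(
    "  scale %.2f | eps_r in [%.3g, %.3g] | sigma in [%.3g, %.3g] S/m\n",
    x$provenance$scale_factor, min(x$eps_grid), max(x$eps_grid),
    min(x$sigma_grid), max(x$sigma_grid)
  ))
  invisible(x)
}

#' Tidy summary of a phantom's tissue composition
#'
#' @param x A `brain_phantom`.
#' @param ... Unused.
#' @return A tibble with one row per label present (air, tissues, anomaly)
#'   and its voxel count and properties.
#' @method tidy brain_phantom
#' @export
tidy.brain_phantom <- function(x, ...) {
  ntis <- nrow(x$table)
  labs <- 0:(ntis + 1)
  counts <- tabulate(as.vector(x$label_grid) + 1L, nbins = ntis + 2)
  nm <- c("air", x$table$tissue, "anomaly")
  tibble::tibble(
    label = labs, tissue = nm, n_voxels = counts,
    eps_r = c(1, x$table$eps_r, if (length(x$provenance$anomalies))
      x$provenance$anomalies[[1]]$eps_r else NA_real_),
    sigma = c(0, x$table$sigma, if (length(x$provenance$anomalies))
      x$provenance$anomalies[[1]]$sigma else NA_real_)
  )[counts > 0 | labs <= ntis, ]
}

#' Plot the central axial slice of a phantom
#'
#' @param object A `brain_phantom`.
#' @param channel `"eps"` or `"sigma"`.
#' @param z Slice index (default: middle).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot brain_phantom
#' @export
autoplot.brain_phantom <- function(object, channel = c("eps", "sigma"),
                                   z = NULL, ...) {
  channel <- match.arg(channel)
  n <- object$grid_n
  z <- z %||% ((n + 1L) %/% 2L)
  g <- if (channel == "eps") object$eps_grid else object$sigma_grid
  df <- expand.grid(x = seq_len(n), y = seq_len(n))
  df$value <- as.vector(g[, , z])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = if (channel == "eps") "eps_r" else "sigma (S/m)") +
    ggplot2::labs(
      title = sprintf("%s, axial slice z = %d / %d", channel, z, n),
      x = NULL, y = NULL
    )
}
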