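test_that("default array reproduces the four-layer 60-dipole geometry", {
  arr <- default_array()
  expect_equal(nrow(arr$positions), 60)
  td <- tidy(arr)
  l1 <- td[td$layer == 1, ]
  expect_equal(nrow(l1), 32)
  expect_true(all(abs(l1$radius_m - 0.12) < 1e-12))
  expect_true(all(l1$z == -0.06))
  expect_equal(sum(td$layer == 2), 16)
  expect_true(all(abs(td$radius_m[td$layer == 2] - 0.115) < 1e-12))
  expect_equal(sum(td$layer == 3), 8)
  expect_equal(sum(td$layer == 4), 4)
  expect_true(all(td$z[td$layer == 4] == 0.10))
  # angular steps: first-layer azimuth increments of 11.25 degrees
  ang <- sort(atan2(l1$y, l1$x) %% (2 * pi))
  expect_equal(diff(ang)[1], 11.25 * pi / 180, tolerance = 1e-10)
  # an antenna inside the head region is rejected
  expect_error(build_array(data.frame(n = 1, radius_m = 0, z_m = 0)), "inside")
})

test_that("complex permittivity follows the lossy-medium sign convention", {
  omega <- 2 * pi * 3e8
  expect_equal(complex_permittivity(5, 0, omega), 5 + 0i)
  # menu value evaluated straight from the defining formula
  v <- complex_permittivity(90, 1.038, omega)
  expect_equal(Re(v), 90)
  expect_equal(Im(v), -1.038 / (omega * 8.8541878128e-12), tolerance = 1e-12)
  expect_lt(Im(complex_permittivity(40, 0.5, omega)), 0)
  expect_error(complex_permittivity(5, 0.1, -1), "omega")
})

test_that("dipole field matches an independent textbook evaluation", {
  arr <- default_array()
  k0 <- 2 * pi * arr$frequency_hz / 299792458
  # independent implementation: spherical-coordinate dipole field components
  dipole_ref <- function(r0, pt, k) {
    d <- pt - r0
    R <- sqrt(sum(d^2))
    ct <- d[3] / R # z-oriented dipole: theta from the z axis
    st <- sqrt(max(0, 1 - ct^2))
    ph <- exp(-1i * k * R) / (4 * pi)
    Er <- 2 * ct * ph * (1 / R^3 + 1i * k / R^2)
    Et <- st * ph * (1 / R^3 + 1i * k / R^2 - k^2 / R)
    # unit vectors
    rhat <- d / R
    if (st < 1e-12) that <- c(1, 0, 0) else {
      phat <- c(-d[2], d[1], 0) / sqrt(d[1]^2 + d[2]^2)
      that <- c(rhat[2] * phat[3] - rhat[3] * phat[2],
                rhat[3] * phat[1] - rhat[1] * phat[3],
                rhat[1] * phat[2] - rhat[2] * phat[1]) * -1
    }
    Er * rhat + Et * that
  }
  set.seed(4)
  for (i in 1:5) {
    pt <- runif(3, -0.1, 0.1)
    E <- incident_field(arr, 1, rbind(pt))
    Eref <- dipole_ref(arr$positions[1, ], pt, k0)
    expect_equal(unname(as.vector(E)), unname(Eref), tolerance = 1e-10)
  }
  # far-field 1/r decay along a fixed direction
  dir <- c(1, 2, 0.5) / sqrt(5.25)
  r <- 50 / k0
  e1 <- incident_field(arr, 1, rbind(arr$positions[1, ] + r * dir))
  e2 <- incident_field(arr, 1, rbind(arr$positions[1, ] + 2 * r * dir))
  expect_equal(sqrt(sum(Mod(e2)^2)) / sqrt(sum(Mod(e1)^2)), 0.5,
               tolerance = 0.01)
  # on the dipole axis the transverse far-field components vanish
  eax <- incident_field(arr, 1, rbind(arr$positions[1, ] + c(0, 0, 3)))
  expect_lt(max(Mod(eax[, 1:2])) / Mod(eax[, 3]), 1e-10)
  expect_error(incident_field(arr, 1, rbind(arr$positions[1, ])), "source")
})

test_that("Green's dyadic obeys reciprocity, the static limit and its definition", {
  k0 <- 2 * pi
  r1 <- c(0.03, -0.02, 0.05); r2 <- c(-0.04, 0.06, -0.01)
  G12 <- greens_interaction(r1, r2, k0)
  G21 <- greens_interaction(r2, r1, k0)
  expect_lt(max(Mod(G12 - t(G21))), 1e-12)
  expect_error(greens_interaction(r1, r1, k0), "singular|coincident")

  # static limit: at kR = 1e-4 the dyadic approaches (3 rhat rhat - I)/(4 pi k^2 R^3)
  ks <- 1e-4 / sqrt(sum((r1 - r2)^2))
  Gs <- greens_interaction(r1, r2, ks)
  d <- r1 - r2; R <- sqrt(sum(d^2)); u <- d / R
  Gstat <- (3 * outer(u, u) - diag(3)) / (4 * pi * ks^2 * R^3)
  expect_lt(max(Mod(Gs - Gstat)) / max(Mod(Gstat)), 1e-6)

  # finite-difference oracle: G = (I + grad grad / k^2) g built numerically
  g <- function(p, q) {
    R <- sqrt(sum((p - q)^2))
    exp(-1i * k0 * R) / (4 * pi * R)
  }
  set.seed(7)
  for (rep in 1:10) {
    a <- runif(3, -0.5, 0.5); b <- runif(3, -0.5, 0.5)
    if (sqrt(sum((a - b)^2)) < 0.2) next
    h <- 1e-4
    Gnum <- matrix(0i, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      ei <- ej <- numeric(3); ei[i] <- h; ej[j] <- h
      d2 <- (g(a + ei + ej, b) - g(a + ei - ej, b) -
               g(a - ei + ej, b) + g(a - ei - ej, b)) / (4 * h^2)
      Gnum[i, j] <- d2 / k0^2
    }
    Gnum <- Gnum + g(a, b) * diag(3)
    Ga <- greens_interaction(a, b, k0)
    expect_lt(max(Mod(Ga - Gnum)) / max(Mod(Ga)), 1e-4)
  }
})

test_that("Born mode is linear in the contrast and zero without it", {
  op <- cached("op10born", build_forward_operator(default_array(), 10, 0.24, "born"))
  air <- list(eps = array(1, rep(10, 3)), sigma = array(0, rep(10, 3)))
  s0 <- solve_scattered_field(air, operator = op, method = "born")
  expect_true(all(Mod(s0$e_scat) == 0))
  v <- sphere_volumes(10)
  s1 <- solve_scattered_field(v, operator = op, method = "born")
  half <- list(eps = 1 + (v$eps - 1) / 2, sigma = v$sigma / 2)
  s2 <- solve_scattered_field(half, operator = op, method = "born")
  expect_equal(s2$e_scat, s1$e_scat / 2, tolerance = 1e-14)
  expect_equal(dim(s1$e_scat), c(60, 59, 3))
  expect_length(s1$input_vec, 360)
})

test_that("iterative full mode matches the dense direct oracle", {
  op <- operator_grid10()
  v <- sphere_volumes(10)
  sf <- solve_scattered_field(v, operator = op, method = "full",
                              solver_tol = 1e-13)
  sd_ <- braintomo:::solve_scattered_field_dense(v, operator = op)
  rel <- sqrt(sum(Mod(sf$e_scat - sd_$e_scat)^2) / sum(Mod(sd_$e_scat)^2))
  expect_lt(rel, 1e-8)
})

test_that("full mode is reciprocal and reduces to Born at weak contrast", {
  op <- operator_grid10()
  v <- sphere_volumes(10)
  sf <- solve_scattered_field(v, operator = op, method = "full",
                              solver_tol = 1e-10)
  # z-component reciprocity for matched z dipoles
  e <- sf$e_scat
  pos <- function(t, r) if (r < t) r else r - 1
  pairs <- cbind(c(3, 10, 25), c(40, 55, 33))
  for (i in seq_len(nrow(pairs))) {
    t <- pairs[i, 1]; r <- pairs[i, 2]
    expect_lt(Mod(e[t, pos(t, r), 3] - e[r, pos(r, t), 3]) / max(Mod(e)), 1e-9)
  }
  # Born limit: relative full-vs-born difference shrinks with contrast
  rel <- vapply(c(0.5, 0.1, 0.01), function(ct) {
    vv <- sphere_volumes(10, eps_in = 1 + ct, sigma_in = 0)
    f <- solve_scattered_field(vv, operator = op, method = "full",
                               solver_tol = 1e-10)
    b <- solve_scattered_field(vv, operator = op, method = "born")
    sqrt(sum(Mod(f$e_scat - b$e_scat)^2) / sum(Mod(f$e_scat)^2))
  }, numeric(1))
  expect_true(all(diff(rel) < 0))
})

test_that("aggregation sums transmitters into the fixed 2xM layout", {
  arr <- default_array()
  e <- array(0i, dim = c(60, 59, 3))
  e[5, 10, 2] <- 1 + 2i # transmitter 5, receiver 11 (self excluded), y component
  rec <- braintomo:::new_scatter_record(e, arr)
  v <- rec$input_vec
  expect_length(v, 360)
  slot <- (2 - 1) * 60 + 11 # y-component block, receiver 11
  expect_equal(v[slot], 1)
  expect_equal(v[180 + slot], 2)
  expect_equal(sum(v != 0), 2)
  # summation over transmitters is order-invariant: a receiver-centric
  # accumulation over a shuffled transmitter list reproduces the input vector
  set.seed(1)
  e2 <- array(complex(real = rnorm(60 * 59 * 3), imaginary = rnorm(60 * 59 * 3)),
              dim = c(60, 59, 3))
  rec2 <- braintomo:::new_scatter_record(e2, arr)
  agg <- matrix(0i, 60, 3)
  for (t in sample(60)) {
    for (r in seq_len(60)[-t]) {
      agg[r, ] <- agg[r, ] + e2[t, if (r < t) r else r - 1, ]
    }
  }
  expect_equal(rec2$input_vec, c(Re(as.vector(agg)), Im(as.vector(agg))),
               tolerance = 1e-12)
})

test_that("noise injection realizes the requested relative power", {
  arr <- default_array()
  set.seed(2)
  e <- array(complex(real = rnorm(60 * 59 * 3), imaginary = rnorm(60 * 59 * 3)),
             dim = c(60, 59, 3))
  rec <- braintomo:::new_scatter_record(e, arr)
  # pooled over many realizations, noise power / signal power -> 10^(-20/10)
  ratios <- vapply(1:40, function(s) {
    nr <- add_noise(rec, -20, seed = s)
    sum(Mod(nr$e_scat - rec$e_scat)^2) / sum(Mod(rec$e_scat)^2)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.01), 5e-4) # within the 5% calibration band
  # two seeds differ in realization, agree in power
  n1 <- add_noise(rec, -20, seed = 1)
  n2 <- add_noise(rec, -20, seed = 2)
  expect_false(identical(n1$e_scat, n2$e_scat))
  expect_identical(add_noise(rec, NULL)$e_scat, rec$e_scat)
  zero <- braintomo:::new_scatter_record(array(0i, dim = c(60, 59, 3)), arr)
  expect_error(add_noise(zero, -20), "zero-signal")
  # post-aggregation option perturbs only the input vector
  pa <- add_noise(rec, -20, seed = 3, where = "aggregated")
  expect_identical(pa$e_scat, rec$e_scat)
  expect_false(identical(pa$input_vec, rec$input_vec))
})
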