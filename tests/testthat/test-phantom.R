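test_that("default tissue table satisfies its physical contract", {
  tb <- default_tissue_table()
  expect_equal(nrow(tb), 16)
  expect_false(anyDuplicated(tb$tissue) > 0)
  expect_true(all(tb$eps_r >= 1))
  expect_true(all(tb$sigma >= 0))
  expect_error(tissue_table(data.frame(tissue = c("a", "a"), eps_r = c(2, 3),
                                       sigma = c(0, 0))), "unique")
  expect_error(tissue_table(data.frame(tissue = "a", eps_r = 0.5, sigma = 0)),
               "eps_r")
})

test_that("base phantom realizes all 16 nested tissues and is deterministic", {
  p32 <- build_base_phantom(grid_n = 32, seed = 7)
  p64 <- build_base_phantom(grid_n = 64, seed = 7)
  for (p in list(p32, p64)) {
    labs <- setdiff(unique(as.vector(p$label_grid)), 0L)
    expect_setequal(labs, 1:16)
  }
  # domain arithmetic
  expect_equal(p64$voxel_size_m * p64$grid_n, p64$domain_side_m,
               tolerance = 1e-12)
  # air outside the head
  expect_equal(p64$eps_grid[1, 1, 1], 1)
  expect_equal(p64$sigma_grid[1, 1, 1], 0)
  expect_true(all(p64$eps_grid >= 1), all(p64$sigma_grid >= 0))
  # determinism
  p64b <- build_base_phantom(grid_n = 64, seed = 7)
  expect_identical(p64$label_grid, p64b$label_grid)
  # too-coarse grid names the tissue it cannot realize
  expect_error(build_base_phantom(grid_n = 16, seed = 7), "tissue")
})

test_that("scaling acts linearly on geometry and properties", {
  p <- build_base_phantom(grid_n = 32, seed = 7)
  expect_identical(scale_phantom(p, 1)$label_grid, p$label_grid)
  ps <- scale_phantom(p, 0.8)
  # a tissue with eps_r 49 (skin) scales to 39.2
  expect_equal(ps$table$eps_r[ps$table$tissue == "skin"], 49 * 0.8)
  expect_equal(ps$table$sigma, p$table$sigma * 0.8)
  # bounding box of the head scales with the factor, within a voxel
  extent <- function(q) {
    idx <- which(q$label_grid > 0, arr.ind = TRUE)
    max(idx[, 1]) - min(idx[, 1]) + 1
  }
  pb <- scale_phantom(p, 1.2)
  expect_lt(abs(extent(pb) - 1.2 * extent(p)), 2.5)
  # geometry that would leave the imaging domain is rejected
  expect_error(scale_phantom(p, 3), "exceeds")
  # scale then inverse-scale restores the label grid (conservation)
  back <- scale_phantom(scale_phantom(p, 1.2), 1 / 1.2)
  expect_lt(mean(back$label_grid != p$label_grid), 0.02)
})

test_that("boundary deformation is seeded, bounded and nesting-preserving", {
  p <- build_base_phantom(grid_n = 64, seed = 7)
  expect_identical(deform_tissue_boundaries(p, 0, seed = 1)$label_grid,
                   p$label_grid)
  d1 <- deform_tissue_boundaries(p, 0.002, seed = 1)
  d2 <- deform_tissue_boundaries(p, 0.002, seed = 2)
  expect_false(identical(d1$label_grid, d2$label_grid))
  expect_identical(deform_tissue_boundaries(p, 0.002, seed = 1)$label_grid,
                   d1$label_grid)
  # a 2 mm displacement moves a small but nonzero voxel fraction
  frac <- mean(d1$label_grid != p$label_grid)
  expect_gt(frac, 0)
  expect_lt(frac, 0.2)
  # nesting survives: every deeper region lies inside every shallower surface
  expect_true(all(apply(d1$surfaces, c(2, 3), diff) < 0))
  expect_setequal(setdiff(unique(as.vector(d1$label_grid)), 0L), 1:16)
  # unpreservable deformation errors out
  expect_error(deform_tissue_boundaries(p, 0.2, seed = 1), "nesting")
})

test_that("anomaly insertion relabels exactly the sphere", {
  p <- build_base_phantom(table = tiny_table(), grid_n = 64, seed = 7)
  a <- anomaly_spec(c(0, 0, 0), 0.007, 150, 1.73)
  pa <- insert_anomaly(p, a)
  n_anom <- sum(pa$label_grid == nrow(p$table) + 1)
  expected <- 4 / 3 * pi * 0.007^3 / p$voxel_size_m^3
  expect_gt(n_anom, expected * 0.7)
  expect_lt(n_anom, expected * 1.3)
  expect_equal(max(pa$eps_grid), 150)
  anom <- pa$label_grid == nrow(p$table) + 1
  expect_true(all(pa$sigma_grid[anom] == 1.73))
  # untouched voxels are identical
  same <- pa$label_grid != nrow(p$table) + 1
  expect_identical(pa$eps_grid[same], p$eps_grid[same])
  # sub-voxel sphere still claims its centre voxel
  tiny <- insert_anomaly(p, anomaly_spec(c(0.001, 0.001, 0.001), 1e-4, 90, 1.038))
  expect_gte(sum(tiny$label_grid == nrow(p$table) + 1), 1)
  # a sphere poking into air is refused
  expect_error(insert_anomaly(p, anomaly_spec(c(0.11, 0, 0), 0.007, 90, 1.038)),
               "air")
})

test_that("strategy draws stay on the published menus with uniform rates", {
  draws <- sample_strategy_params(10000, seed = 42, with_anomaly = TRUE)
  expect_true(all(draws$factor %in% c(0.8, 0.9, 1.0, 1.1, 1.2)))
  expect_true(all(draws$radius_m %in% c(0.004, 0.007, 0.010)))
  expect_true(all(draws$eps_r %in% c(90, 120, 150)))
  expect_true(all(draws$sigma %in% c(1.038, 1.384, 1.73)))
  freq <- table(draws$factor) / nrow(draws)
  expect_true(all(abs(freq - 0.2) < 0.02))
  # deformation order is a permutation of the tissues
  expect_true(all(vapply(draws$order[1:50], function(o) all(sort(o) == 1:16),
                         logical(1))))
  # no-anomaly draws carry no anomaly attributes
  nodraw <- sample_strategy_params(10, seed = 1, with_anomaly = FALSE)
  expect_true(all(is.na(nodraw$radius_m)))
  # determinism
  expect_identical(sample_strategy_params(5, seed = 3)$factor,
                   sample_strategy_params(5, seed = 3)$factor)
})

test_that("random_phantom chains the full strategy deterministically", {
  p1 <- random_phantom(11, table = tiny_table(), grid_n = 20, with_anomaly = TRUE)
  p2 <- random_phantom(11, table = tiny_table(), grid_n = 20, with_anomaly = TRUE)
  expect_identical(p1$label_grid, p2$label_grid)
  expect_equal(length(p1$provenance$anomalies), 1)
  anom_lab <- nrow(p1$table) + 1
  expect_gt(sum(p1$label_grid == anom_lab), 0)
  # tidy summary covers air + tissues
  td <- tidy(p1)
  expect_s3_class(td, "tbl_df")
  expect_true("air" %in% td$tissue)
})

test_that("dataset generation writes resumable, deterministic records", {
  dir1 <- withr::local_tempdir()
  cfg <- list(grid_n = 16L, table = tiny_table())
  ds <- generate_dataset(3, cfg, seed = 5, out_dir = dir1)
  expect_equal(ds$n_samples, 3)
  r1 <- read_sample(ds, 1)
  expect_length(r1$input, 360)
  expect_equal(dim(r1$escat), c(60, 59, 3))
  expect_equal(dim(r1$eps), rep(16, 3))
  expect_true(file.exists(file.path(dir1, "meta.yaml")))
  # same seed elsewhere: byte-identical volumes
  dir2 <- withr::local_tempdir()
  ds2 <- generate_dataset(3, cfg, seed = 5, out_dir = dir2)
  expect_identical(read_sample(ds2, 2)$eps, read_sample(ds, 2)$eps)
  # resume: deleting one record regenerates only it, identically
  file.remove(braintomo:::sample_path(dir1, 2))
  ds3 <- generate_dataset(3, cfg, seed = 5, out_dir = dir1)
  expect_identical(read_sample(ds3, 2)$input, read_sample(ds2, 2)$input)
})
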