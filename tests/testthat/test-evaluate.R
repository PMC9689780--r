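test_that("model misfit reproduces its defining identities", {
  # single-channel identities and the 2-voxel hand example
  expect_equal(model_misfit(c(3, 4), c(3, 4)), 0)
  expect_equal(model_misfit(c(0, 0), c(3, 4)), 100)
  expect_equal(model_misfit(c(3, 0), c(3, 4)), 80)
  # two-channel: perfect -> 0, zero -> 100 regardless of channel scales
  truth <- list(eps = array(runif(27, 1, 80), rep(3, 3)),
                sigma = array(runif(27, 0, 2), rep(3, 3)))
  expect_equal(as.numeric(model_misfit(truth, truth)), 0)
  zero <- list(eps = truth$eps * 0, sigma = truth$sigma * 0)
  expect_equal(as.numeric(model_misfit(zero, truth)), 100)
  # scale invariance: scaling recon and truth together changes nothing
  recon <- list(eps = truth$eps + rnorm(27), sigma = truth$sigma + 0.1)
  m1 <- as.numeric(model_misfit(recon, truth))
  scaled <- function(v, c) list(eps = v$eps * c, sigma = v$sigma * c)
  m2 <- as.numeric(model_misfit(scaled(recon, 7), scaled(truth, 7)))
  expect_equal(m1, m2, tolerance = 1e-12)
  # per-channel attributes agree with direct computation
  expect_equal(attr(model_misfit(recon, truth), "eps_pct"),
               100 * sqrt(sum((recon$eps - truth$eps)^2) / sum(truth$eps^2)))
  expect_error(model_misfit(zero, zero), "nonzero")
})

test_that("data misfit is zero for the truth, 100% for air, phase-invariant", {
  op <- cached("op10born", build_forward_operator(default_array(), 10, 0.24, "born"))
  v <- sphere_volumes(10)
  rec <- solve_scattered_field(v, operator = op, method = "born")
  expect_lt(data_misfit(v, rec, op), 0.1)
  air <- list(eps = array(1, rep(10, 3)), sigma = array(0, rep(10, 3)))
  expect_equal(data_misfit(air, rec, op), 100)
  # relative L2 is invariant under a common phase rotation of both field sets
  rot <- rec
  rot$e_scat <- rec$e_scat * exp(0.73i)
  vrot_misfit <- 100 * sqrt(sum(Mod(rot$e_scat - rec$e_scat * exp(0.73i))^2) /
                              sum(Mod(rec$e_scat * exp(0.73i))^2))
  expect_equal(vrot_misfit, 0)
})

test_that("anomaly detection localizes spheres and degrades gracefully", {
  n <- 24
  side <- 0.24
  g <- braintomo:::voxel_grid(n, side)
  mk_recon <- function(center, radius, eps_in = 120) {
    d2 <- (g[, 1] - center[1])^2 + (g[, 2] - center[2])^2 + (g[, 3] - center[3])^2
    eps <- array(40, rep(n, 3))
    eps[d2 <= radius^2] <- eps_in
    list(eps = eps, sigma = array(0.5, rep(n, 3)))
  }
  a <- anomaly_spec(c(0.02, -0.01, 0.015), 0.02, 120, 1.384)
  truth <- mk_recon(a$center_m, a$radius_m)
  r0 <- anomaly_detection_report(truth, truth, a, side)
  expect_true(r0$detected)
  expect_lt(r0$centroid_err_mm, 1)
  expect_lt(r0$radius_err_mm, side / n * 1000)
  # noisy reconstruction still localizes within a couple of voxels
  set.seed(3)
  noisy <- truth
  noisy$eps <- noisy$eps + array(rnorm(n^3, 0, 5), rep(n, 3))
  rn <- anomaly_detection_report(noisy, truth, a, side)
  expect_true(rn$detected)
  expect_lt(rn$centroid_err_mm, 2 * side / n * 1000)
  # uniform brain: nothing above threshold -> not detected, no error
  uni <- list(eps = array(40, rep(n, 3)), sigma = array(0.5, rep(n, 3)))
  ru <- anomaly_detection_report(uni, truth, a, side)
  expect_false(ru$detected)
  expect_true(is.na(ru$centroid_err_mm))
})

test_that("connected-component labelling separates distant blobs", {
  m <- array(FALSE, c(10, 10, 10))
  m[2:3, 2:3, 2:3] <- TRUE
  m[8:9, 8:9, 8:9] <- TRUE
  lab <- braintomo:::label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(sum(lab == 1), 8)
  expect_equal(sum(lab == 2), 8)
  expect_true(all(lab[!m] == 0))
})

test_that("benchmark table has the stage x noise-level structure", {
  # stub fits: an fcernn fit trained briefly on tiny synthetic samples and an
  # identity U-Net; this checks protocol structure, not reconstruction quality
  set.seed(11)
  samples <- lapply(1:6, function(i) list(
    input = rnorm(360),
    eps = array(runif(12^3, 1, 80), rep(12, 3)),
    sigma = array(runif(12^3, 0, 2), rep(12, 3))
  ))
  fit1 <- train_fcernn(samples, n_blocks = 1, epochs = 2, lr = 1e-3,
                       batch_size = 2, val_frac = 0.2, seed = 1)
  sp <- unet_spec(base_channels = 4, residual = TRUE, head_init_scale = 0)
  fit2 <- list(model = build_unet(sp, seed = 1), spec = sp,
               slice_hw = c(12, 12))
  class(fit2) <- "unet_fit"
  op <- cached("op12born",
               build_forward_operator(default_array(), 12, 0.24, "born"))
  test_samples <- lapply(1:2, function(i) {
    v <- sphere_volumes(12, eps_in = 40, sigma_in = 0.5)
    rec <- solve_scattered_field(v, operator = op, method = "born")
    list(input = rec$input_vec, escat = rec$e_scat, eps = v$eps, sigma = v$sigma)
  })
  bench <- run_benchmark(fit1, fit2, test_samples, op,
                         noise_levels_db = c(NA, -10, -20, -30, -40),
                         n_noise_reals = 2, seed = 3,
                         include_data_misfit = TRUE)
  # 2 samples x [1 noise-free + 4 levels x 2 reps] x 2 stages
  expect_equal(nrow(bench), 2 * (1 + 4 * 2) * 2)
  expect_setequal(unique(bench$stage), c("fcernn", "fcernn+unet"))
  expect_true(all(bench$model_misfit_pct >= 0))
  expect_true(all(is.finite(bench$data_misfit_pct)))
  sm <- summarize_benchmark(bench)
  expect_equal(nrow(sm), 2 * 5)
  # identity U-Net: enhanced stage equals the raw stage up to the clamp
  raw <- bench[bench$stage == "fcernn", ]
  enh <- bench[bench$stage == "fcernn+unet", ]
  expect_equal(enh$model_misfit_pct, raw$model_misfit_pct, tolerance = 1e-6)
  # reproducibility: identical call, identical table
  bench2 <- run_benchmark(fit1, fit2, test_samples, op,
                          noise_levels_db = c(NA, -10, -20, -30, -40),
                          n_noise_reals = 2, seed = 3,
                          include_data_misfit = TRUE)
  expect_identical(bench$model_misfit_pct, bench2$model_misfit_pct)
})
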