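ns <- asNamespace("braintomo")

test_that("architecture spec validates shape arithmetic and builds all-conv", {
  sp <- fcernn_spec(input_len = 360, block_side = 8)
  expect_equal(tail(sp$shape_trace$encoder_len, 1), 8)
  expect_equal(tail(sp$shape_trace$decoder_side, 1), 8)
  expect_equal(sp$encoder_channels, c(32L, 32L, 64L, 64L, 128L, 128L, 256L, 256L))
  expect_equal(sp$encoder_kernels, c(2L, 2L, 2L, 2L, 2L, 2L, 4L, 1L))
  expect_equal(prod(sp$decoder_strides) * 2, 8)
  expect_error(fcernn_spec(block_side = 7), "even")
  # an unachievable block side reports the broken factorization
  expect_error(fcernn_spec(block_side = 2 * 7 * 5 * 5), "factorization")

  model <- build_fcernn(sp, seed = 1)
  types <- vapply(model$layers, `[[`, character(1), "type")
  # no fully connected layers: everything is conv/deconv/norm/activation/reshape
  expect_true(all(types %in% c("conv1d", "bn", "relu", "to_matrix",
                               "deconv3dn", "dense_channels")))
  expect_equal(sum(types == "conv1d"), 8)
  expect_equal(sum(types == "deconv3dn"), 3)
  # every conv is followed by batch normalization then ReLU
  conv_pos <- which(types %in% c("conv1d", "deconv3dn"))
  expect_true(all(types[conv_pos[conv_pos < length(types) - 1] + 1] == "bn"))
  # forward of zeros in eval mode is finite, with the block's shape
  fw <- ns$fcernn_forward(model, matrix(0, 2, 360), training = FALSE)
  arr <- ns$fcernn_output_array(fw$y, 2, sp)
  expect_equal(dim(arr), c(2, 8, 8, 8, 2))
  expect_true(all(is.finite(arr)))
})

test_that("parameter count is modest and resolution-insensitive outside the decoder", {
  n8 <- build_fcernn(fcernn_spec(block_side = 8), 1)$n_params
  n24 <- build_fcernn(fcernn_spec(block_side = 24), 1)$n_params
  expect_lt(n8, 1e7)
  expect_lt(n24, 1e7)
  # encoder parameters are shared arithmetic: the difference comes from the
  # decoder stride kernels only
  enc_params <- function(side) {
    m <- build_fcernn(fcernn_spec(block_side = side), 1)
    types <- vapply(m$layers, `[[`, character(1), "type")
    sum(vapply(m$layers[types == "conv1d"],
               function(l) length(l$W) + length(l$b), numeric(1)))
  }
  expect_equal(enc_params(8), enc_params(24))
})

test_that("volume partition tiles exactly, disjointly, in fixed order", {
  part <- partition_volume(c(64, 64, 64), 8)
  expect_length(part, 8)
  expect_true(all(vapply(part, function(b) length(b$x), numeric(1)) == 32))
  expect_equal(partition_volume(c(64, 64, 64), 1)[[1]]$x, 1:64)
  expect_error(partition_volume(c(64, 64, 64), 6), "cube")
  expect_error(partition_volume(c(10, 10, 10), 27), "evenly")
  # exhaustive cover/disjointness at 16^3 with 8 blocks
  p16 <- partition_volume(rep(16, 3), 8)
  seen <- array(0L, rep(16, 3))
  for (b in p16) seen[b$x, b$y, b$z] <- seen[b$x, b$y, b$z] + 1L
  expect_true(all(seen == 1L))
  # block assembly inverts extraction exactly
  v <- array(rnorm(16^3), rep(16, 3))
  blocks <- lapply(p16, extract_block, v = v)
  expect_identical(assemble_blocks(blocks, p16, 16), v)
})

test_that("normalization statistics round-trip and reject degenerate targets", {
  set.seed(8)
  eps <- array(runif(64, 1, 80), c(4, 4, 4))
  sig <- array(runif(64, 0, 2), c(4, 4, 4))
  st <- compute_norm_stats(matrix(rnorm(6 * 360), 6), list(eps), list(sig))
  nv <- normalize_volume(list(eps = eps, sigma = sig), st)
  expect_true(all(nv$eps >= 0 & nv$eps <= 1))
  back <- denormalize_volume(nv, st)
  expect_equal(back$eps, eps, tolerance = 1e-10)
  expect_equal(back$sigma, sig, tolerance = 1e-10)
  flat <- array(5, c(4, 4, 4))
  expect_error(compute_norm_stats(matrix(rnorm(360), 1), list(flat), list(sig)),
               "degenerate")
})

test_that("training memorizes a 2-sample dataset and is seed-deterministic", {
  set.seed(5)
  samples <- lapply(1:2, function(i) list(
    input = rnorm(360),
    eps = array(runif(64, 1, 80), c(4, 4, 4)),
    sigma = array(runif(64, 0, 2), c(4, 4, 4))
  ))
  fit <- train_fcernn(samples, n_blocks = 1, epochs = 400, lr = 1e-2,
                      batch_size = 2, val_frac = 0, seed = 1)
  expect_lt(tail(fit$history$train_mse, 1), 1e-3)
  # loss decreases over training
  expect_lt(fit$history$train_mse[50], fit$history$train_mse[1])
  # identical reruns
  f2 <- train_fcernn(samples, n_blocks = 1, epochs = 25, lr = 1e-2,
                     batch_size = 2, val_frac = 0, seed = 9)
  f3 <- train_fcernn(samples, n_blocks = 1, epochs = 25, lr = 1e-2,
                     batch_size = 2, val_frac = 0, seed = 9)
  expect_equal(tail(f2$history$train_mse, 1), tail(f3$history$train_mse, 1),
               tolerance = 1e-6)
  # predictions reproduce the memorized sample after clamping
  v <- predict_volume(fit, samples[[1]]$input)
  expect_true(all(v$eps >= 1), all(v$sigma >= 0))
  expect_lt(as.numeric(model_misfit(v, list(eps = samples[[1]]$eps,
                                            sigma = samples[[1]]$sigma))), 20)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1)
})

test_that("block sub-models are independent: removing one leaves others intact", {
  set.seed(6)
  samples <- lapply(1:4, function(i) list(
    input = rnorm(360),
    eps = array(runif(8^3, 1, 80), c(8, 8, 8)),
    sigma = array(runif(8^3, 0, 2), c(8, 8, 8))
  ))
  fit <- train_fcernn(samples, n_blocks = 8, epochs = 3, lr = 1e-3,
                      batch_size = 2, val_frac = 0.25, seed = 2)
  expect_length(fit$models, 8)
  full <- predict_volume(fit, samples[[1]]$input)
  crippled <- fit
  crippled$models[5] <- list(NULL)
  expect_error(predict_volume(crippled, samples[[1]]$input), "block 5")
  # blocks other than the removed one are bit-identical when predicted alone
  part <- fit$partition
  for (bi in c(1, 8)) {
    one <- fit
    keep <- part[bi]
    one$models <- fit$models[bi]
    one$partition <- keep
    v1 <- predict_volume(one, samples[[1]]$input)
    box <- part[[bi]]
    expect_identical(v1$eps[box$x, box$y, box$z],
                     full$eps[box$x, box$y, box$z])
  }
})
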