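# Full-convolutional electromagnetic reconstruction network (3-D).
#
# Encoder: eight 1-D conv layers over the 2-channel measurement vector
# (kernel sizes 2,2,2,2,2,2,4,1; channels 32,32,64,64,128,128,256,256;
# down-sampling strides 2,4,2,4 at layers 1,3,5,7), each followed by batch
# normalization and ReLU. The input is tiled periodically from 2 x M to
# 2 x (8 * 64) so the strided encoder lands exactly on an 8 x 256 feature
# vector, reshaped to a 2x2x2x256 volume. Decoder: three transposed 3-D
# convolutions (channels 128, 64, 32, kernel == stride) + BN + ReLU, with
# strides auto-factorized so their product is block_side / 2. Reconstruction
# head: a kernel-1 transposed conv to 2 channels (permittivity,
# conductivity). No fully connected layers anywhere.

.enc_channels <- c(32L, 32L, 64L, 64L, 128L, 128L, 256L, 256L)
.enc_kernels <- c(2L, 2L, 2L, 2L, 2L, 2L, 4L, 1L)
.enc_strides <- c(2L, 1L, 4L, 1L, 2L, 1L, 4L, 1L)
.dec_channels <- c(128L, 64L, 32L)

# Factor v into three integer strides <= 6, preferring balanced factors
# (small maximum stride keeps the transposed-conv kernels small).
factor_strides <- function(v) {
  if (v < 1) return(NULL)
  best <- NULL
  for (a in 1:6) for (b in 1:6) for (c_ in 1:6) {
    if (a * b * c_ == v && a >= b && b >= c_) {
      if (is.null(best) || a < best[1]) best <- c(a, b, c_)
    }
  }
  best
}

#' Specify a reconstruction-network architecture
#'
#' Validates the shape arithmetic at specification time: the padded input
#' length must survive the encoder strides to an 8 x 256 feature vector, and
#' `block_side / 2` must factor into three decoder strides.
#'
#' @param input_len Length of the measurement input vector (2 x M).
#' @param block_side Output block side in voxels (even, >= 2).
#' @param bn_chi Batch-norm stabilizing constant.
#' @return An `fcernn_spec` with the full shape trace.
#' @examples
#' fcernn_spec(input_len = 360, block_side = 8)$shape_trace
#' @export
fcernn_spec <- function(input_len = 360, block_side = 8, bn_chi = 1e-3) {
  if (input_len %% 2 != 0) abort("input_len must be 2 x M")
  m <- input_len / 2
  m_pad <- 8L * prod(.enc_strides) # 512: lands on an 8-long feature vector
  if (m > m_pad)
    abort(sprintf("input channel length %d exceeds the padded encoder length %d", m, m_pad))
  lens <- Reduce(function(L, s) as.integer(ceiling(L / s)), .enc_strides,
                 accumulate = TRUE, init = m_pad)
  if (tail(lens, 1) != 8)
    abort(sprintf("encoder shape trace broken: %s", paste(lens, collapse = " -> ")))
  if (block_side < 2 || block_side %% 2 != 0)
    abort("block_side must be an even integer >= 2")
  ds <- factor_strides(block_side %/% 2L)
  if (is.null(ds))
    abort(sprintf(
      "no decoder stride factorization: block_side %d needs block_side/2 = %d as a product of three strides <= 6 (shape trace: 2 -> ... -> %d)",
      block_side, block_side %/% 2L, block_side
    ))
  sides <- Reduce(`*`, ds, accumulate = TRUE, init = 2L)
  nm <- nested_raster_map(ds, block_side)
  structure(
    list(
      input_len = as.integer(input_len), m = as.integer(m),
      m_pad = m_pad, block_side = as.integer(block_side),
      encoder_channels = .enc_channels, encoder_kernels = .enc_kernels,
      encoder_strides = .enc_strides, decoder_channels = .dec_channels,
      decoder_strides = ds, bn_chi = bn_chi,
      nested_raster = nm$L, raster_nested = nm$inv,
      shape_trace = list(encoder_len = lens, decoder_side = sides)
    ),
    class = "fcernn_spec"
  )
}

# The matrix-form decoder keeps cells in "nested" order: children of one
# expansion are appended offset-block-major. This computes, for each nested
# cell, its raster (x-fastest) linear index in the assembled block, plus the
# inverse map.
nested_raster_map <- function(strides, block_side) {
  x <- (0:7) %% 2
  y <- ((0:7) %/% 2) %% 2
  z <- (0:7) %/% 4
  for (s in strides) {
    P <- length(x)
    nx <- numeric(P * s^3); ny <- nx; nz <- nx
    o <- 0L
    for (oz in 0:(s - 1)) for (oy in 0:(s - 1)) for (ox in 0:(s - 1)) {
      idx <- seq_len(P) + P * o
      nx[idx] <- x * s + ox
      ny[idx] <- y * s + oy
      nz[idx] <- z * s + oz
      o <- o + 1L
    }
    x <- nx; y <- ny; z <- nz
  }
  B <- block_side
  L <- as.integer(x + B * y + B * B * z + 1)
  inv <- integer(B^3)
  inv[L] <- seq_along(L)
  list(L = L, inv = inv)
}

#' Build a reconstruction-network model for one output block
#'
#' @param spec An [fcernn_spec()].
#' @param seed Seed for weight initialization.
#' @return An `fcernn_model` (layer list, spec, parameter count).
#' @export
build_fcernn <- function(spec = fcernn_spec(), seed = 1) {
  layers <- list()
  cin <- 2L
  with_seed(seed, {
    for (i in seq_len(8)) {
      co <- spec$encoder_channels[i]
      layers <- c(layers, list(
        mk_conv1d(spec$encoder_kernels[i], spec$encoder_strides[i], cin, co),
        mk_bn(co, chi = spec$bn_chi), mk_relu()
      ))
      cin <- co
    }
    layers <- c(layers, list(mk_to_matrix()))
    for (j in seq_len(3)) {
      co <- spec$decoder_channels[j]
      layers <- c(layers, list(
        mk_deconv3dn(spec$decoder_strides[j], cin, co),
        mk_bn(co, chi = spec$bn_chi), mk_relu()
      ))
      cin <- co
    }
    layers <- c(layers, list(mk_dense_channels(cin, 2L)))
  })
  structure(
    list(layers = layers, spec = spec, n_params = seq_param_count(layers)),
    class = "fcernn_model"
  )
}

# Input vectors (N x 2M) -> 2-channel tensors (N, m_pad, 2). The M-long
# channels are tiled periodically to the encoder length so that every
# strided-conv receptive field (the final feature cells each see only a
# window of the sequence) receives measurement signal rather than padding.
fcernn_input_tensor <- function(x, spec) {
  x <- rbind(x)
  n <- nrow(x)
  idx <- ((seq_len(spec$m_pad) - 1L) %% spec$m) + 1L
  arr <- array(0, dim = c(n, spec$m_pad, 2))
  arr[, , 1] <- x[, idx]
  arr[, , 2] <- x[, spec$m + idx]
  arr
}

# Forward pass; the output is a matrix (N * block_side^3, 2) with rows
# (sample fastest, nested cell slower) and the two property channels as
# columns. fcernn_output_array() rearranges it into (N, B, B, B, 2).
fcernn_forward <- function(model, x, training = FALSE) {
  xt <- fcernn_input_tensor(x, model$spec)
  seq_forward(model$layers, xt, training)
}

fcernn_output_array <- function(y, n_batch, spec) {
  B <- spec$block_side
  idx <- rep((spec$raster_nested - 1L) * n_batch, each = n_batch) +
    rep(seq_len(n_batch), times = B^3)
  arr <- y[idx, , drop = FALSE]
  dim(arr) <- c(n_batch, B, B, B, 2L)
  arr
}

# Normalized (eps, sigma) block -> nested-order target matrix (B^3 x 2).
fcernn_nested_target <- function(eps_block, sigma_block, spec) {
  cbind(as.vector(eps_block)[spec$nested_raster],
        as.vector(sigma_block)[spec$nested_raster])
}

#' @export
print.fcernn_model <- function(x, ...) {
  cat(sprintf(
    "<fcernn_model> input 2 x %d (padded to %d) -> block %d^3 x 2; %d trainable parameters\n",
    x$spec$m, x$spec$m_pad, x$spec$block_side, x$n_params
  ))
  cat("  encoder lengths:", paste(x$spec$shape_trace$encoder_len, collapse = " -> "),
      "| decoder sides:", paste(x$spec$shape_trace$decoder_side, collapse = " -> "), "\n")
  invisible(x)
}

#' Partition a cubic volume into N disjoint blocks
#'
#' `n_blocks` must be a perfect cube k^3 with k dividing each axis; the
#' blocks tile the volume exactly and are returned in deterministic
#' lexicographic order (x fastest, then y, then z).
#'
#' @param full_shape Length-3 integer vector of the volume shape.
#' @param n_blocks Number of blocks.
#' @return List of blocks, each `list(x =, y =, z =)` index ranges.
#' @export
partition_volume <- function(full_shape, n_blocks) {
  full_shape <- rep(as.integer(full_shape), length.out = 3)
  k <- round(n_blocks^(1 / 3))
  if (k^3 != n_blocks)
    abort(sprintf("n_blocks = %d is not a perfect cube", n_blocks))
  if (any(full_shape %% k != 0))
    abort(sprintf("block count %d^3 does not divide volume %s evenly",
                  k, paste(full_shape, collapse = "x")))
  b <- full_shape %/% k
  out <- list()
  for (kz in seq_len(k)) for (ky in seq_len(k)) for (kx in seq_len(k)) {
    out[[length(out) + 1]] <- list(
      x = ((kx - 1) * b[1] + 1):(kx * b[1]),
      y = ((ky - 1) * b[2] + 1):(ky * b[2]),
      z = ((kz - 1) * b[3] + 1):(kz * b[3])
    )
  }
  out
}

#' Extract one partition block from a volume
#' @param v 3-D array.
#' @param box A block from [partition_volume()].
#' @return The sub-array.
#' @export
extract_block <- function(v, box) v[box$x, box$y, box$z, drop = FALSE]

#' Assemble partition blocks back into a full volume
#' @param blocks List of sub-arrays, one per partition box.
#' @param partition The [partition_volume()] result that produced them.
#' @param full_shape Shape of the assembled volume.
#' @return The assembled 3-D array.
#' @export
assemble_blocks <- function(blocks, partition, full_shape) {
  v <- array(0, dim = rep(as.integer(full_shape), length.out = 3))
  for (i in seq_along(partition)) {
    box <- partition[[i]]
    v[box$x, box$y, box$z] <- blocks[[i]]
  }
  v
}

# ---- target/input normalization ----

#' Compute normalization statistics from the training split
#'
#' Targets are normalized per channel by min-max to \[0, 1\]; inputs are
#' standardized per feature. Statistics must come from the training split
#' only.
#'
#' @param inputs N x 2M matrix of measurement vectors.
#' @param eps_list,sigma_list Lists of training property volumes.
#' @return A `norm_stats` list.
#' @export
compute_norm_stats <- function(inputs, eps_list, sigma_list) {
  er <- range(unlist(lapply(eps_list, range)))
  sr <- range(unlist(lapply(sigma_list, range)))
  if (er[2] <= er[1] || sr[2] <= sr[1])
    abort("degenerate targets: per-channel max must exceed min")
  mu <- colMeans(inputs)
  sdv <- apply(inputs, 2, sd)
  sdv[sdv < 1e-12] <- 1
  structure(
    list(eps_min = er[1], eps_max = er[2], sigma_min = sr[1], sigma_max = sr[2],
         input_mean = mu, input_sd = sdv),
    class = "norm_stats"
  )
}

#' Normalize a property volume pair to the network's target scale
#' @param vols `list(eps=, sigma=)`.
#' @param stats A [compute_norm_stats()] object.
#' @return `list(eps=, sigma=)` on the normalized scale.
#' @export
normalize_volume <- function(vols, stats) {
  list(
    eps = (vols$eps - stats$eps_min) / (stats$eps_max - stats$eps_min),
    sigma = (vols$sigma - stats$sigma_min) / (stats$sigma_max - stats$sigma_min)
  )
}

#' Invert [normalize_volume()] and clamp to physical ranges
#' @param vols Normalized `list(eps=, sigma=)`.
#' @param stats A [compute_norm_stats()] object.
#' @param clamp Apply the physical clamp eps >= 1, sigma >= 0?
#' @return `list(eps=, sigma=)` on the physical scale.
#' @export
denormalize_volume <- function(vols, stats, clamp = FALSE) {
  eps <- vols$eps * (stats$eps_max - stats$eps_min) + stats$eps_min
  sig <- vols$sigma * (stats$sigma_max - stats$sigma_min) + stats$sigma_min
  if (clamp) {
    eps <- pmax(eps, 1)
    sig <- pmax(sig, 0)
  }
  list(eps = eps, sigma = sig)
}

normalize_inputs <- function(x, stats) {
  sweep(sweep(rbind(x), 2, stats$input_mean), 2, stats$input_sd, "/")
}

# ---- training ----

#' Train the block-partitioned reconstruction network
#'
#' Splits the samples into training and validation, computes normalization
#' statistics on the training split, partitions the output volume into
#' `n_blocks` disjoint blocks, and trains one independent sub-model per
#' block with Adam on the MSE loss between normalized predicted and true
#' property blocks. Sub-models share nothing: no information is exchanged
#' between blocks.
#'
#' @param samples List of `list(input = <2M vector>, eps = <n^3>, sigma = <n^3>)`.
#' @param n_blocks Number of output blocks (perfect cube).
#' @param epochs Training epochs.
#' @param lr Adam learning rate (initial).
#' @param lr_end Final learning rate of an exponential per-epoch decay;
#'   `NULL` keeps `lr` constant.
#' @param batch_size Minibatch size (>= 2 for batch norm).
#' @param val_frac Fraction of samples held out for validation.
#' @param seed Seed for split, initialization and batch order.
#' @param verbose Print per-epoch losses.
#' @return An `fcernn_fit` with sub-models, stats, partition and history.
#' @export
train_fcernn <- function(samples, n_blocks = 1, epochs = 30, lr = 1e-3,
                         lr_end = NULL, batch_size = 16, val_frac = 0.15,
                         seed = 1, verbose = FALSE) {
  ns <- length(samples)
  stopifnot(ns >= 2, batch_size >= 2)
  grid_n <- dim(samples[[1]]$eps)[1]
  inputs <- do.call(rbind, lapply(samples, `[[`, "input"))
  n_val <- if (val_frac <= 0) 0L else max(1L, round(val_frac * ns))
  idx_val <- if (n_val > 0) with_seed(derive_seed(seed, 1), sample(ns, n_val)) else integer(0)
  idx_tr <- setdiff(seq_len(ns), idx_val)
  stats <- compute_norm_stats(
    inputs[idx_tr, , drop = FALSE],
    lapply(samples[idx_tr], `[[`, "eps"),
    lapply(samples[idx_tr], `[[`, "sigma")
  )
  xin <- normalize_inputs(inputs, stats)
  part <- partition_volume(rep(grid_n, 3), n_blocks)
  bside <- length(part[[1]]$x)
  spec <- fcernn_spec(input_len = ncol(inputs), block_side = bside)

  # normalized targets per block in the decoder's nested cell order:
  # (S, b^3, 2), so a minibatch subset reshapes directly to the output matrix
  block_targets <- function(idx, box) {
    tgt <- array(0, dim = c(length(idx), bside^3, 2))
    for (i in seq_along(idx)) {
      nv <- normalize_volume(phantom_like_vols(samples[[idx[i]]]), stats)
      tgt[i, , ] <- fcernn_nested_target(extract_block(nv$eps, box),
                                         extract_block(nv$sigma, box), spec)
    }
    tgt
  }

  models <- vector("list", length(part))
  history <- list()
  for (bi in seq_along(part)) {
    box <- part[[bi]]
    ttr <- block_targets(idx_tr, box)
    tva <- block_targets(idx_val, box)
    model <- build_fcernn(spec, derive_seed(seed, 100 + bi))
    layers <- model$layers
    state <- adam_init(layers)
    step <- 0
    hist_b <- matrix(0, nrow = epochs, ncol = 2)
    for (ep in seq_len(epochs)) {
      lr_ep <- if (is.null(lr_end) || epochs == 1) lr
               else lr * (lr_end / lr)^((ep - 1) / (epochs - 1))
      ord <- with_seed(derive_seed(seed, 1000 * bi + ep), sample(length(idx_tr)))
      ep_loss <- 0; nb <- 0
      for (start in seq(1, length(ord), by = batch_size)) {
        b <- ord[start:min(start + batch_size - 1, length(ord))]
        if (length(b) < 2) next # batch norm needs >= 2 samples
        fw <- fcernn_forward(list(layers = layers, spec = spec),
                             xin[idx_tr[b], , drop = FALSE], training = TRUE)
        layers <- fw$layers
        tb <- ttr[b, , , drop = FALSE]
        dim(tb) <- c(length(b) * bside^3, 2L)
        ls <- mse_loss(fw$y, tb)
        if (!is.finite(ls$loss))
          abort(sprintf("NaN/Inf loss in block %d epoch %d: diverged", bi, ep))
        bw <- seq_backward(layers, fw$caches, ls$dy)
        step <- step + 1
        upd <- adam_step(layers, bw$grads, state, lr_ep, step)
        layers <- upd$layers; state <- upd$state
        ep_loss <- ep_loss + ls$loss; nb <- nb + 1
      }
      val_loss <- if (length(idx_val) > 0) {
        fv <- fcernn_forward(list(layers = layers, spec = spec),
                             xin[idx_val, , drop = FALSE], training = FALSE)
        tv <- tva
        dim(tv) <- c(length(idx_val) * bside^3, 2L)
        mean((fv$y - tv)^2)
      } else NA_real_
      hist_b[ep, ] <- c(ep_loss / max(nb, 1), val_loss)
      if (verbose)
        message(sprintf("block %d epoch %d train %.5f val %.5f",
                        bi, ep, hist_b[ep, 1], hist_b[ep, 2]))
    }
    # recalibrate BN running statistics to the exact online mean of the
    # training-set batch moments (removes eval/train drift of the momentum
    # average)
    j <- 0
    for (start in seq(1, length(idx_tr), by = batch_size)) {
      b <- idx_tr[start:min(start + batch_size - 1, length(idx_tr))]
      if (length(b) < 2) next
      j <- j + 1
      for (li in seq_along(layers))
        if (layers[[li]]$type == "bn") layers[[li]]$momentum <- 1 / j
      fw <- fcernn_forward(list(layers = layers, spec = spec),
                           xin[b, , drop = FALSE], training = TRUE)
      layers <- fw$layers
    }
    model$layers <- layers
    models[[bi]] <- model
    history[[bi]] <- tibble::tibble(
      block = bi, epoch = seq_len(epochs),
      train_mse = hist_b[, 1], val_mse = hist_b[, 2]
    )
  }
  structure(
    list(models = models, stats = stats, partition = part, spec = spec,
         grid_n = grid_n, idx_train = idx_tr, idx_val = idx_val,
         history = dplyr::bind_rows(history),
         config = list(n_blocks = n_blocks, epochs = epochs, lr = lr,
                       batch_size = batch_size, seed = seed)),
    class = "fcernn_fit"
  )
}

phantom_like_vols <- function(s) list(eps = s$eps, sigma = s$sigma)

#' Predict full property volumes from measurement vectors
#'
#' Runs every block's sub-model in evaluation mode, de-normalizes, applies
#' the physical clamp (eps >= 1, sigma >= 0) and assembles the blocks into
#' the full volume.
#'
#' @param fit An [train_fcernn()] fit.
#' @param input_vec One measurement vector (length 2M) or an N x 2M matrix.
#' @return For one vector, `list(eps=, sigma=)`; for a matrix, a list of
#'   such pairs.
#' @export
predict_volume <- function(fit, input_vec) {
  x <- rbind(input_vec)
  xn <- normalize_inputs(x, fit$stats)
  n <- fit$grid_n
  outs <- lapply(seq_len(nrow(x)), function(i) {
    list(eps = array(0, dim = rep(n, 3)), sigma = array(0, dim = rep(n, 3)))
  })
  for (bi in seq_along(fit$partition)) {
    if (is.null(fit$models[[bi]]))
      abort(sprintf("no model for block %d", bi))
    box <- fit$partition[[bi]]
    fw <- fcernn_forward(fit$models[[bi]], xn, training = FALSE)
    ya <- fcernn_output_array(fw$y, nrow(x), fit$spec)
    for (i in seq_len(nrow(x))) {
      nv <- list(eps = ya[i, , , , 1], sigma = ya[i, , , , 2])
      pv <- denormalize_volume(nv, fit$stats, clamp = TRUE)
      outs[[i]]$eps[box$x, box$y, box$z] <- pv$eps
      outs[[i]]$sigma[box$x, box$y, box$z] <- pv$sigma
    }
  }
  if (is.null(dim(input_vec)) && length(outs) == 1) outs[[1]] else outs
}

#' @export
print.fcernn_fit <- function(x, ...) {
  cat(sprintf(
    "<fcernn_fit> %d block model(s) of %d^3 voxels on a %d^3 grid; %d epochs\n",
    length(x$models), x$spec$block_side, x$grid_n, x$config$epochs
  ))
  fin <- dplyr::summarise(
    dplyr::group_by(x$history, .data$block),
    train = dplyr::last(.data$train_mse), val = dplyr::last(.data$val_mse)
  )
  cat(sprintf("  final MSE: train %.5f, val %.5f (mean over blocks)\n",
              mean(fin$train), mean(fin$val)))
  invisible(x)
}

#' @method tidy fcernn_fit
#' @export
tidy.fcernn_fit <- function(x, ...) x$history

#' @method glance fcernn_fit
#' @export
glance.fcernn_fit <- function(x, ...) {
  tibble::tibble(
    n_blocks = length(x$models),
    block_side = x$spec$block_side,
    n_params = sum(vapply(x$models, `[[`, numeric(1), "n_params")),
    epochs = x$config$epochs,
    final_train_mse = mean(tapply(x$history$train_mse, x$history$block, tail, 1)),
    final_val_mse = mean(tapply(x$history$val_mse, x$history$block, tail, 1))
  )
}

#' Plot training curves of a reconstruction-network fit
#' @param object An `fcernn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fcernn_fit
#' @export
autoplot.fcernn_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_mse", "val_mse"),
                           names_to = "split", values_to = "mse")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$mse, colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~block, labeller = ggplot2::label_both) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "MSE (normalized targets)")
}
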