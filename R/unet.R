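# 2-D U-Net image-enhancement stage.
#
# Four conv-pool stages (two 3x3 convs + ReLU, then 2x2 max pooling), a
# bottleneck conv pair, and four up-sampling stages (2x2 transposed conv,
# skip concatenation with the matching encoder feature map, two 3x3 convs +
# ReLU), closing with a 1x1 conv to the 2 output channels. Works on
# 2-channel (permittivity, conductivity) axial slices on the normalized
# target scale; an optional global input residual (default on) makes the
# freshly initialized network start near the identity, which suits an
# enhancement task.

#' Specify a U-Net architecture
#'
#' @param base_channels Channels of the first stage; doubled at each of the
#'   four encoder stages.
#' @param in_channels Input/output channels (2: permittivity, conductivity).
#' @param residual Add the input to the head output (global residual)?
#' @param use_skips Wire the encoder-to-decoder skip concatenations?
#'   Disabling them is only useful for wiring diagnostics.
#' @param head_init_scale Scale of the head initialization; small values
#'   start the network near the identity when `residual = TRUE`.
#' @return A `unet_spec` list.
#' @export
unet_spec <- function(base_channels = 32, in_channels = 2, residual = TRUE,
                      use_skips = TRUE, head_init_scale = 1e-2) {
  structure(
    list(base_channels = as.integer(base_channels),
         in_channels = as.integer(in_channels),
         channels = as.integer(base_channels * c(1, 2, 4, 8)),
         residual = residual, use_skips = use_skips,
         head_init_scale = head_init_scale, depth = 4L),
    class = "unet_spec"
  )
}

#' Build a U-Net model
#'
#' @param spec A [unet_spec()].
#' @param seed Seed for weight initialization.
#' @return A `unet_model`. Input slices must have sides divisible by 16
#'   (four pooling stages).
#' @export
build_unet <- function(spec = unet_spec(), seed = 1) {
  ch <- spec$channels
  L <- list()
  with_seed(seed, {
    cin <- spec$in_channels
    for (i in 1:4) {
      L[[paste0("enc", i, "a")]] <- mk_conv2d3(cin, ch[i])
      L[[paste0("enc", i, "b")]] <- mk_conv2d3(ch[i], ch[i])
      cin <- ch[i]
    }
    L[["bott_a"]] <- mk_conv2d3(ch[4], ch[4])
    L[["bott_b"]] <- mk_conv2d3(ch[4], ch[4])
    up_in <- ch[4]
    for (i in 4:1) {
      L[[paste0("up", i)]] <- mk_upconv2d(up_in, ch[i])
      dec_in <- if (spec$use_skips) 2L * ch[i] else ch[i]
      L[[paste0("dec", i, "a")]] <- mk_conv2d3(dec_in, ch[i])
      L[[paste0("dec", i, "b")]] <- mk_conv2d3(ch[i], ch[i])
      up_in <- ch[i]
    }
    L[["head"]] <- mk_dense_channels(ch[1], spec$in_channels,
                                     init_scale = spec$head_init_scale)
  })
  structure(
    list(layers = L, spec = spec,
         n_params = seq_param_count(unname(L))),
    class = "unet_model"
  )
}

relu_fwd <- function(x) list(y = pmax(x, 0), mask = x > 0)

# Forward pass; returns output and every cache needed for the backward pass.
unet_forward <- function(model, x) {
  L <- model$layers
  sp <- model$spec
  d <- dim(x)
  if (d[2] %% 16 != 0 || d[3] %% 16 != 0)
    abort(sprintf("slice side %dx%d not divisible by 16 (four pooling stages)", d[2], d[3]))
  cc <- list()
  h <- x
  skips <- list()
  for (i in 1:4) {
    r1 <- nn_forward(L[[paste0("enc", i, "a")]], h); m1 <- relu_fwd(r1$y)
    r2 <- nn_forward(L[[paste0("enc", i, "b")]], m1$y); m2 <- relu_fwd(r2$y)
    skips[[i]] <- m2$y
    p <- nn_forward(mk_maxpool2(), m2$y)
    cc[[paste0("enc", i)]] <- list(c1 = r1$cache, m1 = m1$mask,
                                   c2 = r2$cache, m2 = m2$mask, cp = p$cache)
    h <- p$y
  }
  rb1 <- nn_forward(L[["bott_a"]], h); mb1 <- relu_fwd(rb1$y)
  rb2 <- nn_forward(L[["bott_b"]], mb1$y); mb2 <- relu_fwd(rb2$y)
  cc[["bott"]] <- list(c1 = rb1$cache, m1 = mb1$mask, c2 = rb2$cache, m2 = mb2$mask)
  h <- mb2$y
  for (i in 4:1) {
    u <- nn_forward(L[[paste0("up", i)]], h)
    hu <- u$y
    if (sp$use_skips) {
      hcat <- abind4(skips[[i]], hu)
    } else hcat <- hu
    r1 <- nn_forward(L[[paste0("dec", i, "a")]], hcat); m1 <- relu_fwd(r1$y)
    r2 <- nn_forward(L[[paste0("dec", i, "b")]], m1$y); m2 <- relu_fwd(r2$y)
    cc[[paste0("dec", i)]] <- list(cu = u$cache, c1 = r1$cache, m1 = m1$mask,
                                   c2 = r2$cache, m2 = m2$mask,
                                   nskip = if (sp$use_skips) dim(skips[[i]])[4] else 0L)
    h <- m2$y
  }
  hd <- nn_forward(L[["head"]], h)
  cc[["head"]] <- hd$cache
  y <- hd$y
  if (sp$residual) y <- y + x
  list(y = y, caches = cc)
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

unet_backward <- function(model, caches, dy) {
  L <- model$layers
  sp <- model$spec
  g <- list()
  rh <- nn_backward(L[["head"]], caches[["head"]], dy)
  g[["head"]] <- rh$grads
  dh <- rh$dx
  dskip <- vector("list", 4)
  for (i in 1:4) { # forward walked decoder stages 4..1, so reverse is 1..4
    cci <- caches[[paste0("dec", i)]]
    d2 <- dh * cci$m2
    r2 <- nn_backward(L[[paste0("dec", i, "b")]], cci$c2, d2)
    g[[paste0("dec", i, "b")]] <- r2$grads
    d1 <- r2$dx * cci$m1
    r1 <- nn_backward(L[[paste0("dec", i, "a")]], cci$c1, d1)
    g[[paste0("dec", i, "a")]] <- r1$grads
    dcat <- r1$dx
    if (sp$use_skips) {
      ns <- cci$nskip
      dskip[[i]] <- dcat[, , , seq_len(ns), drop = FALSE]
      dup <- dcat[, , , ns + seq_len(dim(dcat)[4] - ns), drop = FALSE]
    } else dup <- dcat
    ru <- nn_backward(L[[paste0("up", i)]], cci$cu, dup)
    g[[paste0("up", i)]] <- ru$grads
    dh <- ru$dx
  }
  ccb <- caches[["bott"]]
  d2 <- dh * ccb$m2
  r2 <- nn_backward(L[["bott_b"]], ccb$c2, d2)
  g[["bott_b"]] <- r2$grads
  d1 <- r2$dx * ccb$m1
  r1 <- nn_backward(L[["bott_a"]], ccb$c1, d1)
  g[["bott_a"]] <- r1$grads
  dh <- r1$dx
  for (i in 4:1) {
    cci <- caches[[paste0("enc", i)]]
    rp <- nn_backward(mk_maxpool2(), cci$cp, dh)
    dpool <- rp$dx
    if (sp$use_skips && !is.null(dskip[[i]])) dpool <- dpool + dskip[[i]]
    d2 <- dpool * cci$m2
    r2 <- nn_backward(L[[paste0("enc", i, "b")]], cci$c2, d2)
    g[[paste0("enc", i, "b")]] <- r2$grads
    d1 <- r2$dx * cci$m1
    r1 <- nn_backward(L[[paste0("enc", i, "a")]], cci$c1, d1)
    g[[paste0("enc", i, "a")]] <- r1$grads
    dh <- r1$dx
  }
  list(grads = g, dx = dh)
}

#' Cut a 2-channel volume into ordered XY slices
#'
#' @param vol3d A 4-D array (n1, n2, nz, 2) or a `list(eps=, sigma=)` pair
#'   of 3-D arrays.
#' @return List of (n1, n2, 2) slices, indexed by z ascending;
#'   [stack_slices()] is its exact inverse.
#' @export
slice_volume <- function(vol3d) {
  v <- as_volume_array(vol3d)
  lapply(seq_len(dim(v)[3]), function(k) v[, , k, , drop = TRUE])
}

#' Stack XY slices back into a 2-channel volume
#' @param slices List of (n1, n2, 2) slices.
#' @return A 4-D array (n1, n2, nz, 2).
#' @export
stack_slices <- function(slices) {
  d <- dim(slices[[1]])
  v <- array(0, dim = c(d[1], d[2], length(slices), d[3]))
  for (k in seq_along(slices)) v[, , k, ] <- slices[[k]]
  v
}

# list(eps=, sigma=) <-> (n1, n2, nz, 2) array
as_volume_array <- function(v) {
  if (is.list(v)) {
    d <- dim(v$eps)
    out <- array(0, dim = c(d, 2))
    out[, , , 1] <- v$eps
    out[, , , 2] <- v$sigma
    out
  } else v
}

as_volume_list <- function(a) list(eps = a[, , , 1], sigma = a[, , , 2])

# Edge-replicating pad of slice batches (N, H, W, C) to a multiple of 16.
pad_slices <- function(x, multiple = 16L) {
  d <- dim(x)
  tgt <- function(n) as.integer(ceiling(n / multiple) * multiple)
  H2 <- tgt(d[2]); W2 <- tgt(d[3])
  ph <- H2 - d[2]; pw <- W2 - d[3]
  ih <- c(rep(1L, ph %/% 2), seq_len(d[2]), rep(d[2], ph - ph %/% 2))
  iw <- c(rep(1L, pw %/% 2), seq_len(d[3]), rep(d[3], pw - pw %/% 2))
  list(x = x[, ih, iw, , drop = FALSE],
       crop_h = (ph %/% 2) + seq_len(d[2]), crop_w = (pw %/% 2) + seq_len(d[3]))
}

#' Train the U-Net enhancement stage
#'
#' Trains on paired (preliminary reconstruction slice, ground-truth slice)
#' images on the normalized target scale, with Adam on the MSE loss. Pairs
#' must come from training phantoms only.
#'
#' @param x Array (S, H, W, 2) of input slices (normalized scale).
#' @param y Array (S, H, W, 2) of target slices (normalized scale).
#' @param spec A [unet_spec()].
#' @param epochs,lr,batch_size Optimization hyperparameters.
#' @param seed Seed for initialization and batch order.
#' @param verbose Print per-epoch loss.
#' @return A `unet_fit`.
#' @export
train_unet <- function(x, y, spec = unet_spec(), epochs = 3, lr = 1e-3,
                       batch_size = 8, seed = 1, verbose = FALSE) {
  stopifnot(identical(dim(x), dim(y)))
  px <- pad_slices(x)
  py <- pad_slices(y)
  model <- build_unet(spec, derive_seed(seed, 5))
  L <- model$layers
  state <- adam_init(L)
  S <- dim(x)[1]
  step <- 0
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, 50 + ep), sample(S))
    ep_loss <- 0; nb <- 0
    for (start in seq(1, S, by = batch_size)) {
      b <- ord[start:min(start + batch_size - 1, S)]
      fw <- unet_forward(list(layers = L, spec = spec),
                         px$x[b, , , , drop = FALSE])
      ls <- mse_loss(fw$y, py$x[b, , , , drop = FALSE])
      if (!is.finite(ls$loss)) abort(sprintf("NaN/Inf U-Net loss in epoch %d", ep))
      bw <- unet_backward(list(layers = L, spec = spec), fw$caches, ls$dy)
      step <- step + 1
      upd <- adam_step(L, bw$grads[names(L)], state, lr, step)
      L <- upd$layers; state <- upd$state
      ep_loss <- ep_loss + ls$loss; nb <- nb + 1
    }
    hist[ep] <- ep_loss / nb
    if (verbose) message(sprintf("unet epoch %d loss %.6f", ep, hist[ep]))
  }
  model$layers <- L
  structure(
    list(model = model, spec = spec,
         history = tibble::tibble(epoch = seq_len(epochs), train_mse = hist),
         slice_hw = dim(x)[2:3],
         config = list(epochs = epochs, lr = lr, batch_size = batch_size,
                       seed = seed)),
    class = "unet_fit"
  )
}

#' Enhance a reconstructed volume slice-by-slice
#'
#' Applies the trained U-Net to every XY slice (on the normalized scale
#' defined by `stats`), restacks, de-normalizes and clamps to physical
#' ranges (eps >= 1, sigma >= 0).
#'
#' @param fit A [train_unet()] fit.
#' @param vol `list(eps=, sigma=)` property volumes on the physical scale.
#' @param stats The [compute_norm_stats()] object of the stage-1 fit.
#' @return Enhanced `list(eps=, sigma=)` volumes.
#' @export
enhance_volume <- function(fit, vol, stats) {
  nv <- normalize_volume(vol, stats)
  d <- dim(nv$eps)
  if (!identical(as.integer(d[1:2]), as.integer(fit$slice_hw)))
    abort(sprintf("volume slices %dx%d do not match the training slice size %dx%d",
                  d[1], d[2], fit$slice_hw[1], fit$slice_hw[2]))
  va <- as_volume_array(nv)
  batch <- aperm(va, c(3, 1, 2, 4)) # slices as batch
  pb <- pad_slices(batch)
  fw <- unet_forward(fit$model, pb$x)
  out <- fw$y[, pb$crop_h, pb$crop_w, , drop = FALSE]
  out <- aperm(out, c(2, 3, 1, 4))
  denormalize_volume(as_volume_list(out), stats, clamp = TRUE)
}

#' @export
print.unet_fit <- function(x, ...) {
  cat(sprintf(
    "<unet_fit> %d-parameter U-Net on %dx%d slices; %d epochs, final MSE %.6f\n",
    x$model$n_params, x$slice_hw[1], x$slice_hw[2],
    nrow(x$history), tail(x$history$train_mse, 1)
  ))
  invisible(x)
}

#' @method tidy unet_fit
#' @export
tidy.unet_fit <- function(x, ...) x$history

#' @method glance unet_fit
#' @export
glance.unet_fit <- function(x, ...) {
  tibble::tibble(
    n_params = x$model$n_params,
    base_channels = x$spec$base_channels,
    residual = x$spec$residual,
    epochs = nrow(x$history),
    final_train_mse = tail(x$history$train_mse, 1)
  )
}
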