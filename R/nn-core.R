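# Minimal neural-network kernel: layers as plain lists with explicit
# forward/backward passes built on im2col-style gathers and BLAS matmuls.
# Tensor layout is always batch-first, channels-last:
#   1-D (N, L, C) | 2-D (N, H, W, C) | 3-D (N, A, B, C, Ch).
# All randomness in initialization is seeded by the caller via with_seed().

he_init <- function(nrow, ncol, fan_in, scale = 1) {
  matrix(rnorm(nrow * ncol, 0, scale * sqrt(2 / fan_in)), nrow, ncol)
}

mk_conv1d <- function(k, s, cin, cout) {
  list(type = "conv1d", k = k, s = s, cin = cin, cout = cout,
       W = he_init(k * cin, cout, k * cin), b = numeric(cout))
}

mk_bn <- function(c, chi = 1e-3, momentum = 0.1) {
  list(type = "bn", c = c, chi = chi, momentum = momentum,
       gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}

mk_relu <- function() list(type = "relu")

mk_reshape3d <- function(a, c) list(type = "reshape3d", a = a, c = c)

# Transposed 3-D convolution with kernel == stride: every input cell expands
# into an (sx, sy, sz) output block through a learned linear map.
mk_deconv3d <- function(s, cin, cout) {
  s <- rep(s, length.out = 3)
  list(type = "deconv3d", s = s, cin = cin, cout = cout,
       W = he_init(cin, prod(s) * cout, cin), b = numeric(cout))
}

# Per-position linear map over channels (a 1x1x...x1 convolution).
mk_dense_channels <- function(cin, cout, init_scale = 1) {
  list(type = "dense_channels", cin = cin, cout = cout,
       W = he_init(cin, cout, cin, scale = init_scale), b = numeric(cout))
}

mk_conv2d3 <- function(cin, cout) {
  list(type = "conv2d3", cin = cin, cout = cout,
       W = he_init(9 * cin, cout, 9 * cin), b = numeric(cout))
}

mk_maxpool2 <- function() list(type = "maxpool2")

mk_upconv2d <- function(cin, cout) {
  list(type = "upconv2d", cin = cin, cout = cout,
       W = he_init(cin, 4 * cout, cin), b = numeric(cout))
}

layer_param_names <- function(layer) {
  switch(layer$type,
    conv1d = , deconv3d = , deconv3dn = , dense_channels = , conv2d3 = ,
    upconv2d = c("W", "b"),
    bn = c("gamma", "beta"),
    character(0)
  )
}

nn_forward <- function(layer, x, training = TRUE) {
  switch(layer$type,
    conv1d = conv1d_fwd(layer, x),
    bn = bn_fwd(layer, x, training),
    relu = {
      mask <- x > 0
      list(y = x * mask, cache = mask, layer = layer)
    },
    reshape3d = {
      d <- dim(x)
      y <- x
      dim(y) <- c(d[1], layer$a, layer$a, layer$a, layer$c)
      list(y = y, cache = d, layer = layer)
    },
    to_matrix = to_matrix_fwd(layer, x),
    deconv3d = deconv3d_fwd(layer, x),
    deconv3dn = deconv3dn_fwd(layer, x),
    dense_channels = dense_fwd(layer, x),
    conv2d3 = conv2d3_fwd(layer, x),
    maxpool2 = maxpool2_fwd(layer, x),
    upconv2d = upconv2d_fwd(layer, x),
    abort(paste("unknown layer type", layer$type))
  )
}

nn_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv1d = conv1d_bwd(layer, cache, dy),
    bn = bn_bwd(layer, cache, dy),
    relu = list(dx = dy * cache, grads = NULL),
    reshape3d = {
      dx <- dy
      dim(dx) <- cache
      list(dx = dx, grads = NULL)
    },
    to_matrix = {
      dx <- dy
      dim(dx) <- cache
      list(dx = dx, grads = NULL)
    },
    deconv3d = deconv3d_bwd(layer, cache, dy),
    deconv3dn = deconv3dn_bwd(layer, cache, dy),
    dense_channels = dense_bwd(layer, cache, dy),
    conv2d3 = conv2d3_bwd(layer, cache, dy),
    maxpool2 = maxpool2_bwd(layer, cache, dy),
    upconv2d = upconv2d_bwd(layer, cache, dy),
    abort(paste("unknown layer type", layer$type))
  )
}

# ---- conv1d (same-style padding, arbitrary stride) ----

conv1d_geometry <- function(L, k, s) {
  Lo <- as.integer(ceiling(L / s))
  Lp <- max((Lo - 1L) * s + k, L) # k < s legitimately skips inputs
  pad_left <- (Lp - L) %/% 2L
  P <- outer(seq_len(k), (seq_len(Lo) - 1L) * s, "+") # k x Lo padded positions
  list(Lo = Lo, Lp = Lp, pad_left = pad_left, P = P)
}

conv1d_fwd <- function(layer, x) {
  d <- dim(x)
  N <- d[1]; L <- d[2]; C <- d[3]
  g <- conv1d_geometry(L, layer$k, layer$s)
  xp <- array(0, dim = c(N, g$Lp, C))
  xp[, g$pad_left + seq_len(L), ] <- x
  xg <- xp[, as.vector(g$P), , drop = FALSE]
  dim(xg) <- c(N, layer$k, g$Lo, C)
  xg <- aperm(xg, c(1, 3, 2, 4))
  dim(xg) <- c(N * g$Lo, layer$k * C)
  y <- xg %*% layer$W
  y <- sweep(y, 2, layer$b, "+")
  dim(y) <- c(N, g$Lo, layer$cout)
  list(y = y, cache = list(xg = xg, N = N, L = L, C = C, g = g),
       layer = layer)
}

conv1d_bwd <- function(layer, cache, dy) {
  g <- cache$g
  N <- cache$N; L <- cache$L; C <- cache$C
  dim(dy) <- c(N * g$Lo, layer$cout)
  dW <- crossprod(cache$xg, dy)
  db <- colSums(dy)
  dxg <- dy %*% t(layer$W)
  dim(dxg) <- c(N, g$Lo, layer$k, C)
  dxg <- aperm(dxg, c(1, 3, 2, 4)) # (N, k, Lo, C)
  dxp <- array(0, dim = c(N, g$Lp, C))
  for (t in seq_len(layer$k)) {
    pt <- g$P[t, ]
    dxp[, pt, ] <- dxp[, pt, ] + dxg[, t, , ]
  }
  dx <- dxp[, g$pad_left + seq_len(L), , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

# ---- batch norm (per channel over batch + spatial positions) ----

bn_fwd <- function(layer, x, training) {
  d <- dim(x)
  C <- d[length(d)]
  M <- prod(d[-length(d)])
  xm <- x
  dim(xm) <- c(M, C)
  if (training) {
    if (d[1] < 2)
      abort("batch normalization needs a batch of at least 2 in training mode")
    if (M < 2) abort("batch normalization needs at least 2 values per channel in training mode")
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu^2
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  invstd <- 1 / sqrt(v + layer$chi)
  a <- layer$gamma * invstd
  y <- xm * rep(a, each = M) + rep(layer$beta - mu * a, each = M)
  dim(y) <- d
  # backward recomputes what it needs from the raw input; nothing else cached
  list(y = y, cache = list(xm = xm, mu = mu, invstd = invstd, d = d,
                           training = training),
       layer = layer)
}

bn_bwd <- function(layer, cache, dy) {
  d <- cache$d
  C <- d[length(d)]
  M <- prod(d[-length(d)])
  dym <- dy
  dim(dym) <- c(M, C)
  sx <- colSums(dym * cache$xm)
  s1 <- colSums(dym)
  # dgamma = sum(dy * xhat), xhat = (x - mu) * invstd
  dgamma <- cache$invstd * (sx - cache$mu * s1)
  dbeta <- s1
  g <- layer$gamma * cache$invstd
  if (cache$training) {
    # dx = g*dy - g/M*s1 - g*invstd^2/M * sum(dy*xhat)*(x - mu), per channel
    q <- g * cache$invstd * dgamma / M
    r <- g * s1 / M - q * cache$mu
    dx <- dym * rep(g, each = M) - cache$xm * rep(q, each = M) - rep(r, each = M)
  } else {
    dx <- dym * rep(g, each = M)
  }
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# ---- transposed 3-D conv, kernel == stride ----

deconv3d_fwd <- function(layer, x) {
  d <- dim(x) # (N, A, B, C, Cin)
  s <- layer$s
  N <- d[1]
  x2 <- x
  dim(x2) <- c(prod(d[1:4]), layer$cin)
  m <- x2 %*% layer$W
  m <- sweep(m, 2, rep(layer$b, each = prod(s)), "+")
  dim(m) <- c(N, d[2], d[3], d[4], s[1], s[2], s[3], layer$cout)
  m <- aperm(m, c(1, 5, 2, 6, 3, 7, 4, 8))
  dim(m) <- c(N, s[1] * d[2], s[2] * d[3], s[3] * d[4], layer$cout)
  list(y = m, cache = list(x2 = x2, d = d), layer = layer)
}

deconv3d_bwd <- function(layer, cache, dy) {
  d <- cache$d
  s <- layer$s
  dim(dy) <- c(d[1], s[1], d[2], s[2], d[3], s[3], d[4], layer$cout)
  dy <- aperm(dy, c(1, 3, 5, 7, 2, 4, 6, 8))
  dm <- dy
  dim(dm) <- c(prod(d[1:4]), prod(s) * layer$cout)
  dW <- crossprod(cache$x2, dm)
  db_full <- colSums(dm)
  dim(db_full) <- c(prod(s), layer$cout)
  db <- colSums(db_full)
  dx <- dm %*% t(layer$W)
  dim(dx) <- d
  list(dx = dx, grads = list(W = dW, b = db))
}

# ---- per-position channel map ----

dense_fwd <- function(layer, x) {
  d <- dim(x)
  x2 <- x
  dim(x2) <- c(prod(d[-length(d)]), layer$cin)
  y <- sweep(x2 %*% layer$W, 2, layer$b, "+")
  dim(y) <- c(d[-length(d)], layer$cout)
  list(y = y, cache = list(x2 = x2, d = d), layer = layer)
}

dense_bwd <- function(layer, cache, dy) {
  d <- cache$d
  dim(dy) <- c(prod(d[-length(d)]), layer$cout)
  dW <- crossprod(cache$x2, dy)
  db <- colSums(dy)
  dx <- dy %*% t(layer$W)
  dim(dx) <- d
  list(dx = dx, grads = list(W = dW, b = db))
}

# ---- 3x3 'same' 2-D conv ----
# im2col via a cached linear-index gather: for each (N, H, W, C) geometry the
# map from (n, h, w, tap, c) to the padded-input linear index is precomputed
# once, making the gather (and the backward scatter-add) single indexed ops.

.im2col_cache <- new.env(parent = emptyenv())

conv2d3_indices <- function(N, H, W, C) {
  key <- paste(N, H, W, C, sep = "x")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  di <- rep(0:2, times = 3)
  dj <- rep(0:2, each = 3)
  n_ <- seq_len(N)
  idx <- array(0L, dim = c(N, H, W, 9L, C))
  for (o in 1:9) {
    hof <- (seq_len(H) + di[o] - 1L) # 0-based padded row index
    wof <- (seq_len(W) + dj[o] - 1L)
    base <- outer(n_, N * hof, "+")            # (N, H): n + N*hrow
    base <- outer(as.vector(base), N * Hp * wof, "+") # (N*H, W)
    idx[, , , o, 1] <- base
  }
  for (c_ in seq_len(C)[-1])
    idx[, , , , c_] <- idx[, , , , 1] + (c_ - 1L) * N * Hp * Wp
  dim(idx) <- NULL
  out <- list(idx = idx, Hp = Hp, Wp = Wp)
  .im2col_cache[[key]] <- out
  out
}

conv2d3_fwd <- function(layer, x) {
  d <- dim(x) # (N, H, W, C)
  N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  g <- conv2d3_indices(N, H, W, C)
  xp <- array(0, dim = c(N, g$Hp, g$Wp, C))
  xp[, 1 + seq_len(H), 1 + seq_len(W), ] <- x
  xg <- xp[g$idx]
  dim(xg) <- c(N * H * W, 9L * C)
  y <- xg %*% layer$W
  y <- y + rep(layer$b, each = nrow(y))
  dim(y) <- c(N, H, W, layer$cout)
  list(y = y, cache = list(xg = xg, d = d), layer = layer)
}

conv2d3_bwd <- function(layer, cache, dy) {
  d <- cache$d
  N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  g <- conv2d3_indices(N, H, W, C)
  dim(dy) <- c(N * H * W, layer$cout)
  dW <- crossprod(cache$xg, dy)
  db <- colSums(dy)
  dxg <- dy %*% t(layer$W)
  dxp <- numeric(N * g$Hp * g$Wp * C)
  nblk <- N * H * W
  dim(dxg) <- c(nblk, 9L, C)
  iv <- g$idx
  dim(iv) <- c(nblk, 9L, C)
  for (o in 1:9) { # offsets never collide within one tap
    ii <- iv[, o, ]
    dxp[ii] <- dxp[ii] + dxg[, o, ]
  }
  dim(dxp) <- c(N, g$Hp, g$Wp, C)
  dx <- dxp[, 1 + seq_len(H), 1 + seq_len(W), , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

# ---- 2x2 max pooling ----

maxpool2_fwd <- function(layer, x) {
  d <- dim(x)
  N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  H2 <- H %/% 2L; W2 <- W %/% 2L
  dim(x) <- c(N, 2, H2, 2, W2, C)
  x <- aperm(x, c(1, 3, 5, 6, 2, 4))
  dim(x) <- c(N * H2 * W2 * C, 4)
  idx <- max.col(x, ties.method = "first")
  y <- x[cbind(seq_len(nrow(x)), idx)]
  dim(y) <- c(N, H2, W2, C)
  list(y = y, cache = list(idx = idx, d = d), layer = layer)
}

maxpool2_bwd <- function(layer, cache, dy) {
  d <- cache$d
  N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  H2 <- H %/% 2L; W2 <- W %/% 2L
  dz <- matrix(0, nrow = N * H2 * W2 * C, ncol = 4)
  dz[cbind(seq_len(nrow(dz)), cache$idx)] <- as.vector(dy)
  dim(dz) <- c(N, H2, W2, C, 2, 2)
  dz <- aperm(dz, c(1, 5, 2, 6, 3, 4))
  dim(dz) <- d
  list(dx = dz, grads = NULL)
}

# ---- transposed 2-D conv, kernel == stride == 2 ----

upconv2d_fwd <- function(layer, x) {
  d <- dim(x) # (N, H, W, Cin)
  N <- d[1]
  x2 <- x
  dim(x2) <- c(prod(d[1:3]), layer$cin)
  m <- sweep(x2 %*% layer$W, 2, rep(layer$b, each = 4), "+")
  dim(m) <- c(N, d[2], d[3], 2, 2, layer$cout)
  m <- aperm(m, c(1, 4, 2, 5, 3, 6))
  dim(m) <- c(N, 2 * d[2], 2 * d[3], layer$cout)
  list(y = m, cache = list(x2 = x2, d = d), layer = layer)
}

upconv2d_bwd <- function(layer, cache, dy) {
  d <- cache$d
  dim(dy) <- c(d[1], 2, d[2], 2, d[3], layer$cout)
  dy <- aperm(dy, c(1, 3, 5, 2, 4, 6))
  dm <- dy
  dim(dm) <- c(prod(d[1:3]), 4 * layer$cout)
  dW <- crossprod(cache$x2, dm)
  dbf <- colSums(dm)
  dim(dbf) <- c(4, layer$cout)
  db <- colSums(dbf)
  dx <- dm %*% t(layer$W)
  dim(dx) <- d
  list(dx = dx, grads = list(W = dW, b = db))
}

# ---- sequential container ----

seq_forward <- function(layers, x, training = TRUE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    res <- nn_forward(layers[[i]], x, training)
    x <- res$y
    caches[[i]] <- res$cache
    layers[[i]] <- res$layer
  }
  list(y = x, caches = caches, layers = layers)
}

seq_backward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    res <- nn_backward(layers[[i]], caches[[i]], dy)
    dy <- res$dx
    grads[i] <- list(res$grads) # keep NULL slots for parameter-free layers
  }
  list(dx = dy, grads = grads)
}

seq_param_count <- function(layers) {
  sum(vapply(layers, function(l) {
    sum(vapply(layer_param_names(l), function(p) length(l[[p]]), numeric(1)))
  }, numeric(1)))
}

# ---- Adam over a flat list of layers ----

adam_init <- function(layers) {
  lapply(layers, function(l) {
    nm <- layer_param_names(l)
    st <- lapply(nm, function(p) list(m = l[[p]] * 0, v = l[[p]] * 0))
    names(st) <- nm
    st
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    nm <- layer_param_names(layers[[i]])
    for (p in nm) {
      g <- grads[[i]][[p]]
      if (is.null(g)) next
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}

mse_loss <- function(y, target) {
  d <- y - target
  list(loss = mean(d^2), dy = 2 * d / length(d))
}

# ---- matrix-form decoder layers ----
# Kernel==stride transposed convs are position-local, so the whole decoder
# can run on (batch*cells, channels) matrices: the expansion is one GEMM
# whose (cells, s^3*Cout) output reinterprets, copy-free, as
# (cells*s^3, Cout) with child cells in offset-major nested order. A fixed
# permutation (precomputed from the stride plan) maps nested order to x/y/z
# raster order once, at the output.

# (N, P, C) tensor -> (N*P, C) matrix; pure dim change.
mk_to_matrix <- function() list(type = "to_matrix")

to_matrix_fwd <- function(layer, x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  list(y = x, cache = d, layer = layer)
}

mk_deconv3dn <- function(s, cin, cout) {
  s <- rep(s, length.out = 3)
  list(type = "deconv3dn", s = s, cin = cin, cout = cout,
       W = he_init(cin, prod(s) * cout, cin), b = numeric(cout))
}

deconv3dn_fwd <- function(layer, x) {
  s3 <- prod(layer$s)
  m <- x %*% layer$W
  m <- m + rep(rep(layer$b, each = s3), each = nrow(m))
  dim(m) <- c(nrow(x) * s3, layer$cout)
  list(y = m, cache = list(x = x, nr = nrow(x)), layer = layer)
}

deconv3dn_bwd <- function(layer, cache, dy) {
  s3 <- prod(layer$s)
  dim(dy) <- c(cache$nr, s3 * layer$cout)
  dW <- crossprod(cache$x, dy)
  dbf <- colSums(dy)
  dim(dbf) <- c(s3, layer$cout)
  db <- colSums(dbf)
  dx <- dy %*% t(layer$W)
  list(dx = dx, grads = list(W = dW, b = db))
}
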