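# Low-level differentiable building blocks.
#
# All feature maps travel as (V, C) matrices (V voxels, depth-fastest raster;
# see volumes.R) so every layer reduces to BLAS GEMMs plus index plumbing.
# Each layer ships a forward returning (out, cache) and a backward mapping
# the upstream gradient to (dx, dparams); backwards are analytic and checked
# against central finite differences in the test suite.

# ---- activations -------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

silu <- function(x) x * sigmoid(x)

silu_grad <- function(x) {
  s <- sigmoid(x)
  s * (1 + x * (1 - s))
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(x) {
  m <- x - apply(x, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

# ---- dense / 1x1x1 channel map ----------------------------------------------

init_linear <- function(cin, cout, rng_sd = sqrt(2 / cin)) {
  list(W = matrix(stats::rnorm(cin * cout, sd = rng_sd), cin, cout),
       b = numeric(cout))
}

linear_fwd <- function(p, x) x %*% p$W + rep(p$b, each = nrow(x))

linear_bwd <- function(p, x, dy) {
  list(dx = dy %*% t(p$W),
       dp = list(W = crossprod(x, dy), b = colSums(dy)))
}

# ---- index caches ------------------------------------------------------------

.idx_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (is.null(.idx_cache[[key]])) .idx_cache[[key]] <- build()
  .idx_cache[[key]]
}

# ---- strided 3D convolution (im2col) ----------------------------------------
#
# dims are (H, W, D); the raster is depth-fastest, i.e. array (D, W, H).
# Weight layout: (k^3 * Cin, Cout), rows ordered kernel-offset-fastest with
# offsets rastered (d, w, h) d-fastest, then input channel.

conv3_index <- function(dims, k, stride, pad) {
  key <- paste("c3", paste(dims, collapse = "x"), k, stride, pad, sep = "_")
  cache_get(key, function() {
    H <- dims[1]; W <- dims[2]; D <- dims[3]
    Dp <- D + 2L * pad; Wp <- W + 2L * pad; Hp <- H + 2L * pad
    od <- (D + 2L * pad - k) %/% stride + 1L
    ow <- (W + 2L * pad - k) %/% stride + 1L
    oh <- (H + 2L * pad - k) %/% stride + 1L
    # coordinates of output voxels (d fastest)
    gd <- rep.int(seq_len(od), times = ow * oh)
    gw <- rep.int(rep(seq_len(ow), each = od), times = oh)
    gh <- rep(seq_len(oh), each = od * ow)
    Vout <- od * ow * oh
    idx <- matrix(0L, Vout, k^3)
    pos <- 1L
    for (kh in 0:(k - 1L)) for (kw in 0:(k - 1L)) for (kd in 0:(k - 1L)) {
      dd <- (gd - 1L) * stride + kd + 1L
      ww <- (gw - 1L) * stride + kw + 1L
      hh <- (gh - 1L) * stride + kh + 1L
      idx[, pos] <- dd + Dp * (ww - 1L) + Dp * Wp * (hh - 1L)
      pos <- pos + 1L
    }
    # mapping of the unpadded voxels into the padded raster
    ind <- seq_len(D) + pad
    inw <- seq_len(W) + pad
    inh <- seq_len(H) + pad
    inner <- as.vector(outer(outer(ind, (inw - 1L) * Dp, `+`),
                             (inh - 1L) * Dp * Wp, `+`))
    ug <- sort(unique(as.vector(idx)))
    list(idx = as.vector(idx), k3 = k^3, Vout = Vout,
         out_dims = c(oh, ow, od), Vpad = Dp * Wp * Hp,
         inner = inner, ug = ug)
  })
}

# note: conv3_index orders kernel offsets (kd fastest) to match the weight
# rows produced by init_conv3 / the analytic MAC count.

init_conv3 <- function(cin, cout, k) {
  fan_in <- k^3 * cin
  list(W = matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
                  fan_in, cout),
       b = numeric(cout))
}

conv3_fwd <- function(p, f, k, stride, pad) {
  ix <- conv3_index(f$dims, k, stride, pad)
  C <- ncol(f$x)
  xp <- matrix(0, ix$Vpad, C)
  xp[ix$inner, ] <- f$x
  xc <- xp[ix$idx, , drop = FALSE]
  dim(xc) <- c(ix$Vout, ix$k3 * C)
  y <- xc %*% p$W + rep(p$b, each = ix$Vout)
  list(out = feat(y, ix$out_dims), cache = list(xc = xc, ix = ix, C = C))
}

conv3_bwd <- function(p, cache, dy) {
  ix <- cache$ix
  dW <- crossprod(cache$xc, dy)
  db <- colSums(dy)
  dxc <- dy %*% t(p$W)
  dim(dxc) <- c(ix$Vout * ix$k3, cache$C)
  acc <- rowsum(dxc, group = ix$idx, reorder = TRUE)
  dxp <- matrix(0, ix$Vpad, cache$C)
  dxp[ix$ug, ] <- acc
  list(dx = dxp[ix$inner, , drop = FALSE], dp = list(W = dW, b = db))
}

# ---- transposed convolution, kernel 2 stride 2 -------------------------------
#
# Weight layout (Cin, 8 * Cout), columns offset-fastest (offsets rastered
# d, w, h) then output channel. Every output voxel receives exactly one
# (input voxel, offset) contribution, so the layer is a GEMM + permutation.

tconv2_index <- function(dims) {
  key <- paste("t2", paste(dims, collapse = "x"), sep = "_")
  cache_get(key, function() {
    H <- dims[1]; W <- dims[2]; D <- dims[3]
    Vin <- H * W * D
    gd <- rep.int(seq_len(D), times = W * H)
    gw <- rep.int(rep(seq_len(W), each = D), times = H)
    gh <- rep(seq_len(H), each = D * W)
    D2 <- 2L * D; W2 <- 2L * W
    rows <- integer(8L * Vin)   # for output voxel u: source row in (Vin, 8) raster
    u_of_row <- integer(8L * Vin)
    r <- 1L
    for (oh in 0:1) for (ow in 0:1) for (od in 0:1) {
      o <- od + 2L * ow + 4L * oh          # offset id, d fastest
      u <- (2L * (gd - 1L) + od + 1L) +
        D2 * (2L * (gw - 1L) + ow) +
        D2 * W2 * (2L * (gh - 1L) + oh)
      u_of_row[seq_len(Vin) + o * Vin] <- u
      r <- r + 1L
    }
    rows[u_of_row] <- seq_len(8L * Vin)
    list(rows = rows, u_of_row = u_of_row, Vin = Vin,
         out_dims = c(2L * H, 2L * W, 2L * D))
  })
}

init_tconv2 <- function(cin, cout) {
  list(W = matrix(stats::rnorm(cin * 8L * cout, sd = sqrt(2 / cin)),
                  cin, 8L * cout),
       b = numeric(cout))
}

tconv2_fwd <- function(p, f) {
  ix <- tconv2_index(f$dims)
  cout <- length(p$b)
  y8 <- f$x %*% p$W                       # (Vin, 8*Cout), offset fastest
  dim(y8) <- c(ix$Vin * 8L, cout)
  y <- y8[ix$rows, , drop = FALSE] + rep(p$b, each = 8L * ix$Vin)
  list(out = feat(y, ix$out_dims), cache = list(ix = ix, x = f$x, cout = cout))
}

tconv2_bwd <- function(p, cache, dy) {
  ix <- cache$ix
  db <- colSums(dy)
  dy8 <- dy[ix$u_of_row, , drop = FALSE]
  dim(dy8) <- c(ix$Vin, 8L * cache$cout)
  list(dx = dy8 %*% t(p$W),
       dp = list(W = crossprod(cache$x, dy8), b = db))
}

# ---- trilinear interpolation (no parameters) ---------------------------------

interp1_matrix <- function(n_in, n_out) {
  key <- paste("i1", n_in, n_out, sep = "_")
  cache_get(key, function() {
    r <- n_out / n_in
    src <- (seq_len(n_out) - 0.5) / r + 0.5
    i0 <- pmin(pmax(floor(src), 1L), n_in)
    i1 <- pmin(i0 + 1L, n_in)
    w1 <- pmin(pmax(src - i0, 0), 1)
    A <- matrix(0, n_out, n_in)
    A[cbind(seq_len(n_out), i0)] <- A[cbind(seq_len(n_out), i0)] + (1 - w1)
    A[cbind(seq_len(n_out), i1)] <- A[cbind(seq_len(n_out), i1)] + w1
    A
  })
}

# apply a 1D matrix along one axis of the (D, W, H, C)-shaped feature
.apply_axis <- function(x, dims, C, axis, A) {
  H <- dims[1]; W <- dims[2]; D <- dims[3]
  a <- x
  dim(a) <- c(D, W, H, C)
  if (axis == 3L) {                        # depth, first array dim
    m <- matrix(a, nrow = D)
    out <- A %*% m
    dim(out) <- c(nrow(A), W, H, C)
  } else if (axis == 2L) {                 # width
    a <- aperm(a, c(2L, 1L, 3L, 4L))
    m <- matrix(a, nrow = W)
    out <- A %*% m
    dim(out) <- c(nrow(A), D, H, C)
    out <- aperm(out, c(2L, 1L, 3L, 4L))
  } else {                                 # height
    a <- aperm(a, c(3L, 1L, 2L, 4L))
    m <- matrix(a, nrow = H)
    out <- A %*% m
    dim(out) <- c(nrow(A), D, W, C)
    out <- aperm(out, c(2L, 3L, 1L, 4L))
  }
  d <- dim(out)
  dim(out) <- c(d[1] * d[2] * d[3], C)
  list(x = out, dims = {nd <- dims; nd[axis] <- nrow(A); nd})
}

trilinear_resize <- function(f, out_dims) {
  C <- ncol(f$x)
  cur <- list(x = f$x, dims = f$dims)
  for (axis in c(3L, 2L, 1L)) {
    if (cur$dims[axis] != out_dims[axis]) {
      A <- interp1_matrix(cur$dims[axis], out_dims[axis])
      cur <- .apply_axis(cur$x, cur$dims, C, axis, A)
    }
  }
  feat(cur$x, out_dims)
}

# adjoint (exact transpose) of trilinear_resize, for backprop
trilinear_resize_bwd <- function(dy_feat, in_dims) {
  C <- ncol(dy_feat$x)
  cur <- list(x = dy_feat$x, dims = dy_feat$dims)
  for (axis in c(1L, 2L, 3L)) {
    if (cur$dims[axis] != in_dims[axis]) {
      A <- t(interp1_matrix(in_dims[axis], cur$dims[axis]))
      cur <- .apply_axis(cur$x, cur$dims, C, axis, A)
    }
  }
  feat(cur$x, in_dims)
}

# ---- layer normalization over channels ---------------------------------------

init_layernorm <- function(C) list(g = rep(1, C), b = numeric(C))

layernorm_fwd <- function(p, x, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  y <- xhat * rep(p$g, each = nrow(x)) + rep(p$b, each = nrow(x))
  list(out = y, cache = list(xhat = xhat, inv = inv))
}

layernorm_bwd <- function(p, cache, dy) {
  V <- nrow(dy)
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  dxh <- dy * rep(p$g, each = V)
  m1 <- rowMeans(dxh)
  m2 <- rowMeans(dxh * cache$xhat)
  dx <- (dxh - m1 - cache$xhat * m2) * cache$inv
  list(dx = dx, dp = list(g = dg, b = db))
}

# ---- parameter-tree utilities ------------------------------------------------

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(t) tree_map(f, t)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_size <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, tree_size, numeric(1))) else length(tree)
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_scale <- function(tree, s) tree_map(function(x) x * s, tree)

# maximum absolute leaf value, for divergence / dead-gradient checks
tree_max_abs <- function(tree) {
  if (is.list(tree)) {
    if (!length(tree)) return(0)
    max(vapply(tree, tree_max_abs, numeric(1)))
  } else if (length(tree)) max(abs(tree)) else 0
}

# ---- AdamW -------------------------------------------------------------------

adamw_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adamw_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 0.01) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  params <- tree_map(function(p) p * (1 - lr * weight_decay), params)
  list(params = params, state = state)
}

# cosine annealing with warm restarts: lr resets to `lr_init` at the start of
# every cycle and decays to `lr_min` by cosine within the cycle
cosine_warm_restart_lr <- function(epoch, lr_init, lr_min, cycle) {
  pos <- (epoch %% cycle) / cycle
  lr_min + 0.5 * (lr_init - lr_min) * (1 + cos(pi * pos))
}
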