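# Iterative axial factorized attention.
#
# 3D self-attention is factorized into per-axis multi-head attention: for one
# axis the other two axes are folded into the batch, so each attention
# operates on sequences of length H, W or D instead of N = H*W*D. One
# iteration sweeps the three axes sequentially (default) or sums their
# outputs (config switch), each pass entering through a SiLU-gated residual.

#' Token sequence with retained 3D geometry
#'
#' @param data numeric array `(B, N, C)` with `N = prod(dims)`.
#' @param dims integer triple (H, W, D). The token raster is depth-fastest
#'   (H outer, then W, then D).
#' @return object of class `token_sequence`.
#' @export
token_sequence <- function(data, dims) {
  stopifnot(length(dim(data)) == 3L, dim(data)[2] == prod(dims))
  structure(list(data = data, dims = as.integer(dims)), class = "token_sequence")
}

#' Convert a multichannel volume to its token sequence
#' @param volume a [multichannel_volume()].
#' @return a [token_sequence()] with `B = 1`.
#' @export
as_token_sequence <- function(volume) {
  f <- vol_to_feat(volume$data)
  d <- dim(f$x)
  token_sequence(array(f$x, c(1L, d[1], d[2])), f$dims)
}

# ---- folding -----------------------------------------------------------------

# internal: (V, C) matrix -> (B_fold, L, C) array for one axis
fold_mat <- function(x, dims, axis) {
  H <- dims[1]; W <- dims[2]; D <- dims[3]; C <- ncol(x)
  a <- x
  if (axis == "H") {
    dim(a) <- c(D * W, H, C)
    a
  } else if (axis == "W") {
    dim(a) <- c(D, W, H, C)
    a <- aperm(a, c(1L, 3L, 2L, 4L))
    dim(a) <- c(D * H, W, C)
    a
  } else if (axis == "D") {
    dim(a) <- c(D, W * H, C)
    a <- aperm(a, c(2L, 1L, 3L))
    a
  } else if (axis == "N") {
    dim(a) <- c(1L, H * W * D, C)
    a
  } else stop("unknown axis '", axis, "'")
}

unfold_mat <- function(a, dims, axis) {
  H <- dims[1]; W <- dims[2]; D <- dims[3]
  C <- dim(a)[3]
  if (axis == "H" || axis == "N") {
    dim(a) <- c(H * W * D, C)
    a
  } else if (axis == "W") {
    dim(a) <- c(D, H, W, C)
    a <- aperm(a, c(1L, 3L, 2L, 4L))
    dim(a) <- c(H * W * D, C)
    a
  } else {
    a <- aperm(a, c(2L, 1L, 3L))
    dim(a) <- c(H * W * D, C)
    a
  }
}

#' Fold a token sequence along one spatial axis
#'
#' Rearranges `(B, N, C)` tokens into an axis-major batch
#' `(B * N/L, L, C)` where `L` is the length of the chosen axis; the other
#' two axes join the batch dimension. The rearrangement is invertible by
#' [unfold_axis()].
#'
#' @param tokens a [token_sequence()].
#' @param axis one of `"H"`, `"W"`, `"D"`.
#' @return numeric array `(B * N/L, L, C)`.
#' @export
fold_axis <- function(tokens, axis) {
  d <- dim(tokens$data)
  B <- d[1]; C <- d[3]
  L <- switch(axis, H = tokens$dims[1], W = tokens$dims[2], D = tokens$dims[3],
              stop("axis must be H, W or D"))
  nb <- d[2] %/% L
  out <- array(0, c(B * nb, L, C))
  for (b in seq_len(B)) {
    fb <- fold_mat(matrix(tokens$data[b, , ], d[2], C), tokens$dims, axis)
    out[seq_len(nb) + (b - 1L) * nb, , ] <- fb
  }
  out
}

#' @rdname fold_axis
#' @param axis_batch array produced by [fold_axis()].
#' @param dims original (H, W, D).
#' @param B original batch size.
#' @export
unfold_axis <- function(axis_batch, dims, axis, B = 1L) {
  d <- dim(axis_batch)
  nb <- d[1] %/% B
  N <- prod(dims); C <- d[3]
  out <- array(0, c(B, N, C))
  for (b in seq_len(B)) {
    m <- unfold_mat(axis_batch[seq_len(nb) + (b - 1L) * nb, , , drop = FALSE],
                    dims, axis)
    out[b, , ] <- m
  }
  token_sequence(out, dims)
}

# ---- multi-head attention on a folded batch ---------------------------------

# The output projection starts at zero so every attention enters its
# residual as the identity; this conditions early optimization without
# changing the parameter count.
init_attn <- function(C) {
  list(Wq = init_linear(C, C, sd_of(C)), Wk = init_linear(C, C, sd_of(C)),
       Wv = init_linear(C, C, sd_of(C)),
       Wo = list(W = matrix(0, C, C), b = numeric(C)))
}

sd_of <- function(C) sqrt(1 / C)

#' Multi-head scaled dot-product attention along a folded axis
#'
#' Standard attention `softmax(Q K' / sqrt(c)) V` applied independently to
#' every sequence of an axis-major batch, with `c = C / num_heads`.
#'
#' @param axis_batch numeric array `(B, L, C)`.
#' @param params list with `Wq`, `Wk`, `Wv`, `Wo` (each `$W` a CxC matrix and
#'   `$b` a length-C bias) as produced by the model builder.
#' @param num_heads head count; must divide C.
#' @return array `(B, L, C)`.
#' @export
axial_mhsa <- function(axis_batch, params, num_heads = 1L) {
  axial_mhsa_fwd(axis_batch, params, num_heads, need_grad = FALSE)$out
}

axial_mhsa_fwd <- function(z, p, heads, need_grad = TRUE) {
  d <- dim(z)
  B <- d[1]; L <- d[2]; C <- d[3]
  if (C %% heads != 0L) stop("channel count ", C, " not divisible by num_heads ", heads)
  ch <- C %/% heads
  scl <- 1 / sqrt(ch)
  xm <- z; dim(xm) <- c(B * L, C)
  Q <- linear_fwd(p$Wq, xm); K <- linear_fwd(p$Wk, xm); V <- linear_fwd(p$Wv, xm)
  O <- matrix(0, B * L, C)
  Acache <- if (need_grad) array(0, c(L, L, B * heads)) else NULL
  for (b in seq_len(B)) {
    rows <- seq.int(b, by = B, length.out = L)     # tokens of sequence b
    for (h in seq_len(heads)) {
      cols <- seq.int((h - 1L) * ch + 1L, h * ch)
      Qb <- Q[rows, cols, drop = FALSE]
      Kb <- K[rows, cols, drop = FALSE]
      S <- tcrossprod(Qb, Kb) * scl
      S <- S - apply(S, 1L, max)
      A <- exp(S); A <- A / rowSums(A)
      O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      if (need_grad) Acache[, , (b - 1L) * heads + h] <- A
    }
  }
  y <- linear_fwd(p$Wo, O)
  dim(y) <- c(B, L, C)
  list(out = y,
       cache = if (need_grad) list(xm = xm, Q = Q, K = K, V = V, O = O,
                                   A = Acache, B = B, L = L, C = C,
                                   heads = heads, ch = ch, scl = scl))
}

axial_mhsa_bwd <- function(p, cache, dy) {
  B <- cache$B; L <- cache$L; C <- cache$C
  heads <- cache$heads; ch <- cache$ch; scl <- cache$scl
  dim(dy) <- c(B * L, C)
  bo <- linear_bwd(p$Wo, cache$O, dy)
  dO <- bo$dx
  dQ <- matrix(0, B * L, C); dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    rows <- seq.int(b, by = B, length.out = L)
    for (h in seq_len(heads)) {
      cols <- seq.int((h - 1L) * ch + 1L, h * ch)
      A <- cache$A[, , (b - 1L) * heads + h]
      dOb <- dO[rows, cols, drop = FALSE]
      Vb <- cache$V[rows, cols, drop = FALSE]
      dV[rows, cols] <- crossprod(A, dOb)
      dA <- tcrossprod(dOb, Vb)
      dS <- A * (dA - rowSums(dA * A))
      dQ[rows, cols] <- (dS %*% cache$K[rows, cols, drop = FALSE]) * scl
      dK[rows, cols] <- (crossprod(dS, cache$Q[rows, cols, drop = FALSE])) * scl
    }
  }
  bq <- linear_bwd(p$Wq, cache$xm, dQ)
  bk <- linear_bwd(p$Wk, cache$xm, dK)
  bv <- linear_bwd(p$Wv, cache$xm, dV)
  dx <- bq$dx + bk$dx + bv$dx
  dim(dx) <- c(B, L, C)
  list(dx = dx, dp = list(Wq = bq$dp, Wk = bk$dp, Wv = bv$dp, Wo = bo$dp))
}

# ---- iterative axial factorized attention ------------------------------------

# internal forward on a (V, C) matrix. p$axes is a named list of per-axis
# attention parameter sets; axes processed in list order.
iaf_fwd <- function(x, dims, p, heads, mode = "sequential", t_iter = 1L,
                    need_grad = TRUE) {
  axes <- names(p$axes)
  caches <- vector("list", t_iter)
  z <- x
  for (it in seq_len(t_iter)) {
    if (mode == "sequential") {
      axc <- vector("list", length(axes)); names(axc) <- axes
      for (ax in axes) {
        zf <- fold_mat(z, dims, ax)
        at <- axial_mhsa_fwd(zf, p$axes[[ax]], heads, need_grad)
        am <- unfold_mat(at$out, dims, ax)
        z <- z + silu(am)
        axc[[ax]] <- list(att = at$cache, pre = if (need_grad) am)
      }
      caches[[it]] <- axc
    } else if (mode == "summed") {
      axc <- vector("list", length(axes)); names(axc) <- axes
      s <- 0
      for (ax in axes) {
        zf <- fold_mat(z, dims, ax)
        at <- axial_mhsa_fwd(zf, p$axes[[ax]], heads, need_grad)
        s <- s + unfold_mat(at$out, dims, ax)
        axc[[ax]] <- list(att = at$cache)
      }
      z <- z + silu(s)
      caches[[it]] <- c(axc, list(.sum = if (need_grad) s))
    } else stop("unknown aggregation mode '", mode, "'")
  }
  list(out = z, cache = if (need_grad) list(iters = caches, dims = dims,
                                            mode = mode, heads = heads))
}

iaf_bwd <- function(p, cache, dz) {
  axes <- names(p$axes)
  dims <- cache$dims
  dp <- tree_zeros_like(p)
  for (it in rev(seq_along(cache$iters))) {
    axc <- cache$iters[[it]]
    if (cache$mode == "sequential") {
      for (ax in rev(axes)) {
        pre <- axc[[ax]]$pre
        dpre <- dz * silu_grad(pre)
        dfold <- fold_mat(dpre, dims, ax)
        bb <- axial_mhsa_bwd(p$axes[[ax]], axc[[ax]]$att, dfold)
        dz <- dz + unfold_mat(bb$dx, dims, ax)
        dp$axes[[ax]] <- tree_add(dp$axes[[ax]], bb$dp)
      }
    } else {
      ds <- dz * silu_grad(axc$.sum)
      for (ax in axes) {
        dfold <- fold_mat(ds, dims, ax)
        bb <- axial_mhsa_bwd(p$axes[[ax]], axc[[ax]]$att, dfold)
        dz <- dz + unfold_mat(bb$dx, dims, ax)
        dp$axes[[ax]] <- tree_add(dp$axes[[ax]], bb$dp)
      }
    }
  }
  list(dx = dz, dp = dp)
}

#' Iterative axial factorized attention over a token sequence
#'
#' One iteration attends along each spatial axis with its own Q/K/V/output
#' projections. In `"sequential"` mode (default) the residual state is
#' updated after every axis — `Z <- Z + silu(Attn_axis(Z))` — so later axes
#' see the refined state; in `"summed"` mode the three axial outputs are
#' computed from the same state and enter one shared SiLU-gated residual.
#'
#' @param tokens a [token_sequence()] (B = 1).
#' @param params per-axis attention parameters (`$axes$H/W/D`).
#' @param num_heads heads per axis.
#' @param mode `"sequential"` or `"summed"`.
#' @param iterations number of sweeps `t >= 1`.
#' @return a [token_sequence()] of identical shape.
#' @export
iaf_attention <- function(tokens, params, num_heads = 1L,
                          mode = "sequential", iterations = 1L) {
  d <- dim(tokens$data)
  stopifnot(d[1] == 1L)
  x <- matrix(tokens$data[1, , ], d[2], d[3])
  r <- iaf_fwd(x, tokens$dims, params, num_heads, mode, iterations,
               need_grad = FALSE)
  token_sequence(array(r$out, c(1L, d[2], d[3])), tokens$dims)
}

# ---- IAFT block --------------------------------------------------------------

init_iaft_block <- function(C, mlp_ratio) {
  hid <- as.integer(round(mlp_ratio * C))
  list(ln1 = init_layernorm(C),
       attn = list(axes = list(H = init_attn(C), W = init_attn(C),
                               D = init_attn(C))),
       ln2 = init_layernorm(C),
       mlp = list(W1 = init_linear(C, hid),
                  W2 = list(W = matrix(0, hid, C), b = numeric(C))))
}

iaft_block_fwd <- function(p, x, dims, heads, mode = "sequential",
                           t_iter = 1L, need_grad = TRUE) {
  n1 <- layernorm_fwd(p$ln1, x)
  ia <- iaf_fwd(n1$out, dims, p$attn, heads, mode, t_iter, need_grad)
  # iaf_fwd returns the residual-updated state; the block residual adds only
  # the accumulated attention increments, so zero branches give the identity
  x1 <- x + (ia$out - n1$out)
  n2 <- layernorm_fwd(p$ln2, x1)
  h <- linear_fwd(p$mlp$W1, n2$out)
  hs <- silu(h)
  m <- linear_fwd(p$mlp$W2, hs)
  out <- x1 + m
  list(out = out,
       cache = if (need_grad) list(n1 = n1$cache, ia = ia$cache, x = x,
                                   n1out = n1$out, x1 = x1, n2 = n2$cache,
                                   n2out = n2$out, h = h, hs = hs))
}

iaft_block_bwd <- function(p, cache, dy) {
  b2 <- linear_bwd(p$mlp$W2, cache$hs, dy)
  dh <- b2$dx * silu_grad(cache$h)
  b1 <- linear_bwd(p$mlp$W1, cache$n2out, dh)
  ln2b <- layernorm_bwd(p$ln2, cache$n2, b1$dx)
  dx1 <- dy + ln2b$dx
  iab <- iaf_bwd(p$attn, cache$ia, dx1)
  ln1b <- layernorm_bwd(p$ln1, cache$n1, iab$dx - dx1)
  dx <- dx1 + ln1b$dx
  list(dx = dx,
       dp = list(ln1 = ln1b$dp, attn = iab$dp, ln2 = ln2b$dp,
                 mlp = list(W1 = b1$dp, W2 = b2$dp)))
}

#' Transformer block with iterative axial attention
#'
#' Pre-norm residual block: `Z' = Z + IAF(norm(Z))`,
#' `Z'' = Z' + MLP(norm(Z'))` with a SiLU MLP of expansion ratio rho.
#'
#' @inheritParams iaf_attention
#' @param params block parameters as initialized by the model builder.
#' @export
iaft_block <- function(tokens, params, num_heads = 1L,
                       mode = "sequential", iterations = 1L) {
  d <- dim(tokens$data)
  stopifnot(d[1] == 1L)
  x <- matrix(tokens$data[1, , ], d[2], d[3])
  r <- iaft_block_fwd(params, x, tokens$dims, num_heads, mode, iterations,
                      need_grad = FALSE)
  token_sequence(array(r$out, c(1L, d[2], d[3])), tokens$dims)
}

# ---- dense O(N^2) oracle -----------------------------------------------------

#' Dense full self-attention baseline
#'
#' Multi-head attention over all `N = H*W*D` tokens at once — the quadratic
#' baseline that axial factorization replaces. Guarded to small `N`; used for
#' equivalence checks against the axial path on degenerate grids.
#'
#' @inheritParams iaf_attention
#' @param max_tokens guard on `N` (dense scores are `N x N`).
#' @export
full_mhsa_oracle <- function(tokens, params, num_heads = 1L,
                             max_tokens = 4096L) {
  d <- dim(tokens$data)
  N <- d[2]; C <- d[3]
  if (N > max_tokens) stop("N = ", N, " exceeds the dense-attention guard")
  ch <- C %/% num_heads
  out <- array(0, d)
  for (b in seq_len(d[1])) {
    xm <- matrix(tokens$data[b, , ], N, C)
    Q <- linear_fwd(params$Wq, xm); K <- linear_fwd(params$Wk, xm)
    V <- linear_fwd(params$Wv, xm)
    O <- matrix(0, N, C)
    for (h in seq_len(num_heads)) {
      cols <- seq.int((h - 1L) * ch + 1L, h * ch)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(ch)
      A <- softmax_rows(S)
      O[, cols] <- A %*% V[, cols, drop = FALSE]
    }
    out[b, , ] <- linear_fwd(params$Wo, O)
  }
  token_sequence(out, tokens$dims)
}

# ---- MAC accounting ----------------------------------------------------------

#' Multiply-accumulate count of one attention pass
#'
#' Closed-form MAC counts for the score (`Q K'`) and value (`A V`) products,
#' with the Q/K/V/output projections reported separately. For a cube of side
#' `S` the axial score/value term scales as `N^{4/3}` (`6 S^4 C`) versus
#' `N^2` (`2 S^6 C`) for full attention.
#'
#' @param dims integer triple (H, W, D).
#' @param C channel width.
#' @param num_heads head count (does not change the totals).
#' @param mode `"axial"` or `"full"`.
#' @return list with `score_value`, `projections`, and `total`.
#' @export
attention_mac_count <- function(dims, C, num_heads = 1L, mode = c("axial", "full")) {
  mode <- match.arg(mode)
  N <- prod(dims)
  if (mode == "axial") {
    # axes of length 1 need no attention pass (softmax over a singleton is
    # the identity), so they contribute neither products nor projections
    active <- dims[dims > 1L]
    sv <- 2 * N * C * sum(active)
    proj <- length(active) * 4 * N * C^2
  } else {
    sv <- 2 * N^2 * C
    proj <- 4 * N * C^2
  }
  list(score_value = sv, projections = proj, total = sv + proj)
}
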