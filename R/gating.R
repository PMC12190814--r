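# Adaptive recalibration of wavelet sub-bands.
#
# After the fixed Haar decomposition, a squeeze-excitation-style gate rates
# each of the 8C sub-band channels: global average pooling, a two-layer MLP,
# and a sigmoid producing per-channel weights in (0, 1) that multiply the
# stack elementwise. Task-relevant frequency bands are amplified, redundant
# ones suppressed, and the gate is the only learnable part of the wavelet
# front end besides the 1x1x1 projection into the stage-1 width.

#' Initialize sub-band gate parameters
#'
#' @param channels number of sub-band channels (8C).
#' @param hidden hidden width of the gating MLP.
#' @param seed optional RNG seed for reproducible initialization.
#' @return a `gate_params` list with linear layers `W1` (channels -> hidden)
#'   and `W2` (hidden -> channels).
#' @export
init_gate_params <- function(channels, hidden, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(list(W1 = init_linear(channels, hidden),
                 W2 = init_linear(hidden, channels),
                 channels = channels, hidden = hidden),
            class = "gate_params")
}

#' Sub-band gate weights
#'
#' `w = sigmoid(W2 . ReLU(W1 . GAP(X_sub)))` where GAP is the spatial mean
#' of each channel. Every weight lies strictly in (0, 1).
#'
#' @param subbands a `subband_stack` from [dwt3()].
#' @param params a `gate_params` object.
#' @return numeric vector of length 8C.
#' @export
gate_weights <- function(subbands, params) {
  g <- apply(subbands$data, 1L, mean)
  gate_weights_core(matrix(g, 1L), params)[1L, ]
}

# core on a (1, channels) row; shared with the network forward
gate_weights_core <- function(g, params) {
  h <- relu(linear_fwd(params$W1, g))
  sigmoid(linear_fwd(params$W2, h))
}

#' Recalibrate a sub-band stack
#'
#' Scales channel `i` of the stack by `w[i]` everywhere (Hadamard product
#' with a per-channel weight).
#'
#' @param subbands a `subband_stack`.
#' @param w numeric weight vector, one entry per channel.
#' @return a `subband_stack` with scaled data.
#' @export
recalibrate <- function(subbands, w) {
  if (length(w) != dim(subbands$data)[1])
    stop("weight length ", length(w), " does not match channel count ",
         dim(subbands$data)[1])
  out <- subbands
  out$data <- subbands$data * as.vector(w)   # channel is the fastest dim
  out
}

#' Wavelet front-end forward pass (AWD-FD)
#'
#' Composition `dwt3 -> gate_weights -> recalibrate -> 1x1x1 projection`:
#' the volume is decomposed into its 8C Haar sub-bands (halving each spatial
#' dimension), the sub-band channels are sigmoid-gated, and a learnable
#' channel map projects into the stage-1 width.
#'
#' @param volume a [multichannel_volume()] with even spatial dims.
#' @param gate a `gate_params` object for 8C channels.
#' @param projection a linear layer list (`$W` of shape 8C x c1, `$b`
#'   length c1), e.g. from the model builder.
#' @return a [multichannel_volume()] with c1 channels at half resolution.
#' @export
awdfd_forward <- function(volume, gate, projection) {
  s <- dwt3(volume)
  w <- gate_weights(s, gate)
  r <- recalibrate(s, w)
  f <- vol_to_feat(r$data)
  y <- linear_fwd(projection, f$x)
  multichannel_volume(feat_to_vol(feat(y, f$dims)), spacing = volume$spacing)
}

# ---- internal differentiable stem used by the network ------------------------

awdfd_stem_fwd <- function(p, f, need_grad = TRUE) {
  a <- f$x
  dim(a) <- c(f$dims[3], f$dims[2], f$dims[1], ncol(f$x))   # (D, W, H, C)
  s <- dwt3_core(a)
  half <- dim(s)[1:3]
  sx <- s
  dim(sx) <- c(prod(half), dim(s)[4])        # (V/8, 8C)
  V <- nrow(sx)
  g <- matrix(colMeans(sx), 1L)
  h_pre <- linear_fwd(p$gate$W1, g)
  h <- relu(h_pre)
  w_pre <- linear_fwd(p$gate$W2, h)
  w <- sigmoid(w_pre)
  rx <- sx * rep(w, each = V)
  y <- linear_fwd(p$proj, rx)
  out_dims <- c(f$dims[1] %/% 2L, f$dims[2] %/% 2L, f$dims[3] %/% 2L)
  list(out = feat(y, out_dims),
       cache = if (need_grad) list(sx = sx, g = g, h_pre = h_pre, h = h,
                                   w = w, rx = rx, V = V, in_dims = f$dims))
}

awdfd_stem_bwd <- function(p, cache, dy) {
  V <- cache$V
  bp <- linear_bwd(p$proj, cache$rx, dy)
  drx <- bp$dx
  dsx_direct <- drx * rep(cache$w, each = V)
  dw <- colSums(drx * cache$sx)
  dwpre <- dw * cache$w * (1 - cache$w)
  b2 <- linear_bwd(p$gate$W2, cache$h, matrix(dwpre, 1L))
  dh <- b2$dx * (cache$h_pre > 0)
  b1 <- linear_bwd(p$gate$W1, cache$g, dh)
  dg <- b1$dx
  dsx <- dsx_direct + rep(dg, each = V) / V
  # adjoint of the orthonormal analysis transform is the synthesis transform
  half_dims <- c(cache$in_dims[3] %/% 2L, cache$in_dims[2] %/% 2L,
                 cache$in_dims[1] %/% 2L)
  ds <- dsx
  dim(ds) <- c(half_dims, ncol(dsx))
  da <- idwt3_core(ds)
  dim(da) <- c(prod(cache$in_dims), dim(da)[4])
  list(dx = da,
       dp = list(gate = list(W1 = b1$dp, W2 = b2$dp), proj = bp$dp))
}
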