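# Model assembly: four-stage encoder (wavelet stem + strided-conv
# downsampling, axial-attention blocks throughout), multi-scale fusion
# decoder, ablation variants, and exact analytic parameter / MAC budgets.

#' Model configuration
#'
#' All architectural degrees of freedom of the segmentation network. The
#' shipped reference configuration (see [wiaf_reference_config()]) freezes
#' these so that the analytic parameter and multiply-accumulate budgets are
#' reproducible to the digit.
#'
#' @param in_channels input modalities (4 for T1/T1ce/T2/FLAIR).
#' @param num_classes output classes (background + 3 tumor labels).
#' @param stage_channels widths c1..c4 of the four encoder stages
#'   (nondecreasing, each divisible by its head count).
#' @param blocks_per_stage attention blocks per stage.
#' @param num_heads heads per stage.
#' @param mlp_ratio expansion ratio of the block MLPs.
#' @param gate_hidden hidden width of the wavelet sub-band gating MLP.
#' @param iterations axial-attention sweeps per block (t).
#' @param aggregation `"sequential"` or `"summed"` axial aggregation.
#' @param decoder list: `align_width`, `fuse_width`, `head_width`,
#'   `se_hidden` (4 hidden widths of the per-level channel gates),
#'   `num_heads` (decoder attention), `plain_width` (baseline decoder).
#' @param variant one of `"full"`, `"B"`, `"B+MSFFD"`, `"B+MSFFD+IAFT"`.
#' @return object of class `wiaf_config`.
#' @export
wiaf_config <- function(in_channels = 4L, num_classes = 4L,
                        stage_channels = c(8L, 32L, 96L, 288L),
                        blocks_per_stage = c(1L, 2L, 1L, 3L),
                        num_heads = c(2L, 4L, 8L, 8L),
                        mlp_ratio = 2,
                        gate_hidden = 659L,
                        iterations = 1L,
                        aggregation = c("sequential", "summed"),
                        decoder = list(),
                        variant = c("full", "B", "B+MSFFD", "B+MSFFD+IAFT")) {
  aggregation <- match.arg(aggregation)
  variant <- match.arg(variant)
  dec <- utils::modifyList(
    list(align_width = 6L, fuse_width = 6L, head_width = 20L,
         se_hidden = c(4L, 16L, 63L, 227L), num_heads = 2L,
         plain_width = 16L),
    decoder)
  stopifnot(length(stage_channels) == 4L, length(blocks_per_stage) == 4L,
            length(num_heads) == 4L, all(diff(stage_channels) >= 0),
            all(stage_channels %% num_heads == 0L),
            iterations >= 1L, mlp_ratio > 0)
  structure(list(in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 stage_channels = as.integer(stage_channels),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 num_heads = as.integer(num_heads),
                 mlp_ratio = mlp_ratio,
                 gate_hidden = as.integer(gate_hidden),
                 iterations = as.integer(iterations),
                 aggregation = aggregation,
                 decoder = dec,
                 variant = variant),
            class = "wiaf_config")
}

#' Frozen reference configuration
#'
#' Reads the committed reference configuration, calibrated once (see
#' `scripts/calibrate_config.R`) so that the full model holds exactly
#' 5,230,007 trainable parameters (5.23 M), the decoder exactly 167,940, the
#' conv-stem ablation variant 5,187,748 (5.19 M), and one forward pass at a
#' `(4, 128, 128, 128)` input costs 9,749,321,472 MACs (9.75 G).
#'
#' @param variant optional variant override.
#' @return a [wiaf_config()].
#' @export
wiaf_reference_config <- function(variant = "full") {
  path <- system.file("extdata", "reference_config.yaml", package = "wiafseg")
  y <- yaml::read_yaml(path)
  wiaf_config(in_channels = y$in_channels, num_classes = y$num_classes,
              stage_channels = unlist(y$stage_channels),
              blocks_per_stage = unlist(y$blocks_per_stage),
              num_heads = unlist(y$num_heads),
              mlp_ratio = y$mlp_ratio, gate_hidden = y$gate_hidden,
              iterations = y$iterations, aggregation = y$aggregation,
              decoder = y$decoder, variant = variant)
}

#' Desk-scale configuration
#'
#' A reduced-width configuration for CPU-scale training and testing on
#' 32-cubed phantoms; architecture identical in kind to the reference model.
#' @inheritParams wiaf_reference_config
#' @export
wiaf_desk_config <- function(variant = "full") {
  wiaf_config(stage_channels = c(8L, 16L, 32L, 64L),
              blocks_per_stage = c(1L, 1L, 1L, 1L),
              num_heads = c(2L, 4L, 4L, 8L),
              gate_hidden = 16L,
              decoder = list(align_width = 6L, fuse_width = 6L,
                             head_width = 12L, se_hidden = c(4L, 8L, 16L, 32L),
                             num_heads = 2L, plain_width = 8L),
              variant = variant)
}

uses_iaft <- function(cfg) cfg$variant %in% c("full", "B+MSFFD+IAFT")
uses_awdfd <- function(cfg) cfg$variant == "full"
uses_msffd <- function(cfg) cfg$variant != "B"

# ---- builder -----------------------------------------------------------------

init_std_block <- function(C, mlp_ratio, reduce_kv) {
  hid <- as.integer(round(mlp_ratio * C))
  list(ln1 = init_layernorm(C),
       attn = init_attn(C),
       kv = if (reduce_kv) init_conv3(C, C, 2L),
       ln2 = init_layernorm(C),
       mlp = list(W1 = init_linear(C, hid),
                  W2 = list(W = matrix(0, hid, C), b = numeric(C))))
}

#' Build a segmentation model
#'
#' Instantiates the parameter tree of the configured variant. All
#' initialization is seeded and deterministic.
#'
#' @param config a [wiaf_config()].
#' @param seed RNG seed for initialization.
#' @return object of class `wiaf_model` (list with `config`, `params`).
#' @export
build_wiaf <- function(config, seed = 1L) {
  set.seed(seed)
  cs <- config$stage_channels
  rho <- config$mlp_ratio
  sub_ch <- 8L * config$in_channels
  stem <- if (uses_awdfd(config)) {
    list(gate = list(W1 = init_linear(sub_ch, config$gate_hidden),
                     W2 = init_linear(config$gate_hidden, sub_ch)),
         proj = init_linear(sub_ch, cs[1]))
  } else {
    list(conv = init_conv3(config$in_channels, cs[1], 3L))
  }
  mk_blocks <- function(C, n, stage) {
    lapply(seq_len(n), function(i) {
      if (uses_iaft(config)) init_iaft_block(C, rho)
      else init_std_block(C, rho, reduce_kv = (stage == 1L))
    })
  }
  stages <- list(
    list(blocks = mk_blocks(cs[1], config$blocks_per_stage[1], 1L)),
    list(down = init_conv3(cs[1], cs[2], 3L),
         blocks = mk_blocks(cs[2], config$blocks_per_stage[2], 2L)),
    list(down = init_conv3(cs[2], cs[3], 3L),
         blocks = mk_blocks(cs[3], config$blocks_per_stage[3], 3L)),
    list(down = init_conv3(cs[3], cs[4], 3L),
         blocks = mk_blocks(cs[4], config$blocks_per_stage[4], 4L))
  )
  dec <- config$decoder
  decoder <- if (uses_msffd(config)) {
    f <- dec$align_width; g <- dec$fuse_width; f2 <- dec$head_width
    list(
      se = lapply(1:4, function(i)
        list(W1 = init_linear(cs[i], dec$se_hidden[i]),
             W2 = init_linear(dec$se_hidden[i], cs[i]))),
      align = list(init_linear(cs[1], f), init_tconv2(cs[2], f),
                   init_tconv2(cs[3], f), init_tconv2(cs[4], f)),
      attn = lapply(1:4, function(i)
        list(axes = list(H = init_attn(f), W = init_attn(f),
                         D = init_attn(f)))),
      fuse = init_linear(4L * f, g),
      up = init_tconv2(g, f2),
      cls = init_linear(f2, config$num_classes))
  } else {
    u <- dec$plain_width
    lvl <- lapply(1:4, function(i) {
      chain <- vector("list", i)
      chain[[1]] <- init_tconv2(cs[i], u)
      if (i > 1) for (j in 2:i) chain[[j]] <- init_tconv2(u, u)
      chain
    })
    list(levels = lvl, fuse = init_linear(4L * u, u),
         cls = init_linear(u, config$num_classes))
  }
  structure(list(config = config,
                 params = list(stem = stem, stages = stages,
                               decoder = decoder)),
            class = "wiaf_model")
}

#' @export
print.wiaf_model <- function(x, ...) {
  cp <- count_params(x)
  cat(sprintf("<wiaf_model> variant '%s', %s trainable parameters\n",
              x$config$variant, format(cp$total, big.mark = ",")))
  invisible(x)
}

#' Build an ablation variant
#'
#' `"B"`: strided-conv stem, standard multi-head self-attention blocks
#' (stage-1 keys/values spatially reduced by a stride-2 convolution), plain
#' transposed-convolution decoder. `"B+MSFFD"` swaps in the fusion decoder;
#' `"B+MSFFD+IAFT"` additionally swaps in axial attention; `"full"` also
#' replaces the stem with the wavelet front end.
#'
#' @param config a [wiaf_config()] (its `variant` field is overridden).
#' @param variant the variant to build.
#' @param seed RNG seed.
#' @return a `wiaf_model`.
#' @export
build_variant <- function(config, variant, seed = 1L) {
  config$variant <- match.arg(variant, c("full", "B", "B+MSFFD",
                                         "B+MSFFD+IAFT"))
  build_wiaf(config, seed = seed)
}

# ---- forward pass ------------------------------------------------------------

iaft_stage_fwd <- function(blocks, cfg, f, heads, need_grad) {
  caches <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    r <- iaft_block_fwd(blocks[[i]], f$x, f$dims, heads,
                        cfg$aggregation, cfg$iterations, need_grad)
    f <- feat(r$out, f$dims)
    caches[[i]] <- r$cache
  }
  list(out = f, caches = caches)
}

std_block_fwd <- function(p, f, heads) {
  x <- f$x
  n1 <- layernorm_fwd(p$ln1, x)$out
  kv_src <- if (!is.null(p$kv)) {
    conv3_fwd(p$kv, feat(n1, f$dims), 2L, 2L, 0L)$out$x
  } else n1
  C <- ncol(x); ch <- C %/% heads
  Q <- linear_fwd(p$attn$Wq, n1)
  K <- linear_fwd(p$attn$Wk, kv_src)
  V <- linear_fwd(p$attn$Wv, kv_src)
  O <- matrix(0, nrow(x), C)
  for (h in seq_len(heads)) {
    cols <- seq.int((h - 1L) * ch + 1L, h * ch)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(ch)
    A <- softmax_rows(S)
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  x1 <- x + linear_fwd(p$attn$Wo, O)
  n2 <- layernorm_fwd(p$ln2, x1)$out
  x1 + linear_fwd(p$mlp$W2, silu(linear_fwd(p$mlp$W1, n2)))
}

encoder_fwd <- function(model, f, need_grad = TRUE) {
  cfg <- model$config
  p <- model$params
  feats <- vector("list", 4L)
  caches <- list(stages = vector("list", 4L))
  # stage 1
  if (uses_awdfd(cfg)) {
    st <- awdfd_stem_fwd(p$stem, f, need_grad)
    caches$stem <- st$cache
    cur <- st$out
  } else {
    st <- conv3_fwd(p$stem$conv, f, 3L, 2L, 1L)
    if (need_grad) caches$stem <- st$cache
    cur <- st$out
  }
  for (s in 1:4) {
    if (s > 1L) {
      dn <- conv3_fwd(p$stages[[s]]$down, cur, 3L, 2L, 1L)
      if (need_grad) caches$stages[[s]]$down <- dn$cache
      cur <- dn$out
    }
    if (uses_iaft(cfg)) {
      sr <- iaft_stage_fwd(p$stages[[s]]$blocks, cfg, cur,
                           cfg$num_heads[s], need_grad)
      caches$stages[[s]]$blocks <- sr$caches
      cur <- sr$out
    } else {
      for (b in p$stages[[s]]$blocks)
        cur <- feat(std_block_fwd(b, cur, cfg$num_heads[s]), cur$dims)
    }
    feats[[s]] <- cur
  }
  list(feats = feats, cache = caches)
}

msffd_fwd <- function(model, feats, need_grad = TRUE) {
  cfg <- model$config
  dp <- model$params$decoder
  dec <- cfg$decoder
  dims1 <- feats[[1]]$dims
  aligned <- vector("list", 4L)
  cc <- list(se = vector("list", 4L), align = vector("list", 4L),
             attn = vector("list", 4L))
  for (i in 1:4) {
    x <- feats[[i]]$x
    V <- nrow(x)
    g <- matrix(colMeans(x), 1L)
    h_pre <- linear_fwd(dp$se[[i]]$W1, g)
    h <- relu(h_pre)
    w <- sigmoid(linear_fwd(dp$se[[i]]$W2, h))
    xs <- x * rep(w, each = V)
    if (need_grad) cc$se[[i]] <- list(x = x, g = g, h_pre = h_pre, h = h,
                                      w = w, V = V)
    fs <- feat(xs, feats[[i]]$dims)
    if (i == 1L) {
      al <- feat(linear_fwd(dp$align[[1]], xs), dims1)
      if (need_grad) cc$align[[1]] <- list(x = xs)
    } else {
      tc <- tconv2_fwd(dp$align[[i]], fs)
      if (need_grad) cc$align[[i]] <- list(cache = tc$cache,
                                           mid_dims = tc$out$dims)
      al <- if (all(tc$out$dims == dims1)) tc$out
            else trilinear_resize(tc$out, dims1)
    }
    at <- iaf_fwd(al$x, dims1, dp$attn[[i]], dec$num_heads,
                  "sequential", 1L, need_grad)
    if (need_grad) cc$attn[[i]] <- at$cache
    aligned[[i]] <- at$out
  }
  cat_x <- do.call(cbind, aligned)
  fu_pre <- linear_fwd(dp$fuse, cat_x)
  fu <- silu(fu_pre)
  up <- tconv2_fwd(dp$up, feat(fu, dims1))
  up_act <- silu(up$out$x)
  logits <- linear_fwd(dp$cls, up_act)
  list(out = feat(logits, up$out$dims),
       cache = if (need_grad) list(cc = cc, cat_x = cat_x, fu_pre = fu_pre,
                                   fu = fu, up_cache = up$cache,
                                   up_pre = up$out$x, up_act = up_act,
                                   dims1 = dims1))
}

plain_decoder_fwd <- function(model, feats) {
  dp <- model$params$decoder
  outs <- vector("list", 4L)
  for (i in 1:4) {
    cur <- feats[[i]]
    for (tc in dp$levels[[i]]) cur <- tconv2_fwd(tc, cur)$out
    outs[[i]] <- silu(cur$x)
  }
  cat_x <- do.call(cbind, outs)
  fu <- silu(linear_fwd(dp$fuse, cat_x))
  feat(linear_fwd(dp$cls, fu), feats[[1]]$dims * 2L)
}

wiaf_fwd_feat <- function(model, f, need_grad = TRUE) {
  enc <- encoder_fwd(model, f, need_grad)
  if (uses_msffd(model$config)) {
    dec <- msffd_fwd(model, enc$feats, need_grad)
    list(out = dec$out,
         cache = if (need_grad) list(enc = enc$cache, dec = dec$cache,
                                     feats = enc$feats))
  } else {
    list(out = plain_decoder_fwd(model, enc$feats), cache = NULL)
  }
}

#' Encoder forward pass
#'
#' Runs the four encoder stages and returns the feature pyramid C1..C4 at
#' strides 2, 4, 8, 16.
#'
#' @param model a `wiaf_model`.
#' @param volume input [multichannel_volume()]; spatial dims divisible by 16.
#' @return list of four [multichannel_volume()]s.
#' @export
encoder_forward <- function(model, volume) {
  d <- dim(volume$data)[2:4]
  if (any(d %% 16L != 0L))
    stop("input spatial dims must be divisible by 16, got ",
         paste(d, collapse = "x"))
  f <- vol_to_feat(volume$data)
  enc <- encoder_fwd(model, f, need_grad = FALSE)
  lapply(enc$feats, function(ff)
    multichannel_volume(feat_to_vol(ff), spacing = volume$spacing * 0 + 1))
}

#' Decoder forward pass
#'
#' Fuses a feature pyramid into full-resolution class logits: per-level
#' channel gating, alignment to the stride-2 grid (transposed convolution
#' plus trilinear interpolation), an axial-attention pass per level with
#' SiLU residual, channel concatenation, 1x1x1 compression, progressive
#' upsampling, and a pointwise classifier.
#'
#' @param model a `wiaf_model` with the fusion decoder.
#' @param pyramid list of four [multichannel_volume()]s from
#'   [encoder_forward()].
#' @return a [multichannel_volume()] of logits (num_classes channels).
#' @export
msffd_forward <- function(model, pyramid) {
  feats <- lapply(pyramid, function(v) vol_to_feat(v$data))
  dec <- msffd_fwd(model, feats, need_grad = FALSE)
  multichannel_volume(feat_to_vol(dec$out))
}

#' Full network forward pass
#'
#' @param model a `wiaf_model`.
#' @param volume input [multichannel_volume()].
#' @return a [multichannel_volume()] holding per-class logits at the input
#'   resolution.
#' @export
wiaf_forward <- function(model, volume) {
  d <- dim(volume$data)[2:4]
  if (any(d %% 16L != 0L))
    stop("input spatial dims must be divisible by 16")
  f <- vol_to_feat(volume$data)
  r <- wiaf_fwd_feat(model, f, need_grad = FALSE)
  multichannel_volume(feat_to_vol(r$out), spacing = volume$spacing)
}

# ---- backward pass (full variant) --------------------------------------------

msffd_bwd <- function(model, feats, cache, dlogits) {
  dp <- model$params$decoder
  dec <- model$config$decoder
  dgrad <- tree_zeros_like(dp)
  bcls <- linear_bwd(dp$cls, cache$up_act, dlogits)
  dgrad$cls <- bcls$dp
  dup <- bcls$dx * silu_grad(cache$up_pre)
  bup <- tconv2_bwd(dp$up, cache$up_cache, dup)
  dgrad$up <- bup$dp
  dfu <- bup$dx * silu_grad(cache$fu_pre)
  bfuse <- linear_bwd(dp$fuse, cache$cat_x, dfu)
  dgrad$fuse <- bfuse$dp
  f <- dec$align_width
  dfeats <- vector("list", 4L)
  for (i in 1:4) {
    dal <- bfuse$dx[, seq.int((i - 1L) * f + 1L, i * f), drop = FALSE]
    ba <- iaf_bwd(dp$attn[[i]], cache$cc$attn[[i]], dal)
    dgrad$attn[[i]] <- ba$dp
    dal <- ba$dx
    se <- cache$cc$se[[i]]
    if (i == 1L) {
      b1 <- linear_bwd(dp$align[[1]], cache$cc$align[[1]]$x, dal)
      dgrad$align[[1]] <- b1$dp
      dxs <- b1$dx
    } else {
      mid_dims <- cache$cc$align[[i]]$mid_dims
      dmid <- if (all(mid_dims == cache$dims1)) feat(dal, mid_dims)
              else trilinear_resize_bwd(feat(dal, cache$dims1), mid_dims)
      bt <- tconv2_bwd(dp$align[[i]], cache$cc$align[[i]]$cache, dmid$x)
      dgrad$align[[i]] <- bt$dp
      dxs <- bt$dx
    }
    # back through the channel gate
    V <- se$V
    dx_direct <- dxs * rep(se$w, each = V)
    dw <- colSums(dxs * se$x)
    dwpre <- dw * se$w * (1 - se$w)
    b2 <- linear_bwd(dp$se[[i]]$W2, se$h, matrix(dwpre, 1L))
    dh <- b2$dx * (se$h_pre > 0)
    b1g <- linear_bwd(dp$se[[i]]$W1, se$g, dh)
    dgrad$se[[i]] <- list(W1 = b1g$dp, W2 = b2$dp)
    dfeats[[i]] <- dx_direct + rep(b1g$dx, each = V) / V
  }
  list(dfeats = dfeats, dp = dgrad)
}

encoder_bwd <- function(model, cache, dfeats) {
  cfg <- model$config
  p <- model$params
  dgrad <- tree_zeros_like(p[c("stem", "stages")])
  dcur <- NULL
  for (s in 4:1) {
    dcur <- if (is.null(dcur)) dfeats[[s]] else dcur + dfeats[[s]]
    blocks <- p$stages[[s]]$blocks
    bl_cache <- cache$stages[[s]]$blocks
    for (i in rev(seq_along(blocks))) {
      bb <- iaft_block_bwd(blocks[[i]], bl_cache[[i]], dcur)
      dgrad$stages[[s]]$blocks[[i]] <- bb$dp
      dcur <- bb$dx
    }
    if (s > 1L) {
      bd <- conv3_bwd(p$stages[[s]]$down, cache$stages[[s]]$down, dcur)
      dgrad$stages[[s]]$down <- bd$dp
      dcur <- bd$dx
    }
  }
  if (uses_awdfd(cfg)) {
    bs <- awdfd_stem_bwd(p$stem, cache$stem, dcur)
    dgrad$stem <- bs$dp
  } else {
    bs <- conv3_bwd(p$stem$conv, cache$stem, dcur)
    dgrad$stem <- list(conv = bs$dp)
  }
  dgrad
}

# full-model gradient for a single case; dlogits on the (V, num_classes) grid
wiaf_bwd <- function(model, fwd, dlogits) {
  if (!uses_iaft(model$config) || !uses_msffd(model$config))
    stop("training backward is implemented for the attention+fusion variants")
  db <- msffd_bwd(model, fwd$cache$feats, fwd$cache$dec, dlogits)
  denc <- encoder_bwd(model, fwd$cache$enc, db$dfeats)
  list(stem = denc$stem, stages = denc$stages, decoder = db$dp)
}

# ---- budgets -----------------------------------------------------------------

#' Count trainable parameters
#'
#' @param model a `wiaf_model`.
#' @return list with `total` and a per-component `breakdown` (stem, one
#'   entry per encoder stage, decoder).
#' @export
count_params <- function(model) {
  p <- model$params
  br <- c(stem = tree_size(p$stem),
          stage1 = tree_size(p$stages[[1]]),
          stage2 = tree_size(p$stages[[2]]),
          stage3 = tree_size(p$stages[[3]]),
          stage4 = tree_size(p$stages[[4]]),
          decoder = tree_size(p$decoder))
  list(total = sum(br), breakdown = br)
}

#' Analytic multiply-accumulate count of one forward pass
#'
#' Counts one MAC per reported FLOP under a fixed convention: convolutions
#' (including the fixed wavelet analysis filters), channel projections, and
#' attention score / value products are counted; normalizations,
#' activations, softmax, pooling and interpolation are excluded. The count
#' is closed-form from the configuration — no forward pass is run.
#'
#' @param config a [wiaf_config()].
#' @param input_shape integer `(C, H, W, D)`.
#' @return list with `total` and per-component `breakdown`.
#' @export
count_macs <- function(config, input_shape = c(4L, 128L, 128L, 128L)) {
  cfg <- config
  cs <- cfg$stage_channels
  rho <- cfg$mlp_ratio
  t <- cfg$iterations
  Cin <- input_shape[1]
  d0 <- input_shape[2:4]
  N0 <- prod(d0)
  dims_s <- lapply(1:4, function(s) d0 %/% (2L^s))
  Ns <- vapply(dims_s, prod, numeric(1))
  iaft_block_macs <- function(C, N, dims)
    t * (12 * N * C^2 + 2 * N * C * sum(dims)) + 2 * rho * N * C^2
  std_block_macs <- function(C, N, dims, reduce) {
    M <- if (reduce) N / 8 else N
    kv_conv <- if (reduce) M * 8 * C^2 else 0
    4 * N * C^2 + kv_conv + 2 * N * M * C + 2 * rho * N * C^2
  }
  block_macs <- function(s) {
    fn <- if (uses_iaft(cfg)) function(C, N, dims) iaft_block_macs(C, N, dims)
          else function(C, N, dims) std_block_macs(C, N, dims, s == 1L)
    cfg$blocks_per_stage[s] * fn(cs[s], Ns[s], dims_s[[s]])
  }
  stem <- if (uses_awdfd(cfg)) {
    8 * Cin * N0 +                       # Haar analysis (8 taps per coeff)
      2 * (8 * Cin) * cfg$gate_hidden +  # gating MLP (GAP excluded)
      Ns[1] * (8 * Cin) * cs[1]          # 1x1x1 projection
  } else {
    Ns[1] * 27 * Cin * cs[1]
  }
  stages <- numeric(4)
  stages[1] <- block_macs(1L)
  for (s in 2:4)
    stages[s] <- Ns[s] * 27 * cs[s - 1] * cs[s] + block_macs(s)
  dec <- cfg$decoder
  decoder <- if (uses_msffd(cfg)) {
    f <- dec$align_width; g <- dec$fuse_width; f2 <- dec$head_width
    se <- sum(2 * cs * dec$se_hidden)
    align <- Ns[1] * cs[1] * f + Ns[1] * cs[2] * f +
      Ns[2] * cs[3] * f + Ns[3] * cs[4] * f
    attn <- 4 * (12 * Ns[1] * f^2 + 2 * Ns[1] * f * sum(dims_s[[1]]))
    fuse <- Ns[1] * 4 * f * g
    up <- N0 * g * f2
    cls <- N0 * f2 * cfg$num_classes
    se + align + attn + fuse + up + cls
  } else {
    u <- dec$plain_width
    lv <- 0
    for (i in 1:4) {
      Vi <- Ns[i]
      lv <- lv + Vi * cs[i] * 8 * u          # first transposed conv
      if (i > 1) for (j in 2:i) {
        Vi <- Vi * 8
        lv <- lv + Vi * u * 8 * u
      }
    }
    lv + N0 * 4 * u * u + N0 * u * cfg$num_classes
  }
  br <- c(stem = stem, stage1 = stages[1], stage2 = stages[2],
          stage3 = stages[3], stage4 = stages[4], decoder = decoder)
  list(total = sum(br), breakdown = br)
}

#' Parameter and MAC report
#'
#' @param config a [wiaf_config()].
#' @param input_shape input shape for the MAC count.
#' @param seed build seed (counts do not depend on it).
#' @return data.frame with per-component parameters and MACs plus totals.
#' @export
summarize_model <- function(config, input_shape = c(4L, 128L, 128L, 128L),
                            seed = 1L) {
  model <- build_wiaf(config, seed = seed)
  cp <- count_params(model)
  cm <- count_macs(config, input_shape)
  df <- data.frame(component = c(names(cp$breakdown), "total"),
                   params = c(unname(cp$breakdown), cp$total),
                   macs = c(unname(cm$breakdown), cm$total))
  df$params_M <- round(df$params / 1e6, 2)
  df$macs_G <- round(df$macs / 1e9, 2)
  df
}
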