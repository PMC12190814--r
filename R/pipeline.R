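# Case I/O, training loop, prediction and evaluation.

# BraTS label convention <-> internal class indices
LABEL_VALUES <- c(0L, 1L, 2L, 4L)

labels_to_onehot <- function(labels) {
  cls <- match(as.vector(labels), LABEL_VALUES)
  if (anyNA(cls)) stop("labelmap contains values outside {0, 1, 2, 4}")
  y <- matrix(0, length(cls), 4L)
  y[cbind(seq_along(cls), cls)] <- 1
  y
}

# labels arrive in (H, W, D); reorder rows to the internal depth-fastest raster
labels_to_onehot_feat <- function(labels) {
  a <- aperm(labels, c(3L, 2L, 1L))
  labels_to_onehot(as.vector(a))
}

#' Per-channel z-score normalization over nonzero voxels
#'
#' @param volume a [multichannel_volume()].
#' @param eps zero threshold.
#' @return normalized [multichannel_volume()].
#' @export
normalize_volume <- function(volume, eps = 1e-8) {
  v <- volume$data
  for (m in seq_len(dim(v)[1])) {
    ch <- v[m, , , ]
    nz <- abs(ch) > eps
    if (any(nz)) {
      mu <- mean(ch[nz]); sd <- stats::sd(ch[nz])
      if (sd > 0) v[m, , , ] <- (ch - mu) / sd
    }
  }
  multichannel_volume(v, volume$spacing)
}

# center crop / zero pad one axis to length `n`
.fit_axis <- function(len, n) {
  if (len >= n) {
    s <- (len - n) %/% 2L + 1L
    list(src = s:(s + n - 1L), dst = 1:n)
  } else {
    s <- (n - len) %/% 2L + 1L
    list(src = 1:len, dst = s:(s + len - 1L))
  }
}

crop_pad <- function(arr, target) {
  d <- dim(arr)
  nd <- length(d)
  sp <- nd - 2L   # first spatial dim index - 1 (channels first if rank 4)
  ax <- lapply(1:3, function(i) .fit_axis(d[i + nd - 3L], target[i]))
  if (nd == 4L) {
    out <- array(0, c(d[1], target))
    out[, ax[[1]]$dst, ax[[2]]$dst, ax[[3]]$dst] <-
      arr[, ax[[1]]$src, ax[[2]]$src, ax[[3]]$src, drop = FALSE]
  } else {
    out <- array(if (is.integer(arr)) 0L else 0, target)
    out[ax[[1]]$dst, ax[[2]]$dst, ax[[3]]$dst] <-
      arr[ax[[1]]$src, ax[[2]]$src, ax[[3]]$src, drop = FALSE]
  }
  out
}

#' Load a multimodal case from NIfTI files
#'
#' Stacks the four modalities in the fixed order T1, T1ce, T2, FLAIR,
#' z-scores each channel over its nonzero voxels, and optionally center
#' crops / zero pads to a target cube.
#'
#' @param paths named character vector/list with entries `t1`, `t1ce`, `t2`,
#'   `flair` and optionally `seg`.
#' @param target optional integer: target cube side.
#' @param normalize apply z-score normalization (default TRUE).
#' @return list with `volume` ([multichannel_volume()]) and `labels`
#'   (integer array or NULL).
#' @export
load_case <- function(paths, target = NULL, normalize = TRUE) {
  paths <- as.list(paths)
  need <- modality_names
  if (!all(need %in% names(paths)))
    stop("missing modality file(s): ",
         paste(setdiff(need, names(paths)), collapse = ", "))
  imgs <- lapply(need, function(m) {
    img <- RNifti::readNifti(paths[[m]])
    array(as.numeric(img), dim(img))
  })
  d <- dim(imgs[[1]])
  for (img in imgs) if (!all(dim(img) == d))
    stop("modality shapes are not co-registered")
  pix <- tryCatch(RNifti::pixdim(RNifti::readNifti(paths[["t1"]]))[1:3],
                  error = function(e) c(1, 1, 1))
  vol <- array(0, c(4L, d))
  for (m in 1:4) vol[m, , , ] <- imgs[[m]]
  labels <- NULL
  if (!is.null(paths$seg)) {
    seg <- RNifti::readNifti(paths$seg)
    labels <- array(as.integer(round(as.numeric(seg))), dim(seg))
    if (!all(dim(labels) == d)) stop("label shape mismatch")
  }
  if (!is.null(target)) {
    tgt <- rep(as.integer(target), length.out = 3L)
    vol <- crop_pad(vol, tgt)
    if (!is.null(labels)) labels <- crop_pad(labels, tgt)
  }
  v <- multichannel_volume(vol, spacing = pix)
  if (normalize) v <- normalize_volume(v)
  list(volume = v, labels = labels)
}

# ---- training ----------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the full optimization protocol: AdamW, initial learning
#' rate 2e-4 decayed to 1e-5 by cosine annealing with warm restarts every 20
#' epochs, batch size 2, 400 epochs. The `"desk"` preset is the committed
#' CPU-scale configuration: 32-cubed phantoms, 20 epochs, batch size 1,
#' initial learning rate 5e-3 with a 40-epoch cosine cycle so the rate stays
#' high throughout the short run.
#'
#' @param preset `"full"` or `"desk"`.
#' @param ... overrides of individual fields.
#' @return a `train_config` list.
#' @export
train_config <- function(preset = c("desk", "full"), ...) {
  preset <- match.arg(preset)
  base <- list(lr_init = 2e-4, lr_min = 1e-5, cycle = 20L, batch_size = 2L,
               epochs = 400L, weight_decay = 0.01,
               loss = loss_weights(), augment = augment_policy(),
               augment_train = TRUE, seed = 0L, preset = preset)
  if (preset == "desk") {
    base$epochs <- 20L
    base$lr_init <- 5e-3
    base$cycle <- 40L
    base$batch_size <- 1L
  }
  cfg <- utils::modifyList(base, list(...))
  stopifnot(cfg$lr_init >= cfg$lr_min, cfg$lr_min > 0, cfg$batch_size >= 1)
  structure(cfg, class = "train_config")
}

case_to_training_pair <- function(case, tc) {
  v <- case$volume
  labels <- case$labels
  if (tc$augment_train) {
    a <- augment(v, labels, tc$augment)
    v <- a$volume; labels <- a$labels
  }
  list(f = vol_to_feat(normalize_volume(v)$data),
       y = labels_to_onehot_feat(labels))
}

#' Train a segmentation model
#'
#' Runs the AdamW optimization loop with the compound Dice + cross-entropy
#' loss and cosine annealing with warm restarts (the learning rate resets to
#' its initial value at the start of every cycle). The model with the best
#' validation mean region Dice is checkpointed. Fully seeded; a non-finite
#' loss aborts with diagnostics.
#'
#' @param model_config a [wiaf_config()] (variant `"full"`).
#' @param dataset output of [generate_dataset()], or a list with `cases`.
#' @param tc a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (best checkpoint), `final_model`, `log`
#'   (per-epoch data.frame), `best_epoch`, `best_val_dice`.
#' @export
train <- function(model_config, dataset, tc = train_config("desk"),
                  verbose = FALSE) {
  cases <- dataset$cases %||% dataset
  train_cases <- Filter(function(cs) identical(cs$split, "train"), cases)
  val_cases <- Filter(function(cs) identical(cs$split, "val"), cases)
  if (!length(train_cases)) train_cases <- cases
  set.seed(tc$seed)
  model <- build_wiaf(model_config, seed = tc$seed + 1L)
  opt <- adamw_init(model$params)
  log <- vector("list", tc$epochs)
  best <- list(dice = -Inf, params = model$params, epoch = 0L)
  for (epoch in seq_len(tc$epochs)) {
    lr <- cosine_warm_restart_lr(epoch - 1L, tc$lr_init, tc$lr_min, tc$cycle)
    ord <- sample(length(train_cases))
    ep_loss <- 0; nb <- 0L
    for (bs in split(ord, ceiling(seq_along(ord) / tc$batch_size))) {
      gsum <- NULL; lsum <- 0
      for (ci in bs) {
        pair <- case_to_training_pair(train_cases[[ci]], tc)
        fw <- wiaf_fwd_feat(model, pair$f, need_grad = TRUE)
        lg <- combined_loss_grad(fw$out$x, pair$y, tc$loss)
        if (!is.finite(lg$loss))
          stop(sprintf(paste0("training diverged: non-finite loss at epoch ",
                              "%d (lr %.2e); inspect the log"), epoch, lr))
        gr <- wiaf_bwd(model, fw, lg$grad)
        gsum <- if (is.null(gsum)) gr else tree_add(gsum, gr)
        lsum <- lsum + lg$loss
      }
      gavg <- tree_scale(gsum, 1 / length(bs))
      stp <- adamw_step(model$params, gavg, opt, lr,
                        weight_decay = tc$weight_decay)
      model$params <- stp$params
      opt <- stp$state
      ep_loss <- ep_loss + lsum / length(bs); nb <- nb + 1L
    }
    ep_loss <- ep_loss / nb
    val_dice <- NA_real_
    if (length(val_cases)) {
      val_dice <- mean(vapply(val_cases, function(cs) {
        pred <- predict_labels(model, normalize_volume(cs$volume))
        rs_p <- brats_regions(pred); rs_g <- brats_regions(cs$labels)
        mean(c(dice_score(rs_p$ET, rs_g$ET), dice_score(rs_p$TC, rs_g$TC),
               dice_score(rs_p$WT, rs_g$WT)))
      }, numeric(1)))
      if (val_dice > best$dice)
        best <- list(dice = val_dice, params = model$params, epoch = epoch)
    }
    log[[epoch]] <- data.frame(epoch = epoch, lr = lr, loss = ep_loss,
                               val_dice = val_dice)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  val dice %.3f",
                      epoch, lr, ep_loss, val_dice))
  }
  best_model <- model
  if (is.finite(best$dice)) best_model$params <- best$params
  list(model = best_model, final_model = model,
       log = do.call(rbind, log),
       best_epoch = best$epoch, best_val_dice = best$dice)
}

#' Save / load a model checkpoint
#'
#' @param model a `wiaf_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

# ---- prediction --------------------------------------------------------------

#' Predict a BraTS-convention labelmap
#'
#' Voxelwise argmax of the softmax class probabilities, mapped back to the
#' label values \{0, 1, 2, 4\}. Deterministic.
#'
#' @param model a trained `wiaf_model`.
#' @param volume input [multichannel_volume()] (normalized).
#' @return integer labelmap (H, W, D).
#' @export
predict_labels <- function(model, volume) {
  f <- vol_to_feat(volume$data)
  r <- wiaf_fwd_feat(model, f, need_grad = FALSE)
  cls <- max.col(r$out$x, ties.method = "first")
  lab <- LABEL_VALUES[cls]
  d <- r$out$dims
  a <- array(lab, c(d[3], d[2], d[1]))      # (D, W, H)
  aperm(a, c(3L, 2L, 1L))
}

#' @export
predict.wiaf_model <- function(object, volume, ...) {
  predict_labels(object, volume)
}

# ---- evaluation --------------------------------------------------------------

region_case_metrics <- function(pred, gt, spacing = c(1, 1, 1)) {
  rp <- brats_regions(pred); rg <- brats_regions(gt)
  out <- list()
  for (rn in c("ET", "TC", "WT")) {
    h <- hd95(rp[[rn]], rg[[rn]], spacing)
    out[[rn]] <- c(dice = dice_score(rp[[rn]], rg[[rn]]),
                   hd95 = as.numeric(h),
                   hd95_empty = as.numeric(isTRUE(attr(h, "empty"))))
  }
  out
}

t_ci <- function(x, level = 0.95) {
  n <- length(x)
  m <- mean(x)
  if (n < 2L) return(c(mean = m, lo = m, hi = m))
  se <- stats::sd(x) / sqrt(n)
  q <- stats::qt(1 - (1 - level) / 2, df = n - 1L)
  c(mean = m, lo = m - q * se, hi = m + q * se)
}

#' Evaluate predictions against reference labelmaps
#'
#' Computes per-case, per-region Dice and HD95 (ET / TC / WT) and
#' region-level means with Student-t 95% confidence intervals. With a
#' single case the interval degenerates to the point value and is flagged.
#'
#' @param preds named list of predicted labelmaps.
#' @param gts named list of reference labelmaps (matching names/order).
#' @param spacing voxel spacing in mm.
#' @return an `eval_report`: list with `per_case` and `summary` data.frames.
#' @export
evaluate <- function(preds, gts, spacing = c(1, 1, 1)) {
  if (length(preds) != length(gts)) stop("unmatched case lists")
  ids <- names(preds) %||% sprintf("case_%03d", seq_along(preds))
  rows <- list()
  for (i in seq_along(preds)) {
    m <- region_case_metrics(preds[[i]], gts[[i]], spacing)
    for (rn in names(m))
      rows[[length(rows) + 1L]] <-
        data.frame(case = ids[i], region = rn, dice = m[[rn]]["dice"],
                   hd95 = m[[rn]]["hd95"],
                   hd95_sentinel = m[[rn]]["hd95_empty"] > 0)
  }
  per_case <- do.call(rbind, rows)
  rownames(per_case) <- NULL
  srows <- list()
  for (rn in c("ET", "TC", "WT")) {
    sub <- per_case[per_case$region == rn, ]
    cd <- t_ci(sub$dice); ch <- t_ci(sub$hd95)
    srows[[rn]] <- data.frame(
      region = rn, n = nrow(sub),
      dice_mean = cd["mean"], dice_lo = cd["lo"], dice_hi = cd["hi"],
      hd95_mean = ch["mean"], hd95_lo = ch["lo"], hd95_hi = ch["hi"],
      degenerate_ci = nrow(sub) < 2L)
  }
  summary <- do.call(rbind, srows)
  rownames(summary) <- NULL
  structure(list(per_case = per_case, summary = summary),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Paired t-test between two per-case score vectors
#'
#' Standard paired-sample t-test on the per-case differences, with
#' significance flags at 0.05 and 0.01. Identical vectors (zero variance of
#' the differences) yield `t = 0`, `p = 1` and are flagged degenerate.
#'
#' @param scores_a,scores_b equal-length numeric vectors (n >= 2).
#' @return list with `t`, `p`, `df`, `mean_diff`, `significant_05`,
#'   `significant_01`, `degenerate`.
#' @export
paired_ttest <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) stop("unequal lengths")
  n <- length(scores_a)
  if (n < 2L) stop("paired t-test needs at least 2 pairs")
  d <- scores_a - scores_b
  if (stats::sd(d) == 0) {
    return(list(t = 0, p = 1, df = n - 1L, mean_diff = mean(d),
                significant_05 = FALSE, significant_01 = FALSE,
                degenerate = TRUE))
  }
  ht <- stats::t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       mean_diff = mean(d),
       significant_05 = ht$p.value < 0.05,
       significant_01 = ht$p.value < 0.01,
       degenerate = FALSE)
}
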