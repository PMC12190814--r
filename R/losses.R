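# Segmentation objectives and evaluation metrics.

#' Loss weighting
#'
#' @param lambda1 weight of the Dice term.
#' @param lambda2 weight of the cross-entropy term.
#' @param eps Dice smoothing constant.
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(lambda1 = 1, lambda2 = 1, eps = 1e-5) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda1 + lambda2 > 0, eps > 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, eps = eps),
            class = "loss_weights")
}

# canonicalize prediction/target pairs to (V, K) matrices
.as_vk <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (is.null(d)) return(matrix(x, ncol = 1L))
  if (length(d) == 4L) {                      # (K, H, W, D)
    m <- aperm(x, c(2L, 3L, 4L, 1L))
    dim(m) <- c(prod(d[2:4]), d[1])
    m
  } else matrix(x, ncol = 1L)
}

#' Soft Dice loss
#'
#' `1 - (2 sum(y p) + eps) / (sum(y + p) + eps)` per class, averaged over
#' foreground classes (all classes except the first when more than one
#' channel is present; for single-channel binary inputs the one channel is
#' used). Prioritizes regional overlap over per-voxel classification, which
#' counteracts the extreme foreground/background imbalance of tumor
#' segmentation.
#'
#' @param pred per-class probabilities, `(K, H, W, D)` array or `(V, K)`
#'   matrix, values in `[0, 1]`.
#' @param target one-hot labels of the same shape.
#' @param eps smoothing constant.
#' @return scalar loss.
#' @export
dice_loss <- function(pred, target, eps = 1e-5) {
  p <- .as_vk(pred); y <- .as_vk(target)
  if (!all(dim(p) == dim(y))) stop("pred/target shape mismatch")
  ks <- if (ncol(p) > 1L) 2:ncol(p) else 1L
  ls <- vapply(ks, function(k) {
    num <- 2 * sum(y[, k] * p[, k]) + eps
    den <- sum(y[, k] + p[, k]) + eps
    1 - num / den
  }, numeric(1))
  mean(ls)
}

#' Cross-entropy loss
#'
#' Mean voxelwise cross-entropy; categorical over the class axis for
#' multi-channel inputs, and the binary form
#' `-(y log p + (1-y) log(1-p))` for a single probability channel.
#' Probabilities are clamped at 1e-12.
#'
#' @inheritParams dice_loss
#' @return scalar loss.
#' @export
ce_loss <- function(pred, target) {
  p <- .as_vk(pred); y <- .as_vk(target)
  if (!all(dim(p) == dim(y))) stop("pred/target shape mismatch")
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  if (ncol(p) == 1L) {
    -mean(y * log(p) + (1 - y) * log(1 - p))
  } else {
    -mean(rowSums(y * log(p)))
  }
}

#' Weighted compound loss
#'
#' `lambda1 * dice_loss + lambda2 * ce_loss`.
#'
#' @inheritParams dice_loss
#' @param weights a [loss_weights()].
#' @return scalar loss.
#' @export
combined_loss <- function(pred, target, weights = loss_weights()) {
  weights$lambda1 * dice_loss(pred, target, weights$eps) +
    weights$lambda2 * ce_loss(pred, target)
}

# gradient of the compound loss w.r.t. logits, for (V, K) softmax outputs
combined_loss_grad <- function(logits, y, weights = loss_weights()) {
  V <- nrow(logits); K <- ncol(logits)
  p <- softmax_rows(logits)
  # CE: d/dlogits mean(-sum y log p) = (p - y) / V
  dce <- (p - y) / V
  # Dice: dL/dp then chain through softmax
  gp <- matrix(0, V, K)
  fg <- 2:K
  for (k in fg) {
    A <- 2 * sum(y[, k] * p[, k]) + weights$eps
    B <- sum(y[, k] + p[, k]) + weights$eps
    gp[, k] <- -(2 * y[, k] * B - A) / B^2 / length(fg)
  }
  ddice <- p * (gp - rowSums(gp * p))
  loss <- weights$lambda1 * dice_loss(p, y, weights$eps) +
    weights$lambda2 * ce_loss(p, y)
  list(loss = loss,
       grad = weights$lambda1 * ddice + weights$lambda2 * dce)
}

# ---- evaluation metrics ------------------------------------------------------

#' Dice similarity coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param pred_mask,gt_mask logical/0-1 arrays of equal shape.
#' @return value in `[0, 1]`.
#' @export
dice_score <- function(pred_mask, gt_mask) {
  a <- as.logical(pred_mask); b <- as.logical(gt_mask)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) return(1)
  2 * sum(a & b) / (sa + sb)
}

# surface voxels: mask voxels with at least one 6-neighbour outside the mask
# (volume boundary counts as outside)
.surface_coords <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  core <- pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  nb <- pad[1:d[1], 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    pad[3:(d[1] + 2L), 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    pad[2:(d[1] + 1L), 1:d[2], 2:(d[3] + 1L)] &
    pad[2:(d[1] + 1L), 3:(d[2] + 2L), 2:(d[3] + 1L)] &
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 1:d[3]] &
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L)]
  which(core & !nb, arr.ind = TRUE)
}

# directed surface distances from each point of A to the nearest point of B
.directed_dists <- function(A, B, chunk = 2048L) {
  n <- nrow(A)
  out <- numeric(n)
  bsq <- rowSums(B * B)
  for (s in seq(1L, n, chunk)) {
    e <- min(s + chunk - 1L, n)
    Ab <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ab * Ab), bsq, `+`) - 2 * tcrossprod(Ab, B)
    out[s:e] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

#' 95th-percentile Hausdorff distance
#'
#' The 95th percentile of the pooled symmetric surface-to-surface Euclidean
#' distances between two binary masks, in millimetres (voxel coordinates are
#' scaled by `spacing`). If either mask is empty the volume diagonal is
#' returned as a sentinel, with attribute `empty = TRUE`.
#'
#' @param pred_mask,gt_mask binary arrays of equal shape.
#' @param spacing mm per voxel, length 3.
#' @return distance in mm (attribute `empty` flags the sentinel case).
#' @export
hd95 <- function(pred_mask, gt_mask, spacing = c(1, 1, 1)) {
  pm <- array(as.logical(pred_mask), dim(pred_mask))
  gm <- array(as.logical(gt_mask), dim(gt_mask))
  if (!any(pm) || !any(gm)) {
    sent <- sqrt(sum((dim(pm) * spacing)^2))
    return(structure(sent, empty = TRUE))
  }
  A <- .surface_coords(pm)
  B <- .surface_coords(gm)
  A <- sweep(A, 2L, spacing, `*`)
  B <- sweep(B, 2L, spacing, `*`)
  pooled <- c(.directed_dists(A, B), .directed_dists(B, A))
  unname(stats::quantile(pooled, 0.95, type = 7))
}

#' Compose BraTS evaluation regions from a labelmap
#'
#' Labels follow the BraTS convention: 0 background, 1 necrotic and
#' non-enhancing tumor core (NCR/NET), 2 peritumoral edema (ED), 4 enhancing
#' tumor (ET). Regions: ET = \{4\}, TC = \{1, 4\}, WT = \{1, 2, 4\}, nested
#' ET ⊆ TC ⊆ WT by construction.
#'
#' @param labelmap integer array with values in \{0, 1, 2, 4\}.
#' @return `region_masks` list with logical arrays `ET`, `TC`, `WT`.
#' @export
brats_regions <- function(labelmap) {
  u <- unique(as.vector(labelmap))
  bad <- setdiff(u, c(0L, 1L, 2L, 4L))
  if (length(bad)) stop("unknown label value(s): ", paste(bad, collapse = ", "))
  structure(list(ET = labelmap == 4L,
                 TC = labelmap == 1L | labelmap == 4L,
                 WT = labelmap == 1L | labelmap == 2L | labelmap == 4L),
            class = "region_masks")
}
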