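#' Multi-channel 3D volume
#'
#' Container for a real-valued rank-4 image tensor laid out as
#' `(channels, height, width, depth)`, optionally carrying the voxel spacing
#' in millimetres. This is the network input type: for multimodal MRI the
#' channels are the co-registered acquisition contrasts (T1, T1ce, T2,
#' FLAIR).
#'
#' @param data numeric array of dimension `(C, H, W, D)`, all values finite.
#' @param spacing numeric length-3 vector, mm per voxel along (H, W, D).
#' @return an object of class `multichannel_volume`.
#' @export
multichannel_volume <- function(data, spacing = c(1, 1, 1)) {
  stopifnot(is.numeric(data), length(dim(data)) == 4L)
  if (!all(is.finite(data))) stop("volume values must be finite")
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "multichannel_volume")
}

#' @export
print.multichannel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<multichannel_volume> %d channel(s), %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], d[4], paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
dim.multichannel_volume <- function(x) dim(x$data)

# ---- internal feature-map representation ------------------------------------
#
# Inside the network a feature map is a plain (V, C) matrix plus its (H, W, D)
# geometry, with voxels rastered depth-fastest (D, then W, then H). That
# raster equals the column-major order of an array with dims (D, W, H), so
# axis folding for attention and separable filtering reduce to dim<-/aperm.

feat <- function(x, dims) {
  stopifnot(is.matrix(x), nrow(x) == prod(dims))
  list(x = x, dims = as.integer(dims))
}

# (C,H,W,D) array -> (V,C) matrix, depth-fastest raster
vol_to_feat <- function(vol) {
  a <- aperm(vol, c(4L, 3L, 2L, 1L))       # (D, W, H, C)
  d <- dim(a)
  dim(a) <- c(d[1] * d[2] * d[3], d[4])
  feat(a, dims = c(d[3], d[2], d[1]))      # dims stored as (H, W, D)
}

feat_to_vol <- function(f, channels = ncol(f$x)) {
  h <- f$dims[1]; w <- f$dims[2]; dd <- f$dims[3]
  a <- f$x
  dim(a) <- c(dd, w, h, channels)
  aperm(a, c(4L, 3L, 2L, 1L))              # (C, H, W, D)
}

# null-default helper
`%||%` <- function(a, b) if (is.null(a)) b else a
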