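#' Orthonormal Haar analysis filter bank
#'
#' Returns the two-tap orthonormal Haar pair: low-pass
#' \eqn{\phi = (1/\sqrt2, 1/\sqrt2)} and high-pass
#' \eqn{\psi = (1/\sqrt2, -1/\sqrt2)}. Under this normalization the
#' single-level 3D transform is an orthogonal map, so energy is conserved
#' (Parseval) and the synthesis transform is the exact adjoint/inverse.
#'
#' @return object of class `filter_bank` with fields `low`, `high`,
#'   `normalization`.
#' @export
haar_analysis_filters <- function() {
  s <- 1 / sqrt(2)
  structure(list(low = c(s, s), high = c(s, -s), normalization = "orthonormal"),
            class = "filter_bank")
}

#' Fixed sub-band ordering of the 3D transform
#'
#' Letters are ordered (height, width, depth); `L`/`H` denote low/high-pass
#' filtering along that axis. The stack is channel-major: all eight bands of
#' input channel 1, then channel 2, and so on.
#' @export
BAND_ORDER <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")

# ---- core transforms on internal (D, W, H, C) arrays ------------------------

# pairwise 2-tap analysis along array dim `ax` (1 = D, 2 = W, 3 = H)
.analysis_pair <- function(a, ax, f) {
  n <- dim(a)[ax]
  if (n %% 2L != 0L) stop("spatial dimension ", n, " along axis ", ax,
                          " is odd; single-level DWT needs even dims")
  odd <- seq(1L, n, 2L); even <- seq(2L, n, 2L)
  idx <- function(i) switch(ax,
    a[i, , , , drop = FALSE], a[, i, , , drop = FALSE], a[, , i, , drop = FALSE])
  list(lo = f$low[1] * idx(odd) + f$low[2] * idx(even),
       hi = f$high[1] * idx(odd) + f$high[2] * idx(even))
}

# synthesis adjoint of .analysis_pair under the same filters
.synthesis_pair <- function(lo, hi, ax, f) {
  dl <- dim(lo)
  dl[ax] <- dl[ax] * 2L
  out <- array(0, dl)
  n <- dl[ax]
  odd <- seq(1L, n, 2L); even <- seq(2L, n, 2L)
  assign_ax <- function(i, v) switch(ax,
    out[i, , , ] <<- v, out[, i, , ] <<- v, out[, , i, ] <<- v)
  assign_ax(odd,  f$low[1] * lo + f$high[1] * hi)
  assign_ax(even, f$low[2] * lo + f$high[2] * hi)
  out
}

# (D, W, H, C) -> (D/2, W/2, H/2, 8C) with channel-major band layout
dwt3_core <- function(a, f = haar_analysis_filters()) {
  d3 <- .analysis_pair(a, 1L, f)                       # along depth
  d2 <- list(L = .analysis_pair(d3$lo, 2L, f), H = .analysis_pair(d3$hi, 2L, f))
  out <- vector("list", 8L)
  i <- 1L
  for (hpart in c("lo", "hi")) for (wpart in c("lo", "hi")) for (dpart in c("L", "H")) {
    wd <- d2[[dpart]][[wpart]]
    # wd is filtered along D (dpart) and W (wpart); now filter along H
    hres <- .analysis_pair(wd, 3L, f)
    out[[i]] <- if (hpart == "lo") hres$lo else hres$hi
    i <- i + 1L
  }
  # out order: (h, w, d) letters with d fastest, w next, h outer == BAND_ORDER
  dl <- dim(out[[1]])
  C <- dl[4]
  res <- array(0, c(dl[1], dl[2], dl[3], 8L * C))
  for (ch in seq_len(C)) for (b in 1:8)
    res[, , , (ch - 1L) * 8L + b] <- out[[b]][, , , ch]
  res
}

# caching note: dwt3_core recomputes the H filtering once per (h,w,d) combo;
# cost is negligible next to the attention stages.

idwt3_core <- function(s, f = haar_analysis_filters()) {
  dl <- dim(s)
  C8 <- dl[4]
  if (C8 %% 8L != 0L) stop("sub-band channel count ", C8, " is not a multiple of 8")
  C <- C8 %/% 8L
  bands <- vector("list", 8L)
  for (b in 1:8) bands[[b]] <- s[, , , (seq_len(C) - 1L) * 8L + b, drop = FALSE]
  # invert along H first (adjoint order is irrelevant for separable orthogonal)
  wd <- vector("list", 4L)  # combos (w, d) after removing H letter
  i <- 1L
  for (w in 1:2) for (d in 1:2) {
    loH <- bands[[(1L - 1L) * 4L + (w - 1L) * 2L + d]]      # h = L
    hiH <- bands[[(2L - 1L) * 4L + (w - 1L) * 2L + d]]      # h = H
    wd[[i]] <- .synthesis_pair(loH, hiH, 3L, f)
    i <- i + 1L
  }
  dL <- .synthesis_pair(wd[[1]], wd[[3]], 2L, f)             # d = L: (wL, wH)
  dH <- .synthesis_pair(wd[[2]], wd[[4]], 2L, f)             # d = H
  .synthesis_pair(dL, dH, 1L, f)
}

# ---- public volume-level API -------------------------------------------------

#' Single-level 3D discrete wavelet transform
#'
#' Decomposes each channel of a volume into its eight Haar sub-bands
#' (separable two-tap filtering with stride-2 decimation over non-overlapping
#' pairs starting at the first voxel), halving every spatial dimension.
#'
#' @param volume a [multichannel_volume()] with even spatial dims.
#' @param filters a `filter_bank`, by default [haar_analysis_filters()].
#' @return a `subband_stack`: list with `data` of dim `(8C, H/2, W/2, D/2)`,
#'   `band_order`, and `source_channels`.
#' @export
dwt3 <- function(volume, filters = haar_analysis_filters()) {
  x <- volume$data
  a <- aperm(x, c(4L, 3L, 2L, 1L))           # (D, W, H, C)
  s <- dwt3_core(a, filters)
  out <- aperm(s, c(4L, 3L, 2L, 1L))          # (8C, H/2, W/2, D/2)
  structure(list(data = out, band_order = BAND_ORDER,
                 source_channels = dim(x)[1], spacing = volume$spacing),
            class = "subband_stack")
}

#' Inverse single-level 3D discrete wavelet transform
#'
#' Exact inverse of [dwt3()] under orthonormal filters.
#'
#' @param subbands a `subband_stack` (channel count divisible by 8).
#' @param filters matching `filter_bank`.
#' @return a [multichannel_volume()].
#' @export
idwt3 <- function(subbands, filters = haar_analysis_filters()) {
  s <- subbands$data
  if (dim(s)[1] %% 8L != 0L)
    stop("sub-band stack must have a channel count divisible by 8")
  a <- aperm(s, c(4L, 3L, 2L, 1L))
  x <- idwt3_core(a, filters)
  multichannel_volume(aperm(x, c(4L, 3L, 2L, 1L)),
                      spacing = subbands$spacing %||% c(1, 1, 1))
}

# ---- filter-bank serialization ----------------------------------------------

#' Serialize the fixed filter bank to a text file
#'
#' The non-learnable analysis filters are frozen to disk so the transform
#' shipped with a trained model is unambiguous. Taps are stored as C99
#' hex-float strings, so a reload reproduces the doubles bit-for-bit; the
#' sub-band ordering is recorded alongside.
#'
#' @param filters a `filter_bank`.
#' @param path output file path (YAML).
#' @export
write_filter_bank <- function(filters, path) {
  obj <- list(
    format = "wiafseg-filter-bank-v1",
    normalization = filters$normalization,
    low_hex = sprintf("%a", filters$low),
    high_hex = sprintf("%a", filters$high),
    band_order = BAND_ORDER
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_filter_bank
#' @export
read_filter_bank <- function(path) {
  obj <- yaml::read_yaml(path)
  stopifnot(identical(obj$format, "wiafseg-filter-bank-v1"))
  hex2d <- function(s) unname(vapply(s, strtoi_hexfloat, numeric(1)))
  structure(list(low = hex2d(obj$low_hex), high = hex2d(obj$high_hex),
                 normalization = obj$normalization),
            class = "filter_bank")
}

# parse a C99 hex float ("0x1.6a09e667f3bcdp-1")
strtoi_hexfloat <- function(s) {
  s <- trimws(s)
  sign <- 1
  if (startsWith(s, "-")) { sign <- -1; s <- substring(s, 2) }
  stopifnot(startsWith(tolower(s), "0x"))
  body <- substring(s, 3)
  parts <- strsplit(body, "p", fixed = TRUE)[[1]]
  expo <- as.integer(parts[2])
  mant <- strsplit(parts[1], ".", fixed = TRUE)[[1]]
  intpart <- strtoi(mant[1], 16L)
  frac <- 0
  if (length(mant) > 1L && nzchar(mant[2])) {
    digs <- strsplit(mant[2], "")[[1]]
    frac <- sum(strtoi(digs, 16L) * 16^(-seq_along(digs)))
  }
  sign * (intpart + frac) * 2^expo
}
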