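# Synthetic multimodal tumor phantoms.
#
# Emulates the geometry and contrast structure of BraTS-style inputs with no
# data download: four co-registered channels over a dark background, an
# ellipsoidal "brain", and a nested tumor (enhancing core, necrotic shell,
# edema rim) rendered with modality-specific intensities plus Gaussian
# noise. Labels follow the BraTS convention {0, 1, 2, 4}.

#' Phantom specification
#'
#' @param grid cube side in voxels (64 for tests, 32 for CPU training).
#' @param brain_frac brain ellipsoid semi-axes as fractions of grid/2.
#' @param wt_frac mean whole-tumor semi-axes as a fraction of the brain
#'   semi-axes (0.37 targets a ~5% tumor/brain volume fraction).
#' @param tc_frac,et_frac tumor-core and enhancing-core semi-axes relative
#'   to the whole tumor; strictly decreasing WT > TC > ET.
#' @param axis_jitter per-axis uniform jitter half-range on the tumor size.
#' @param surface_amp amplitude of the low-order angular surface
#'   perturbation applied to the tumor boundary (avoids trivially learnable
#'   perfect ellipsoids).
#' @param intensities 5x4 matrix of tissue intensities (rows background,
#'   brain, ED, NCR/NET, ET; columns T1, T1ce, T2, FLAIR).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid = 64L,
                         brain_frac = c(0.90, 0.84, 0.80),
                         wt_frac = 0.37,
                         tc_frac = 0.68,
                         et_frac = 0.42,
                         axis_jitter = 0.10,
                         surface_amp = 0.08,
                         intensities = default_intensities(),
                         noise_sd = 0.05) {
  stopifnot(grid >= 16L, grid %% 2L == 0L, wt_frac > 0, tc_frac < 1,
            et_frac < tc_frac, noise_sd >= 0, all(is.finite(intensities)))
  structure(list(grid = as.integer(grid), brain_frac = brain_frac,
                 wt_frac = wt_frac, tc_frac = tc_frac, et_frac = et_frac,
                 axis_jitter = axis_jitter, surface_amp = surface_amp,
                 intensities = intensities, noise_sd = noise_sd),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_intensities <- function() {
  m <- rbind(
    background = c(0.00, 0.00, 0.00, 0.00),
    brain      = c(0.50, 0.50, 0.45, 0.40),
    ED         = c(0.45, 0.45, 0.70, 0.85),   # edema: bright on T2/FLAIR
    NCR_NET    = c(0.30, 0.25, 0.55, 0.60),   # necrotic core: dark on T1ce
    ET         = c(0.55, 0.95, 0.60, 0.65))   # enhancing rim: bright on T1ce
  colnames(m) <- c("t1", "t1ce", "t2", "flair")
  m
}

#' Generate one multimodal tumor phantom
#'
#' Fully determined by `seed`: tumor center, per-axis size jitter and the
#' surface perturbation are drawn from a seeded stream. Labels are nested
#' ET ⊂ TC ⊂ WT (4 = enhancing core, 1 = necrotic shell, 2 = edema rim) on
#' an ellipsoidal brain.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return list with `volume` (a 4-channel [multichannel_volume()]) and
#'   `labels` (integer array).
#' @export
generate_phantom <- function(spec, seed = 1L) {
  set.seed(seed)
  g <- spec$grid
  ctr <- (g + 1) / 2
  brain_semi <- spec$brain_frac * g / 2
  if (any(brain_semi * spec$wt_frac * spec$et_frac * spec$tc_frac < 1))
    stop("degenerate geometry: enhancing core below one voxel")
  co <- seq_len(g) - ctr
  X <- array(rep(co, times = g * g), c(g, g, g))                  # H
  Y <- array(rep(rep(co, each = g), times = g), c(g, g, g))       # W
  Z <- array(rep(co, each = g * g), c(g, g, g))                   # D
  brain <- (X / brain_semi[1])^2 + (Y / brain_semi[2])^2 +
    (Z / brain_semi[3])^2 <= 1
  # tumor geometry
  jit <- stats::runif(3, 1 - spec$axis_jitter, 1 + spec$axis_jitter)
  wt_semi <- brain_semi * spec$wt_frac * jit
  cmax <- brain_semi * 0.45
  tc_ctr <- stats::runif(3, -1, 1) * cmax
  rho <- function(semi) sqrt(((X - tc_ctr[1]) / semi[1])^2 +
                             ((Y - tc_ctr[2]) / semi[2])^2 +
                             ((Z - tc_ctr[3]) / semi[3])^2)
  # low-order angular surface perturbation with random phases
  ph <- stats::runif(6, 0, 2 * pi)
  dx <- X - tc_ctr[1]; dy <- Y - tc_ctr[2]; dz <- Z - tc_ctr[3]
  rr <- sqrt(dx^2 + dy^2 + dz^2) + 1e-9
  th <- acos(pmin(pmax(dz / rr, -1), 1))
  phi <- atan2(dy, dx)
  jfield <- spec$surface_amp * (cos(2 * th + ph[1]) * cos(phi + ph[2]) +
                                  0.5 * cos(3 * th + ph[3]) * cos(2 * phi + ph[4]) +
                                  0.5 * cos(th + ph[5]) * sin(3 * phi + ph[6])) / 2
  wt <- (rho(wt_semi) <= 1 + jfield) & brain
  tc <- (rho(wt_semi * spec$tc_frac) <= 1) & brain
  et <- (rho(wt_semi * spec$et_frac) <= 1) & brain
  labels <- array(0L, c(g, g, g))
  labels[wt] <- 2L          # edema rim
  labels[tc] <- 1L          # necrotic shell
  labels[et] <- 4L          # enhancing core
  # render modalities
  tis <- array(1L, c(g, g, g))                       # background row
  tis[brain] <- 2L
  tis[labels == 2L] <- 3L
  tis[labels == 1L] <- 4L
  tis[labels == 4L] <- 5L
  vol <- array(0, c(4L, g, g, g))
  for (m in 1:4) {
    img <- spec$intensities[tis, m]
    dim(img) <- c(g, g, g)
    vol[m, , , ] <- img + stats::rnorm(g^3, sd = spec$noise_sd)
  }
  list(volume = multichannel_volume(vol), labels = labels, seed = seed)
}

#' Augmentation policy
#'
#' @param flip_prob per-axis flip probability.
#' @param rot_prob rotation probability.
#' @param rot_max_deg rotation half-range in degrees.
#' @param noise_sd additive Gaussian noise on the image channels.
#' @export
augment_policy <- function(flip_prob = 0.3, rot_prob = 0.5,
                           rot_max_deg = 30, noise_sd = 0.02) {
  list(flip_prob = flip_prob, rot_prob = rot_prob,
       rot_max_deg = rot_max_deg, noise_sd = noise_sd)
}

# rotate (volume, labels) by `deg` about principal axis `ax` (1=H, 2=W, 3=D);
# image channels trilinear, labels nearest-neighbour
.rotate_pair <- function(vol, labels, ax, deg) {
  d <- dim(labels)
  ctr <- (d + 1) / 2
  th <- deg * pi / 180
  pl <- setdiff(1:3, ax)
  co1 <- seq_len(d[pl[1]]) - ctr[pl[1]]
  co2 <- seq_len(d[pl[2]]) - ctr[pl[2]]
  G <- expand.grid(u = co1, v = co2)
  su <- G$u * cos(th) - G$v * sin(th) + ctr[pl[1]]
  sv <- G$u * sin(th) + G$v * cos(th) + ctr[pl[2]]
  i0 <- floor(su); j0 <- floor(sv)
  fu <- su - i0; fv <- sv - j0
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  n1 <- d[pl[1]]; n2 <- d[pl[2]]
  inside <- su >= 1 & su <= n1 & sv >= 1 & sv <= n2
  idx <- function(i, j) cl(i, n1) + n1 * (cl(j, n2) - 1)
  w00 <- (1 - fu) * (1 - fv); w10 <- fu * (1 - fv)
  w01 <- (1 - fu) * fv; w11 <- fu * fv
  nn <- idx(round(su), round(sv))
  # process each slice along the rotation axis
  out_v <- vol; out_l <- labels
  perm <- order(c(pl, ax))
  for (k in seq_len(d[ax])) {
    sl <- switch(ax,
                 labels[k, , ], labels[, k, ], labels[, , k])
    lv <- sl[nn]; lv[!inside] <- 0L
    dim(lv) <- dim(sl)
    switch(ax,
           out_l[k, , ] <- lv, out_l[, k, ] <- lv, out_l[, , k] <- lv)
    for (m in seq_len(dim(vol)[1])) {
      im <- switch(ax,
                   vol[m, k, , ], vol[m, , k, ], vol[m, , , k])
      smp <- im[idx(i0, j0)] * w00 + im[idx(i0 + 1, j0)] * w10 +
        im[idx(i0, j0 + 1)] * w01 + im[idx(i0 + 1, j0 + 1)] * w11
      smp[!inside] <- 0
      dim(smp) <- dim(im)
      switch(ax,
             out_v[m, k, , ] <- smp, out_v[m, , k, ] <- smp,
             out_v[m, , , k] <- smp)
    }
  }
  list(vol = out_v, labels = out_l)
}

#' Apply training augmentations
#'
#' Per-axis random flips, a random rotation about one principal axis with
#' trilinear image / nearest-neighbour label resampling, and additive
#' Gaussian noise on the image only, in that order. All randomness comes
#' from the current RNG stream; seed beforehand for reproducibility.
#'
#' @param volume a [multichannel_volume()].
#' @param labels matching integer labelmap.
#' @param policy an [augment_policy()].
#' @return list with augmented `volume` and `labels`.
#' @export
augment <- function(volume, labels, policy = augment_policy()) {
  vol <- volume$data
  for (ax in 1:3) {
    if (stats::runif(1) < policy$flip_prob) {
      ridx <- rev(seq_len(dim(labels)[ax]))
      vol <- switch(ax, vol[, ridx, , , drop = FALSE],
                    vol[, , ridx, , drop = FALSE],
                    vol[, , , ridx, drop = FALSE])
      labels <- switch(ax, labels[ridx, , , drop = FALSE],
                       labels[, ridx, , drop = FALSE],
                       labels[, , ridx, drop = FALSE])
    }
  }
  if (stats::runif(1) < policy$rot_prob) {
    ax <- sample.int(3L, 1L)
    deg <- stats::runif(1, -policy$rot_max_deg, policy$rot_max_deg)
    r <- .rotate_pair(vol, labels, ax, deg)
    vol <- r$vol; labels <- r$labels
  }
  if (policy$noise_sd > 0)
    vol <- vol + stats::rnorm(length(vol), sd = policy$noise_sd)
  list(volume = multichannel_volume(vol, volume$spacing), labels = labels)
}

#' Generate a phantom dataset with manifest and optional NIfTI export
#'
#' Per-case seeds are derived deterministically from the master seed. With
#' `dir` set, cases are written in the BraTS naming convention
#' (`<id>_t1.nii.gz`, `_t1ce`, `_t2`, `_flair`, `_seg`) plus a plain-text
#' manifest. Cases are split train/val/test in `split` proportions (8:1:1
#' by default).
#'
#' @param n number of cases (>= 1).
#' @param spec a [phantom_spec()].
#' @param seed master seed.
#' @param dir optional output directory for NIfTI export.
#' @param split three nonnegative proportions.
#' @return list with `cases` (each: volume, labels, seed, id, split) and
#'   `manifest` (data.frame).
#' @export
generate_dataset <- function(n, spec = phantom_spec(), seed = 1L,
                             dir = NULL, split = c(8, 1, 1)) {
  stopifnot(n >= 1)
  case_seeds <- as.integer((seed * 7919L + seq_len(n) * 104729L) %% .Machine$integer.max)
  nt <- round(n * split[1] / sum(split))
  nv <- round(n * split[2] / sum(split))
  roles <- c(rep("train", nt), rep("val", nv), rep("test", n - nt - nv))
  cases <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(spec, case_seeds[i])
    id <- sprintf("case_%03d", i)
    cases[[i]] <- list(volume = ph$volume, labels = ph$labels,
                       seed = case_seeds[i], id = id, split = roles[i])
    tab <- table(factor(ph$labels, levels = c(0, 1, 2, 4)))
    rows[[i]] <- data.frame(id = id, seed = case_seeds[i], split = roles[i],
                            n_bg = as.integer(tab[1]), n_ncr = as.integer(tab[2]),
                            n_ed = as.integer(tab[3]), n_et = as.integer(tab[4]))
    if (!is.null(dir)) write_case_nifti(cases[[i]], dir)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  list(cases = cases, manifest = manifest)
}

modality_names <- c("t1", "t1ce", "t2", "flair")

write_case_nifti <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in 1:4) {
    img <- case$volume$data[m, , , ]
    RNifti::writeNifti(RNifti::asNifti(img, pixdim = case$volume$spacing),
                       file.path(dir, sprintf("%s_%s.nii.gz", case$id,
                                              modality_names[m])))
  }
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(case$labels),
                                           dim(case$labels))),
                     file.path(dir, sprintf("%s_seg.nii.gz", case$id)))
  invisible(NULL)
}
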