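# Losses, overlap and surface-distance metrics, region composition,
# and the paired statistics.

test_that("dice loss reproduces closed-form overlap cases", {
  y <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0))
  p_perfect <- y
  expect_equal(dice_loss(p_perfect, y, eps = 1e-12), 0, tolerance = 1e-9)
  # disjoint masks of S voxels each -> 1 - eps/(2S + eps)
  p_disjoint <- matrix(c(0, 0, 0, 0, 1, 1, 1, 1))
  S <- 4; eps <- 1e-5
  expect_equal(dice_loss(p_disjoint, y, eps = eps), 1 - eps / (2 * S + eps),
               tolerance = 1e-12)
  # half overlap: 2 of 4 target voxels hit, 2 false positives
  p_half <- matrix(c(1, 1, 0, 0, 1, 1, 0, 0))
  expect_equal(dice_loss(p_half, y, eps = 1e-12), 0.5, tolerance = 1e-9)
})

test_that("cross-entropy reproduces closed forms and clamps safely", {
  expect_equal(ce_loss(matrix(0.5, 6, 1), matrix(rep(c(1, 0), 3))), log(2),
               tolerance = 1e-12)
  expect_equal(ce_loss(matrix(c(0.9, 0.2)), matrix(c(1, 0))),
               -0.5 * (log(0.9) + log(0.8)), tolerance = 1e-9)
  y <- cbind(c(1, 0), c(0, 1))
  expect_equal(ce_loss(y, y), 0, tolerance = 1e-9)
  expect_true(is.finite(ce_loss(matrix(c(0, 1)), matrix(c(1, 0)))))
})

test_that("the compound loss is the stated weighted sum", {
  set.seed(41)
  p <- matrix(runif(20), 10, 2); p <- p / rowSums(p)
  y <- cbind(rbinom(10, 1, 0.5)); y <- cbind(1 - y, y)
  expect_equal(combined_loss(p, y, loss_weights(0, 0.0001)) /
                 0.0001, ce_loss(p, y), tolerance = 1e-9)
  expect_equal(combined_loss(p, y, loss_weights(1, 0)), dice_loss(p, y),
               tolerance = 1e-12)
  w <- loss_weights(1, 1)
  expect_equal(combined_loss(p, y, w),
               dice_loss(p, y, w$eps) + ce_loss(p, y), tolerance = 1e-12)
  expect_error(loss_weights(0, 0))
})

test_that("dice_score handles overlap, disjoint, and empty masks", {
  a <- array(FALSE, c(8, 8, 8)); a[1:2, 1:2, 1:2] <- TRUE
  expect_equal(dice_score(a, a), 1)
  b <- array(FALSE, c(8, 8, 8)); b[5:6, 5:6, 5:6] <- TRUE
  expect_equal(dice_score(a, b), 0)
  shifted <- array(FALSE, c(8, 8, 8)); shifted[2:3, 1:2, 1:2] <- TRUE
  expect_equal(dice_score(a, shifted), 0.5)     # 2x2x2 cubes shifted by 1
  e <- array(FALSE, c(8, 8, 8))
  expect_equal(dice_score(e, e), 1)
  # binary limit identity: dice_score = 1 - dice_loss as eps -> 0
  set.seed(42)
  m1 <- array(runif(64) > 0.5, c(4, 4, 4))
  m2 <- array(runif(64) > 0.5, c(4, 4, 4))
  expect_equal(dice_score(m1, m2),
               1 - dice_loss(matrix(as.numeric(m1)), matrix(as.numeric(m2)),
                             eps = 1e-14), tolerance = 1e-9)
})

test_that("hd95 agrees with the all-pairs oracle and basic geometry", {
  cube <- array(FALSE, c(12, 12, 12)); cube[3:6, 3:6, 3:6] <- TRUE
  expect_equal(hd95(cube, cube), 0)
  shifted <- array(FALSE, c(12, 12, 12)); shifted[6:9, 3:6, 3:6] <- TRUE
  expect_equal(as.numeric(hd95(cube, shifted)), 3.0, tolerance = 1e-12)
  expect_equal(as.numeric(hd95(cube, shifted)), oracle_hd95(cube, shifted),
               tolerance = 1e-12)
  # random blobs against the oracle, including anisotropic spacing
  set.seed(43)
  for (rep in 1:3) {
    a <- array(runif(216) > 0.6, c(6, 6, 6))
    b <- array(runif(216) > 0.6, c(6, 6, 6))
    if (!any(a) || !any(b)) next
    sp <- c(1, 1.5, 2)
    expect_equal(as.numeric(hd95(a, b, sp)), oracle_hd95(a, b, sp),
                 tolerance = 1e-10)
    # symmetry
    expect_equal(as.numeric(hd95(a, b, sp)), as.numeric(hd95(b, a, sp)),
                 tolerance = 1e-12)
  }
})

test_that("hd95 is translation-equivariant and flags empty masks", {
  base <- array(FALSE, c(16, 16, 16)); base[3:5, 3:6, 4:5] <- TRUE
  other <- array(FALSE, c(16, 16, 16)); other[4:6, 4:7, 5:6] <- TRUE
  d0 <- as.numeric(hd95(base, other))
  sh <- function(m, k) {
    out <- array(FALSE, dim(m))
    out[(1 + k):16, , ] <- m[1:(16 - k), , ]
    out
  }
  expect_equal(as.numeric(hd95(sh(base, 3), sh(other, 3))), d0,
               tolerance = 1e-12)
  s <- hd95(array(FALSE, c(4, 4, 4)), base[1:4, 1:4, 1:4])
  expect_true(isTRUE(attr(s, "empty")))
  expect_equal(as.numeric(s), sqrt(3 * 16), tolerance = 1e-12)
})

test_that("BraTS regions nest and count correctly", {
  lm <- array(0L, c(5, 2, 1))
  lm[1:3, 1, 1] <- 1L; lm[1:5, 2, 1] <- 2L; lm[4:5, 1, 1] <- 4L
  r <- brats_regions(lm)
  expect_equal(sum(r$ET), 2)
  expect_equal(sum(r$TC), 5)
  expect_equal(sum(r$WT), 10)
  # single-voxel membership
  one <- array(0L, c(2, 2, 2)); one[1, 1, 1] <- 4L
  r1 <- brats_regions(one)
  expect_true(r1$ET[1, 1, 1] && r1$TC[1, 1, 1] && r1$WT[1, 1, 1])
  one[1, 1, 1] <- 2L
  r2 <- brats_regions(one)
  expect_true(!r2$ET[1, 1, 1] && !r2$TC[1, 1, 1] && r2$WT[1, 1, 1])
  expect_error(brats_regions(array(3L, c(2, 2, 2))), "unknown label")
  # nesting holds for arbitrary valid labelmaps
  set.seed(44)
  for (rep in 1:5) {
    lmr <- array(sample(c(0L, 1L, 2L, 4L), 64, TRUE), c(4, 4, 4))
    rr <- brats_regions(lmr)
    expect_true(all(rr$ET <= rr$TC))
    expect_true(all(rr$TC <= rr$WT))
  }
})

test_that("the loss gradient used in training matches finite differences", {
  set.seed(45)
  V <- 30; K <- 4
  lg <- matrix(rnorm(V * K), V, K)
  y <- diag(K)[sample(1:K, V, TRUE), ]
  r <- wiafseg:::combined_loss_grad(lg, y)
  idx <- sample(length(lg), 12)
  for (i in idx) {
    lp <- lg; lp[i] <- lg[i] + 1e-6
    lm <- lg; lm[i] <- lg[i] - 1e-6
    num <- (combined_loss(wiafseg:::softmax_rows(lp), y) -
              combined_loss(wiafseg:::softmax_rows(lm), y)) / 2e-6
    expect_equal(r$grad[i], num, tolerance = 1e-5)
  }
})

test_that("paired t-test matches the textbook statistic and contracts", {
  a <- c(2, 4, 6, 8); b <- c(1, 2, 3, 4)      # differences 1, 2, 3, 4
  r <- paired_ttest(a, b)
  expect_equal(r$t, 2.5 / (sd(c(1, 2, 3, 4)) / 2), tolerance = 1e-9)
  expect_equal(r$t, 3.873, tolerance = 1e-3)
  # antisymmetry
  r2 <- paired_ttest(b, a)
  expect_equal(r2$t, -r$t, tolerance = 1e-12)
  expect_equal(r2$p, r$p, tolerance = 1e-12)
  # shift invariance
  r3 <- paired_ttest(a + 10, b + 10)
  expect_equal(r3$t, r$t, tolerance = 1e-9)
  # identical vectors degenerate cleanly
  r4 <- paired_ttest(a, a)
  expect_equal(r4$t, 0)
  expect_equal(r4$p, 1)
  expect_true(r4$degenerate)
  expect_error(paired_ttest(1, 1), "at least 2")
})
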