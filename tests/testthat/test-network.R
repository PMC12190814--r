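# Model assembly: shapes, variants, determinism, budgets, gradient flow.

test_that("encoder produces a halving feature pyramid", {
  cfg <- wiaf_desk_config()
  m <- build_wiaf(cfg, seed = 1)
  set.seed(31)
  v <- rand_mcv(4, 32, 32, 32)
  pyr <- encoder_forward(m, v)
  dims <- t(vapply(pyr, function(p) dim(p$data), integer(4)))
  expect_equal(dims[, 1], cfg$stage_channels)
  expect_equal(dims[, 2], c(16L, 8L, 4L, 2L))
  expect_equal(dims[, 3], c(16L, 8L, 4L, 2L))
  expect_equal(dims[, 4], c(16L, 8L, 4L, 2L))
  expect_error(encoder_forward(m, rand_mcv(4, 24, 24, 24)), "divisible by 16")
})

test_that("full forward keeps the input resolution and is deterministic", {
  cfg <- wiaf_desk_config()
  m <- build_wiaf(cfg, seed = 1)
  set.seed(32)
  v <- rand_mcv(4, 32, 32, 32)
  o1 <- wiaf_forward(m, v)
  expect_equal(dim(o1$data), c(4L, 32L, 32L, 32L))
  o2 <- wiaf_forward(m, v)
  expect_identical(o1$data, o2$data)
  # softmax over the class axis sums to one per voxel
  p <- apply(o1$data, c(2, 3, 4), function(z) exp(z - max(z)) / sum(exp(z - max(z))))
  expect_equal(range(apply(p, c(2, 3, 4), sum)), c(1, 1), tolerance = 1e-6)
})

test_that("decoder consumes the pyramid produced by the encoder", {
  cfg <- wiaf_desk_config()
  m <- build_wiaf(cfg, seed = 5)
  set.seed(33)
  v <- rand_mcv(4, 32, 32, 32)
  pyr <- encoder_forward(m, v)
  lg <- msffd_forward(m, pyr)
  expect_equal(dim(lg$data), c(4L, 32L, 32L, 32L))
  expect_equal(lg$data, wiaf_forward(m, v)$data, tolerance = 1e-12)
})

test_that("ablation variants share the input/output contract", {
  cfg <- wiaf_desk_config()
  set.seed(34)
  v <- rand_mcv(4, 32, 32, 32)
  shapes <- lapply(c("full", "B", "B+MSFFD", "B+MSFFD+IAFT"), function(vr) {
    mv <- build_variant(cfg, vr, seed = 2)
    dim(wiaf_forward(mv, v)$data)
  })
  for (s in shapes) expect_equal(s, c(4L, 32L, 32L, 32L))
  # variant "full" is the default model parameter-for-parameter
  m1 <- build_wiaf(cfg, seed = 7)
  m2 <- build_variant(cfg, "full", seed = 7)
  expect_identical(m1$params, m2$params)
})

test_that("parameter counts follow closed forms and are deterministic", {
  # bare channel map m -> n with bias
  lin <- wiafseg:::init_linear(13L, 7L)
  expect_identical(wiafseg:::tree_size(lin), 13 * 7 + 7)
  cfg <- wiaf_desk_config()
  c1 <- count_params(build_wiaf(cfg, seed = 1))
  c2 <- count_params(build_wiaf(cfg, seed = 99))
  expect_identical(c1, c2)           # counts do not depend on the seed
  expect_identical(sum(c1$breakdown), c1$total)
})

test_that("MAC accounting is proportional to spatial volume", {
  cfg <- wiaf_desk_config(variant = "B+MSFFD+IAFT")   # conv stem
  m64 <- count_macs(cfg, c(4L, 64L, 64L, 64L))
  m32 <- count_macs(cfg, c(4L, 32L, 32L, 32L))
  # halving all spatial dims divides every convolution's MACs by 8
  expect_equal(m64$breakdown[["stem"]] / m32$breakdown[["stem"]], 8)
  expect_equal(sum(m64$breakdown), m64$total)
  # a 1x1x1 channel map costs m*n MACs per voxel: the projection term of the
  # wavelet stem is (8*Cin)*c1 per stage-1 voxel
  cfg_full <- wiaf_desk_config()
  a <- count_macs(cfg_full, c(4L, 32L, 32L, 32L))$breakdown[["stem"]]
  want <- 8 * 4 * 32^3 + 2 * 32 * cfg_full$gate_hidden +
    16^3 * 32 * cfg_full$stage_channels[1]
  expect_equal(a, want)
})

test_that("gradients reach every component of the full model", {
  cfg <- wiaf_config(stage_channels = c(4L, 4L, 8L, 8L),
                     blocks_per_stage = c(1L, 1L, 1L, 1L),
                     num_heads = c(2L, 2L, 2L, 2L), gate_hidden = 5L,
                     decoder = list(align_width = 4L, fuse_width = 4L,
                                    head_width = 4L, se_hidden = c(2L, 2L, 2L, 2L),
                                    num_heads = 2L))
  m <- build_wiaf(cfg, seed = 8)
  set.seed(35)
  m$params <- randomize_tree(m$params)     # break zero-initialized branches
  f <- wiafseg:::vol_to_feat(array(rnorm(4 * 16^3), c(4, 16, 16, 16)))
  fw <- wiafseg:::wiaf_fwd_feat(m, f, need_grad = TRUE)
  dl <- matrix(rnorm(length(fw$out$x)), nrow(fw$out$x), ncol(fw$out$x))
  gr <- wiafseg:::wiaf_bwd(m, fw, dl)
  expect_gt(wiafseg:::tree_max_abs(gr$stem), 0)
  for (s in 1:4) expect_gt(wiafseg:::tree_max_abs(gr$stages[[s]]), 0)
  expect_gt(wiafseg:::tree_max_abs(gr$decoder), 0)
  # the analytic gradient agrees with finite differences on sampled leaves
  lossfn <- function(mm) sum(wiafseg:::wiaf_fwd_feat(mm, f, need_grad = FALSE)$out$x * dl)
  w <- m$params$stages[[3]]$down$W
  i <- sample(length(w), 1)
  mp <- m; mp$params$stages[[3]]$down$W[i] <- w[i] + 1e-5
  mm2 <- m; mm2$params$stages[[3]]$down$W[i] <- w[i] - 1e-5
  num <- (lossfn(mp) - lossfn(mm2)) / 2e-5
  expect_equal(gr$stages[[3]]$down$W[i], num, tolerance = 1e-4)
})

test_that("the frozen reference configuration reloads consistently", {
  cfg <- wiaf_reference_config()
  expect_s3_class(cfg, "wiaf_config")
  expect_equal(cfg$stage_channels, c(8L, 32L, 96L, 288L))
  df <- summarize_model(wiaf_desk_config(), c(4L, 32L, 32L, 32L))
  expect_identical(df$component[nrow(df)], "total")
  expect_identical(df, summarize_model(wiaf_desk_config(), c(4L, 32L, 32L, 32L)))
})
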