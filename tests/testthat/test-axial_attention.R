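# Axial factorized attention: folding, per-axis attention, iterative
# aggregation, the dense baseline, and the complexity accounting.

make_tokens <- function(dims, C, seed = 1) {
  set.seed(seed)
  token_sequence(array(rnorm(prod(dims) * C), c(1L, prod(dims), C)), dims)
}

test_that("axis folding produces axis-major batches and round-trips", {
  tk <- make_tokens(c(2, 3, 4), 5)
  fH <- fold_axis(tk, "H")
  expect_equal(dim(fH), c(12L, 2L, 5L))     # (W*D, H, C)
  fD <- fold_axis(tk, "D")
  expect_equal(dim(fD), c(6L, 4L, 5L))      # (H*W, D, C)
  for (ax in c("H", "W", "D")) {
    back <- unfold_axis(fold_axis(tk, ax), tk$dims, ax)
    expect_equal(back$data, tk$data)
  }
  expect_error(fold_axis(tk, "Q"), "axis")
})

test_that("axial attention matches the hand-rolled dense oracle", {
  set.seed(21)
  for (case in list(c(3, 4, 1), c(8, 6, 2), c(5, 8, 4))) {
    L <- case[1]; C <- case[2]; heads <- case[3]
    p <- wiafseg:::init_attn(C)
    p$Wo <- wiafseg:::init_linear(C, C)     # oracle needs a nontrivial output map
    x <- matrix(rnorm(L * C), L, C)
    zb <- array(x, c(1L, L, C))
    got <- axial_mhsa(zb, p, heads)
    expect_equal(matrix(got[1, , ], L, C), oracle_dense_attention(x, p, heads),
                 tolerance = 1e-6)
  }
})

test_that("length-1 sequences reduce to the value-projection path", {
  set.seed(22)
  C <- 6
  p <- wiafseg:::init_attn(C)
  p$Wo <- wiafseg:::init_linear(C, C)
  x <- matrix(rnorm(3 * C), 3, C)           # batch of 3 singleton sequences
  zb <- array(x, c(3L, 1L, C))
  got <- axial_mhsa(zb, p, 2L)
  want <- wiafseg:::linear_fwd(p$Wo, wiafseg:::linear_fwd(p$Wv, x))
  expect_equal(matrix(got[, 1, ], 3, C), want, tolerance = 1e-10)
})

test_that("constant values collapse attention to that value row", {
  set.seed(23)
  C <- 4; L <- 7
  p <- wiafseg:::init_attn(C)
  p$Wv$W <- matrix(0, C, C); p$Wv$b <- rnorm(C)   # V identical at every position
  zb <- array(rnorm(L * C), c(1L, L, C))
  got <- axial_mhsa(zb, p, 2L)
  rows <- matrix(got[1, , ], L, C)
  for (i in 2:L) expect_equal(rows[i, ], rows[1, ], tolerance = 1e-10)
})

test_that("zero value projections make iaf_attention the identity", {
  set.seed(24)
  C <- 6
  p <- list(axes = list(H = wiafseg:::init_attn(C), W = wiafseg:::init_attn(C),
                        D = wiafseg:::init_attn(C)))
  for (ax in names(p$axes)) {
    p$axes[[ax]]$Wv$W[] <- 0; p$axes[[ax]]$Wv$b[] <- 0
    p$axes[[ax]]$Wo$b[] <- 0
  }
  tk <- make_tokens(c(2, 2, 4), C, seed = 24)
  out <- iaf_attention(tk, p, num_heads = 2L)
  expect_identical(out$data, tk$data)
})

test_that("sequential and summed aggregation are genuinely different", {
  set.seed(25)
  C <- 6
  p <- list(axes = list(H = wiafseg:::init_attn(C), W = wiafseg:::init_attn(C),
                        D = wiafseg:::init_attn(C)))
  for (ax in names(p$axes)) p$axes[[ax]]$Wo <- wiafseg:::init_linear(C, C)
  tk <- make_tokens(c(3, 3, 3), C, seed = 25)
  o_seq <- iaf_attention(tk, p, 2L, mode = "sequential")
  o_sum <- iaf_attention(tk, p, 2L, mode = "summed")
  expect_gt(max(abs(o_seq$data - o_sum$data)), 0)
})

test_that("degenerate (1,1,L) grids equal the dense-attention path", {
  set.seed(26)
  C <- 6; L <- 9
  p <- list(axes = list(H = wiafseg:::init_attn(C), W = wiafseg:::init_attn(C),
                        D = wiafseg:::init_attn(C)))
  p$axes$D$Wo <- wiafseg:::init_linear(C, C)
  # singleton-axis passes are disabled by zero value/output branches
  for (ax in c("H", "W")) {
    p$axes[[ax]]$Wv$W[] <- 0; p$axes[[ax]]$Wv$b[] <- 0; p$axes[[ax]]$Wo$b[] <- 0
  }
  tk <- make_tokens(c(1, 1, L), C, seed = 26)
  got <- iaf_attention(tk, p, 2L)
  dense <- full_mhsa_oracle(tk, p$axes$D, 2L)
  want <- tk$data + wiafseg:::silu(dense$data)
  expect_equal(got$data, want, tolerance = 1e-6)
})

test_that("softmax rows are a convex combination (weights sum to one)", {
  set.seed(27)
  S <- matrix(rnorm(40), 8, 5)
  A <- wiafseg:::softmax_rows(S)
  expect_equal(rowSums(A), rep(1, 8), tolerance = 1e-6)
  expect_true(all(A >= 0))
})

test_that("iaft_block is a residual identity under zero branch weights", {
  C <- 6
  p <- wiafseg:::init_iaft_block(C, 2)
  for (ax in names(p$attn$axes)) {
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      p$attn$axes[[ax]][[nm]]$W[] <- 0
      p$attn$axes[[ax]][[nm]]$b[] <- 0
    }
  }
  p$mlp$W1$W[] <- 0; p$mlp$W1$b[] <- 0; p$mlp$W2$W[] <- 0; p$mlp$W2$b[] <- 0
  tk <- make_tokens(c(2, 3, 2), C, seed = 28)
  out <- iaft_block(tk, p, 2L)
  expect_equal(out$data, tk$data, tolerance = 1e-12)
})

test_that("iaft_block preserves shape, stays finite, and is deterministic", {
  set.seed(29)
  C <- 8
  p <- wiafseg:::init_iaft_block(C, 2)
  for (seed in 1:3) {
    tk <- make_tokens(c(4, 2, 4), C, seed = 100 + seed)
    o1 <- iaft_block(tk, p, 2L)
    expect_equal(dim(o1$data), dim(tk$data))
    expect_true(all(is.finite(o1$data)))
    o2 <- iaft_block(tk, p, 2L)
    expect_identical(o1$data, o2$data)
  }
})

test_that("dense oracle is permutation-equivariant and guarded", {
  set.seed(30)
  C <- 4; L <- 6
  p <- wiafseg:::init_attn(C)
  p$Wo <- wiafseg:::init_linear(C, C)
  tk <- make_tokens(c(1, 1, L), C, seed = 30)
  out <- full_mhsa_oracle(tk, p, 2L)
  perm <- sample(L)
  tkp <- token_sequence(tk$data[, perm, , drop = FALSE], tk$dims)
  outp <- full_mhsa_oracle(tkp, p, 2L)
  expect_equal(outp$data[1, , ], out$data[1, perm, ], tolerance = 1e-10)
  big <- token_sequence(array(0, c(1, 8, C)), c(2, 2, 2))
  expect_error(full_mhsa_oracle(big, p, 2L, max_tokens = 4L), "guard")
})

test_that("MAC accounting scales as N^{4/3} axial and N^2 full", {
  r8 <- attention_mac_count(c(8, 8, 8), 16, 4, "axial")$score_value
  r16 <- attention_mac_count(c(16, 16, 16), 16, 4, "axial")$score_value
  expect_equal(r16 / r8, 16)
  f8 <- attention_mac_count(c(8, 8, 8), 16, 4, "full")$score_value
  f16 <- attention_mac_count(c(16, 16, 16), 16, 4, "full")$score_value
  expect_equal(f16 / f8, 64)
  # degenerate single-axis grids coincide with full attention
  ax <- attention_mac_count(c(1, 1, 32), 16, 4, "axial")
  fu <- attention_mac_count(c(1, 1, 32), 16, 4, "full")
  expect_equal(ax$score_value, fu$score_value)
  expect_equal(ax$projections, fu$projections)
})
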