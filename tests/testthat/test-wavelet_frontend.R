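# Wavelet front end: Haar analysis/synthesis, sub-band gating, AWD-FD stem.

test_that("Haar filter bank is orthonormal", {
  fb <- haar_analysis_filters()
  expect_equal(fb$low, c(1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(fb$high, c(1, -1) / sqrt(2), tolerance = 1e-12)
  expect_equal(sum(fb$low^2), 1, tolerance = 1e-12)
  expect_equal(sum(fb$high^2), 1, tolerance = 1e-12)
  expect_equal(sum(fb$low * fb$high), 0, tolerance = 1e-12)
})

test_that("dwt3 reproduces closed-form constant and impulse cases", {
  vc <- multichannel_volume(array(1, c(1, 2, 2, 2)))
  sc <- dwt3(vc)
  expect_equal(dim(sc$data), c(8L, 1L, 1L, 1L))
  expect_equal(sc$data[1, 1, 1, 1], 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(max(abs(sc$data[2:8, 1, 1, 1])), 0, tolerance = 1e-12)

  vi <- multichannel_volume(array(c(1, rep(0, 7)), c(1, 2, 2, 2)))
  si <- dwt3(vi)
  oracle <- oracle_dwt3(vi$data)
  expect_equal(abs(si$data[, 1, 1, 1]), rep((1 / sqrt(2))^3, 8),
               tolerance = 1e-12)
  expect_equal(si$data, oracle, tolerance = 1e-12)
})

test_that("dwt3 separates directional structure into the right bands", {
  # a ramp along height only excites height-high-pass bands (H??)
  v <- array(0, c(1, 4, 4, 4))
  for (h in 1:4) v[1, h, , ] <- h
  s <- dwt3(multichannel_volume(v))
  en <- vapply(1:8, function(b) sum(s$data[b, , , ]^2), numeric(1))
  names(en) <- BAND_ORDER
  expect_gt(en["LLL"], 0)
  expect_gt(en["HLL"], 0)
  expect_equal(unname(en[c("LLH", "LHL", "LHH", "HLH", "HHL", "HHH")]),
               rep(0, 6), tolerance = 1e-12)
})

test_that("dwt3 matches the direct filter-bank oracle on random volumes", {
  set.seed(11)
  for (shape in list(c(1, 2, 2, 2), c(2, 4, 4, 4), c(1, 4, 6, 2))) {
    v <- rand_mcv(shape[1], shape[2], shape[3], shape[4])
    expect_equal(dwt3(v)$data, oracle_dwt3(v$data), tolerance = 1e-10)
  }
})

test_that("transform conserves energy and inverts exactly", {
  set.seed(12)
  v <- rand_mcv(2, 4, 4, 4)
  s <- dwt3(v)
  expect_equal(sum(s$data^2), sum(v$data^2),
               tolerance = 1e-6)
  expect_equal(idwt3(s)$data, v$data, tolerance = 1e-6)
  # all-zero stack inverts to all zeros
  s$data[] <- 0
  expect_equal(max(abs(idwt3(s)$data)), 0)
})

test_that("a unit LLL coefficient reconstructs a constant 2x2x2 block", {
  s <- dwt3(multichannel_volume(array(0, c(1, 4, 4, 4))))
  s$data[1, 1, 1, 1] <- 1           # LLL of channel 1, first block
  r <- idwt3(s)
  expect_equal(r$data[1, 1:2, 1:2, 1:2], array(1 / (2 * sqrt(2)), c(2, 2, 2)),
               tolerance = 1e-12)
  expect_equal(sum(abs(r$data)), 8 / (2 * sqrt(2)), tolerance = 1e-12)
})

test_that("malformed inputs raise dimension errors", {
  expect_error(dwt3(multichannel_volume(array(0, c(1, 3, 4, 4)))), "odd")
  bad <- structure(list(data = array(0, c(7, 2, 2, 2))),
                   class = "subband_stack")
  expect_error(idwt3(bad), "divisible by 8")
})

test_that("serialized filter bank reloads to bit-identical transforms", {
  fb <- haar_analysis_filters()
  path <- tempfile(fileext = ".yaml")
  write_filter_bank(fb, path)
  fb2 <- read_filter_bank(path)
  expect_identical(fb$low, fb2$low)
  expect_identical(fb$high, fb2$high)
  set.seed(13)
  v <- rand_mcv(1, 4, 4, 4)
  expect_identical(dwt3(v, fb)$data, dwt3(v, fb2)$data)
})

test_that("gate weights behave as a sigmoid channel gate", {
  set.seed(14)
  v <- rand_mcv(1, 4, 4, 4)
  s <- dwt3(v)
  gp <- init_gate_params(8L, 4L, seed = 1)
  w <- gate_weights(s, gp)
  expect_length(w, 8L)
  expect_true(all(w > 0 & w < 1))
  # zero parameters give exactly 0.5 everywhere
  gp0 <- gp
  gp0$W1$W[] <- 0; gp0$W1$b[] <- 0; gp0$W2$W[] <- 0; gp0$W2$b[] <- 0
  expect_equal(gate_weights(s, gp0), rep(0.5, 8))
  # GAP makes the gate invariant to spatial permutation
  sp <- s
  perm <- sample(prod(dim(s$data)[2:4]))
  for (ch in 1:8) {
    flat <- as.vector(s$data[ch, , , ])
    sp$data[ch, , , ] <- array(flat[perm], dim(s$data)[2:4])
  }
  expect_equal(gate_weights(sp, gp), w, tolerance = 1e-12)
})

test_that("recalibration scales channels exactly", {
  set.seed(15)
  s <- dwt3(rand_mcv(1, 4, 4, 4))
  expect_equal(recalibrate(s, rep(1, 8))$data, s$data)
  expect_equal(max(abs(recalibrate(s, rep(0, 8))$data)), 0)
  # two-channel mean example
  st <- structure(list(data = array(c(1, 2), c(2, 2, 2, 2))),
                  class = "subband_stack")
  st$data[1, , , ] <- 1; st$data[2, , , ] <- 2
  r <- recalibrate(st, c(0.25, 0.5))
  expect_equal(mean(r$data[1, , , ]), 0.25)
  expect_equal(mean(r$data[2, , , ]), 1.0)
  expect_error(recalibrate(s, c(1, 2)), "does not match")
})

test_that("awdfd_forward halves resolution and is zero on zero input", {
  set.seed(16)
  gate <- init_gate_params(32L, 8L)
  proj <- wiafseg:::init_linear(32L, 8L)
  v <- rand_mcv(4, 8, 8, 8)
  out <- awdfd_forward(v, gate, proj)
  expect_equal(dim(out$data), c(8L, 4L, 4L, 4L))
  z <- multichannel_volume(array(0, c(4, 8, 8, 8)))
  outz <- awdfd_forward(z, gate, proj)   # projection bias is zero at init
  expect_equal(max(abs(outz$data)), 0)
})

test_that("stem parameter count equals the full-vs-conv-stem ablation delta", {
  cfg <- wiaf_desk_config()
  m_full <- build_wiaf(cfg, seed = 1)
  m_v3 <- build_variant(cfg, "B+MSFFD+IAFT", seed = 1)
  delta <- count_params(m_full)$total - count_params(m_v3)$total
  learnable_stem <- wiafseg:::tree_size(m_full$params$stem)
  conv_stem <- wiafseg:::tree_size(m_v3$params$stem)
  expect_identical(delta, learnable_stem - conv_stem)
})
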