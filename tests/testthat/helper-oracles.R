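# Brute-force oracles and small utilities shared across the test files.
# The oracles are deliberately naive (explicit loops, no reuse of the
# package's separable/vectorized paths).

# direct 8-filter 3D wavelet analysis: every output coefficient is an
# explicit sum over a 2x2x2 neighbourhood weighted by the tap products
oracle_dwt3 <- function(vol, fb = haar_analysis_filters()) {
  d <- dim(vol)
  C <- d[1]; H <- d[2]; W <- d[3]; D <- d[4]
  out <- array(0, c(8L * C, H / 2, W / 2, D / 2))
  pick <- function(sel) if (sel) fb$high else fb$low
  for (ch in seq_len(C)) for (b in 1:8) {
    hs <- (b - 1) %/% 4; ws <- ((b - 1) %/% 2) %% 2; ds <- (b - 1) %% 2
    fh <- pick(hs == 1); fw <- pick(ws == 1); fd <- pick(ds == 1)
    for (i in seq_len(H / 2)) for (j in seq_len(W / 2)) for (k in seq_len(D / 2)) {
      acc <- 0
      for (a in 0:1) for (bb in 0:1) for (cc in 0:1)
        acc <- acc + fh[a + 1] * fw[bb + 1] * fd[cc + 1] *
          vol[ch, 2 * i - 1 + a, 2 * j - 1 + bb, 2 * k - 1 + cc]
      out[(ch - 1) * 8 + b, i, j, k] <- acc
    }
  }
  out
}

# hand-rolled dense multi-head attention on a single (L, C) sequence
oracle_dense_attention <- function(x, p, heads) {
  L <- nrow(x); C <- ncol(x); ch <- C / heads
  Q <- x %*% p$Wq$W + rep(p$Wq$b, each = L)
  K <- x %*% p$Wk$W + rep(p$Wk$b, each = L)
  V <- x %*% p$Wv$W + rep(p$Wv$b, each = L)
  O <- matrix(0, L, C)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * ch + 1):(h * ch)
    S <- matrix(0, L, L)
    for (i in seq_len(L)) for (j in seq_len(L))
      S[i, j] <- sum(Q[i, cols] * K[j, cols]) / sqrt(ch)
    for (i in seq_len(L)) {
      e <- exp(S[i, ] - max(S[i, ]))
      a <- e / sum(e)
      O[i, cols] <- colSums(a * V[, cols, drop = FALSE])
    }
  }
  O %*% p$Wo$W + rep(p$Wo$b, each = L)
}

# all-pairs directed surface distance oracle (no chunking, plain loops)
oracle_hd95 <- function(a, b, spacing = c(1, 1, 1)) {
  surf <- function(m) {
    d <- dim(m)
    co <- which(m, arr.ind = TRUE)
    keep <- logical(nrow(co))
    for (r in seq_len(nrow(co))) {
      p <- co[r, ]
      on_surface <- FALSE
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        q <- p; q[ax] <- q[ax] + s
        if (any(q < 1L) || any(q > d)) on_surface <- TRUE
        else if (!m[q[1], q[2], q[3]]) on_surface <- TRUE
      }
      keep[r] <- on_surface
    }
    sweep(co[keep, , drop = FALSE], 2L, spacing, `*`)
  }
  A <- surf(a); B <- surf(b)
  dmin <- function(P, Q) {
    out <- numeric(nrow(P))
    for (i in seq_len(nrow(P)))
      out[i] <- sqrt(min(colSums((t(Q) - P[i, ])^2)))
    out
  }
  unname(stats::quantile(c(dmin(A, B), dmin(B, A)), 0.95, type = 7))
}

rand_mcv <- function(C, H, W, D) {
  multichannel_volume(array(stats::rnorm(C * H * W * D), c(C, H, W, D)))
}

# fill every numeric leaf of a parameter tree with small random values
randomize_tree <- function(tree) {
  wiafseg:::tree_map(function(x) {
    x[] <- stats::rnorm(length(x), sd = 0.05)
    x
  }, tree)
}
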