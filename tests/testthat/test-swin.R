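# Backbone operations: patch partition/merge/expand, windowed and
# shifted-window attention against brute-force dense oracles, block
# structure, stage shape laws and the attention cost formula.

set.seed(7)

test_that("patch partition flattens raw patches with the documented order", {
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  pp <- patch_partition(img, patch_size = 4L)
  expect_equal(dim(pp$values), c(4L, 48L))
  expect_equal(pp$h, 2L)
  expect_equal(pp$w, 2L)
  # independent extraction: token (r, c), feature (ch, dy, dx)
  expected <- matrix(0, 4, 48)
  t_i <- 0L
  for (r in 1:2) for (c in 1:2) {
    t_i <- t_i + 1L
    for (ch in 1:3) for (dy in 0:3) for (dx in 0:3) {
      j <- (ch - 1) * 16 + dy * 4 + dx + 1
      expected[t_i, j] <- img[(r - 1) * 4 + dy + 1, (c - 1) * 4 + dx + 1, ch]
    }
  }
  expect_equal(pp$values, expected)

  const_img <- array(0.5, c(8, 8, 3))
  ppc <- patch_partition(const_img, 4L)
  expect_true(all(apply(ppc$values, 2, function(x) length(unique(x)) == 1L)))
})

test_that("patch merging follows the gather-concat-normalise-project law", {
  # shape law: 4x4x8 -> 2x2x16
  fm <- list(values = matrix(rnorm(16 * 8), 16, 8), h = 4L, w = 4L)
  W <- matrix(rnorm(32 * 16, sd = 0.1), 32, 16)
  mg <- patch_merge(fm, W)
  expect_equal(c(mg$h, mg$w, ncol(mg$values)), c(2L, 2L, 16L))

  # 2x2x1 toy against a hand computation
  v <- matrix(c(1, 2, 3, 4), 4, 1)  # tokens (1,1),(1,2),(2,1),(2,2)
  fm1 <- list(values = v, h = 2L, w = 2L)
  W1 <- matrix(rnorm(8), 4, 2)
  out <- patch_merge(fm1, W1)
  gat <- c(1, 2, 3, 4)              # TL, TR, BL, BR of the only 2x2 block
  ln <- (gat - mean(gat)) / sqrt(mean((gat - mean(gat))^2) + 1e-5)
  expect_equal(as.vector(out$values), as.vector(ln %*% W1), tolerance = 1e-10)

  # two successive merges on an H/4 grid give a stride-16 map
  fm2 <- patch_merge(patch_merge(fm, W), matrix(rnorm(64 * 32, sd = .1), 64, 32))
  expect_equal(c(fm2$h, fm2$w, ncol(fm2$values)), c(1L, 1L, 32L))
})

test_that("patch expanding rearranges channel quarters into 2x2 blocks", {
  fm <- list(values = matrix(rnorm(4 * 16), 4, 16), h = 2L, w = 2L)
  ex <- patch_expand(fm, matrix(rnorm(16 * 32, sd = 0.1), 16, 32))
  expect_equal(c(ex$h, ex$w, ncol(ex$values)), c(4L, 4L, 8L))

  # 1x1x4 toy with an identity-like map: channel quarter q of the 2c
  # vector becomes spatial offset (TL, TR, BL, BR)
  fm1 <- list(values = matrix(1:4, 1, 4), h = 1L, w = 1L)
  W <- diag(8)[1:4, ] * 2     # z = 2 * (x1..x4, 0, 0, 0, 0)
  out <- patch_expand(fm1, W)
  expect_equal(c(out$h, out$w, ncol(out$values)), c(2L, 2L, 2L))
  z <- as.vector(fm1$values %*% W)   # length 8, quarters of size 2
  expected <- rbind(z[1:2], z[3:4], z[5:6], z[7:8])  # TL,TR,BL,BR rows
  expect_equal(out$values, expected)

  # expand then merge preserves spatial dims
  W2 <- matrix(rnorm(8 * 4, sd = 0.1), 8, 4)
  back <- patch_merge(patch_expand(fm, matrix(rnorm(16 * 32, sd = .1), 16, 32)),
                      matrix(rnorm(32 * 16, sd = .1), 32, 16))
  expect_equal(c(back$h, back$w), c(fm$h, fm$w))
})

test_that("W-MSA on a single window equals brute-force dense attention", {
  M <- 4L
  C <- 4L
  heads <- 2L
  fm <- list(values = matrix(rnorm(16 * C), 16, C), h = M, w = M)
  wts <- rand_block_wts(C, M, heads)
  got <- window_attention(fm, wts, M, heads = heads)

  rel <- ix_relpos(M)
  bias <- lapply(seq_len(heads), function(h) matrix(wts$bias[rel, h], 16, 16))
  # single window: window-major token order equals row-major order
  ora <- dense_attention_oracle(fm$values, wts$qkv.W, wts$qkv.b, heads, bias)
  ora <- sweep(ora %*% wts$proj.W, 2, wts$proj.b, "+")
  expect_equal(got$values, ora, tolerance = 1e-5)
})

test_that("all-equal Q and K with zero bias give the projected window mean of V", {
  M <- 2L
  C <- 4L
  wts <- rand_block_wts(C, M, 1L, zero_bias_tab = TRUE)
  wts$qkv.W[, 1:(2 * C)] <- 0        # Q and K identically zero
  wts$qkv.b[1:(2 * C)] <- 0
  fm <- list(values = matrix(rnorm(16 * C), 16, C), h = 4L, w = 4L)
  got <- window_attention(fm, wts, M, heads = 1L)

  V <- sweep(fm$values %*% wts$qkv.W[, 2 * C + 1:C], 2,
             wts$qkv.b[2 * C + 1:C], "+")
  iw <- ix_window(4L, 4L, M)
  meanV <- matrix(0, 16, C)
  for (wi in seq_len(iw$nwin)) {
    rows <- iw$perm[(wi - 1) * 4 + 1:4]
    meanV[rows, ] <- matrix(colMeans(V[rows, , drop = FALSE]), 4, C, byrow = TRUE)
  }
  expected <- sweep(meanV %*% wts$proj.W, 2, wts$proj.b, "+")
  expect_equal(got$values, expected, tolerance = 1e-10)
})

test_that("cyclic shift composed with its inverse restores the grid", {
  for (hw in list(c(8L, 8L), c(6L, 10L))) {
    sh <- ix_shift(hw[1], hw[2], 2L)
    inv <- integer(length(sh))
    inv[sh] <- seq_along(sh)
    x <- matrix(rnorm(prod(hw) * 3), prod(hw), 3)
    expect_identical(x[sh, ][inv, ], x)
  }
})

test_that("SW-MSA equals dense attention restricted to pre-shift regions", {
  M <- 4L
  s <- M %/% 2L
  h <- w <- 2L * M
  C <- 4L
  heads <- 2L
  fm <- list(values = matrix(rnorm(h * w * C), h * w, C), h = h, w = w)
  wts <- rand_block_wts(C, M, heads, zero_bias_tab = TRUE)
  got <- shifted_window_attention(fm, wts, M, heads = heads)

  # combinatorial structure, built independently: region from original
  # coordinates (slices at h-M and h-s), window from shifted coordinates
  r <- rep(seq_len(h), each = w)
  c <- rep(seq_len(w), times = h)
  reg1 <- function(v, n) ifelse(v - 1 < n - M, 0L, ifelse(v - 1 < n - s, 1L, 2L))
  region <- reg1(r, h) * 3L + reg1(c, w)
  sr <- ((r - 1 - s) %% h) + 1       # position after shifting content up-left
  sc <- ((c - 1 - s) %% w) + 1
  win <- (ceiling(sr / M) - 1) * (w / M) + ceiling(sc / M)
  allowed <- outer(win, win, "==") & outer(region, region, "==")

  ora <- dense_attention_oracle(fm$values, wts$qkv.W, wts$qkv.b, heads,
                                allowed = allowed)
  ora <- sweep(ora %*% wts$proj.W, 2, wts$proj.b, "+")
  expect_equal(got$values, ora, tolerance = 1e-5)
})

test_that("shift masks allow exactly the pre-shift-contiguous token pairs", {
  for (M in c(2L, 4L)) {
    s <- M %/% 2L
    h <- w <- 2L * M
    ia <- ix_attn(h, w, M, s)
    r <- rep(seq_len(h), each = w)
    c <- rep(seq_len(w), times = h)
    reg1 <- function(v, n) ifelse(v - 1 < n - M, 0L, ifelse(v - 1 < n - s, 1L, 2L))
    region <- reg1(r, h) * 3L + reg1(c, w)
    for (wi in seq_len(ia$nwin)) {
      rows <- ia$fwd[(wi - 1) * ia$ntok + 1:ia$ntok]   # original token ids
      expect_true(all(rows > 0))
      rg <- region[rows]
      expect_identical(ia$masks[[wi]] == 0, outer(rg, rg, "=="))
    }
  }
})

test_that("a transformer block with zeroed projections is the identity", {
  C <- 4L
  M <- 2L
  wts <- rand_block_wts(C, M, 1L)
  wts$proj.W[] <- 0; wts$proj.b[] <- 0
  wts$mlp.W2[] <- 0; wts$mlp.b2[] <- 0
  fm <- list(values = matrix(rnorm(24 * C), 24, C), h = 4L, w = 6L)
  out <- swin_block_apply(fm, wts, M, heads = 1L)
  expect_equal(out$values, fm$values)
})

test_that("block pairs preserve shape (including non-divisible, padded grids)", {
  C <- 4L
  M <- 4L
  wts1 <- rand_block_wts(C, M, 2L)
  wts2 <- rand_block_wts(C, M, 2L)
  for (hw in list(c(8L, 8L), c(6L, 10L))) {
    fm <- list(values = matrix(rnorm(prod(hw) * C), prod(hw), C),
               h = hw[1], w = hw[2])
    out <- swin_block_pair(fm, wts1, wts2, M, heads = 2L)
    expect_equal(dim(out$values), dim(fm$values))
    # pair == sequential composition of the two sub-blocks
    step <- swin_block_apply(fm, wts1, M, heads = 2L, shift = 0L)
    step <- swin_block_apply(step, wts2, M, heads = 2L, shift = M %/% 2L)
    expect_equal(out$values, step$values)
  }
})

test_that("backbone stage outputs follow the resolution/channel law", {
  cfg <- swin_config(patch_size = 4L, channels = 8L, depths = c(1L, 1L, 1L, 1L),
                     window = 2L, heads = c(1L, 2L, 4L, 8L), mlp_ratio = 2)
  prm <- swin_init_params(cfg)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  us <- run_backbone(img, prm, cfg)
  expect_equal(vapply(us, function(u) u$h, 0L), c(U1 = 16L, U2 = 8L, U3 = 4L, U4 = 2L))
  expect_equal(vapply(us, function(u) ncol(u$values), 0L),
               c(U1 = 8L, U2 = 16L, U3 = 32L, U4 = 64L))
  expect_equal(vapply(us, function(u) u$stride, 0L),
               c(U1 = 4L, U2 = 8L, U3 = 16L, U4 = 32L))
  # deterministic given fixed parameters and input
  us2 <- run_backbone(img, prm, cfg)
  expect_identical(us$U4$values, us2$U4$values)
})

test_that("parameter count is a pure function of the configuration", {
  n1 <- sum(vapply(swin_init_params(swin_config_tiny()), length, 0))
  n2 <- sum(vapply(swin_init_params(swin_config_tiny()), length, 0))
  expect_identical(n1, n2)
  cfgA <- swin_config(channels = 8L, depths = c(1L, 1L, 1L, 1L), window = 2L,
                      heads = c(1L, 2L, 4L, 8L), mlp_ratio = 2)
  nA <- sum(vapply(swin_init_params(cfgA), length, 0))
  expect_gt(n1, nA)
})

test_that("the W-MSA cost formula evaluates and scales as stated", {
  expect_equal(wmsa_cost(8, 8, 2, 4), 5120)
  # linear in h*w at fixed C, M
  expect_equal(wmsa_cost(16, 16, 8, 4) / wmsa_cost(8, 8, 8, 4), 4)
  # second term grows quadratically in M
  second <- function(M) wmsa_cost(M, M, 1, M) - 4 * M * M
  expect_equal(second(8) / second(4), (8 / 4)^2 * (8 * 8) / (4 * 4))
})
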