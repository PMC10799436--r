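test_that("convolutional Q/K/V projection is per-voxel channel mixing", {
  set.seed(31)
  N <- 6; d <- 8
  X <- matrix(rnorm(N * d), N, d)
  I <- diag(N)
  # identity kernel -> Q equals the input tokens
  out <- project_qkv_conv(X, list(Wq = I, Wk = I, Wv = I))
  expect_equal(out$Q, X)
  # zero kernel -> Q = 0
  Z <- matrix(0, N, N)
  expect_equal(project_qkv_conv(X, list(Wq = Z, Wk = Z, Wv = Z))$Q,
               matrix(0, N, d))
  # random weights -> equals an explicit per-voxel matrix multiply, and the
  # head slice picks d/H columns
  W <- list(Wq = matrix(rnorm(N * N), N), Wk = matrix(rnorm(N * N), N),
            Wv = matrix(rnorm(N * N), N))
  full <- project_qkv_conv(X, W)
  for (v in seq_len(d))
    expect_equal(full$Q[, v], as.numeric(W$Wq %*% X[, v]))
  h2 <- project_qkv_conv(X, W, head = 2, n_heads = 4)
  expect_equal(h2$K, (W$Wk %*% X)[, 3:4])
  expect_error(project_qkv_conv(X, W, head = 1, n_heads = 3), "divisible")
})

test_that("single-head attention: degenerate cases and formula oracle", {
  # one token: softmax of a scalar is 1, output = V
  V <- matrix(c(2, -1), 1)
  sh <- single_head_attention(matrix(1, 1, 2), matrix(3, 1, 2), V)
  expect_equal(sh$attention, matrix(1, 1, 1))
  expect_equal(sh$output, V)

  # zero queries: uniform weights, output = column mean of V
  set.seed(32)
  K <- matrix(rnorm(8), 4, 2); V <- matrix(rnorm(8), 4, 2)
  sh <- single_head_attention(matrix(0, 4, 2), K, V)
  expect_equal(sh$attention, matrix(0.25, 4, 4))
  expect_equal(sh$output, matrix(colMeans(V), 4, 2, byrow = TRUE))

  # random N=4, d=2 vs the direct formula oracle
  for (i in 1:5) {
    Q <- matrix(rnorm(8), 4, 2); K <- matrix(rnorm(8), 4, 2)
    V <- matrix(rnorm(8), 4, 2)
    got <- single_head_attention(Q, K, V, d = 2)
    want <- oracle_attention(Q, K, V, d = 2)
    expect_equal(got$output, want$output, tolerance = 1e-6)
    expect_equal(got$attention, want$attention, tolerance = 1e-6)
    expect_equal(rowSums(got$attention), rep(1, 4), tolerance = 1e-5)
  }
})

test_that("multi-head attention concatenates heads back to dim d", {
  set.seed(33)
  cfg1 <- transformer_config(L = 1, H = 1, d = 8, n_tokens = 6)
  p1 <- init_transformer_params(cfg1, seed = 3)
  X <- matrix(rnorm(48), 6, 8)
  mh <- multi_head_attention(X, p1$layers[[1]], cfg1)
  hp <- p1$layers[[1]]$heads[[1]]
  sh <- single_head_attention(hp$Wq %*% X, hp$Wk %*% X, hp$Wv %*% X,
                              d = adfuse:::attn_scale(cfg1)^2)
  expect_equal(mh$output, sh$output)
  expect_equal(mh$attention[, , 1], sh$attention)

  # default H=4, d=8: per-head width 2, concatenation restores 8
  cfg4 <- transformer_config(L = 1, H = 4, d = 8, n_tokens = 6)
  p4 <- init_transformer_params(cfg4, seed = 4)
  mh4 <- multi_head_attention(X, p4$layers[[1]], cfg4)
  expect_equal(dim(mh4$output), c(6, 8))
  expect_equal(dim(mh4$attention), c(6, 6, 4))

  # symmetry: tie all head projections and feed tokens whose head slices are
  # identical columns; every head then sees the same Q/K/V and the per-head
  # attention matrices coincide with the single-head oracle
  for (h in 2:4) p4$layers[[1]]$heads[[h]] <- p4$layers[[1]]$heads[[1]]
  Xsym <- matrix(rnorm(6), 6, 8)           # one column pattern repeated
  mht <- multi_head_attention(Xsym, p4$layers[[1]], cfg4)
  hp <- p4$layers[[1]]$heads[[1]]
  want <- oracle_attention((hp$Wq %*% Xsym)[, 1:2], (hp$Wk %*% Xsym)[, 1:2],
                           (hp$Wv %*% Xsym)[, 1:2],
                           d = adfuse:::attn_scale(cfg4)^2)
  for (h in 1:4)
    expect_equal(mht$attention[, , h], want$attention, tolerance = 1e-10)
})

test_that("gated residual and feed-forward evaluate their defining formulas", {
  set.seed(34)
  X <- matrix(rnorm(12), 3, 4); O <- matrix(rnorm(12), 3, 4)
  expect_equal(gated_residual(O, X, 0), X)
  expect_equal(gated_residual(matrix(0, 3, 4), X, 1), X)
  expect_equal(gated_residual(O, X, 0.3), 0.3 * O + X)
  expect_error(gated_residual(matrix(0, 2, 2), X, 1), "shape")

  I4 <- diag(4)
  Xp <- abs(X)
  expect_equal(feed_forward(Xp, I4, numeric(4), I4, numeric(4)), Xp)
  expect_equal(feed_forward(X, I4, numeric(4), I4, numeric(4)), pmax(X, 0))
  W1 <- matrix(rnorm(4 * 6), 4, 6); b1 <- rnorm(6)
  W2 <- matrix(rnorm(6 * 4), 6, 4); b2 <- rnorm(4)
  want <- pmax(X %*% W1 + matrix(b1, 3, 6, TRUE), 0) %*% W2 +
    matrix(b2, 3, 4, TRUE)
  expect_equal(feed_forward(X, W1, b1, W2, b2), want)
  expect_error(feed_forward(X, W2, b1, W1, b2), "shapes")
})

test_that("a full encoder block matches an independent straight-line oracle", {
  set.seed(35)
  cfg <- transformer_config(L = 1, H = 2, d = 4, D = 8, n_tokens = 4)
  p <- init_transformer_params(cfg, seed = 6)
  p$layers[[1]]$alpha <- 0.6
  X <- matrix(rnorm(16), 4, 4)
  got <- encoder_stack(X, cfg, p)

  # straight-line re-implementation: pre-norm, per-head conv QKV + softmax
  # attention, concat, gated residual, pre-norm FFN, residual
  ln <- function(x, g, b) {
    t(apply(x, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5))) *
      matrix(g, nrow(x), length(g), TRUE) + matrix(b, nrow(x), length(b), TRUE)
  }
  lp <- p$layers[[1]]
  Xn <- ln(X, lp$ln1_gamma, lp$ln1_beta)
  O <- matrix(0, 4, 4)
  for (h in 1:2) {
    sl <- ((h - 1) * 2 + 1):(h * 2)
    hp <- lp$heads[[h]]
    Qh <- (hp$Wq %*% Xn)[, sl]; Kh <- (hp$Wk %*% Xn)[, sl]
    Vh <- (hp$Wv %*% Xn)[, sl]
    S <- Qh %*% t(Kh) / sqrt(2)
    A <- t(apply(S, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
    O[, sl] <- A %*% Vh
  }
  X1 <- 0.6 * O + X
  Xn2 <- ln(X1, lp$ln2_gamma, lp$ln2_beta)
  want <- X1 + pmax(Xn2 %*% lp$W1 + matrix(lp$b1, 4, 8, TRUE), 0) %*% lp$W2 +
    matrix(lp$b2, 4, 4, TRUE)
  expect_equal(got$tokens, want, tolerance = 1e-5)
})

test_that("encoder stack records the attention geometry and is deterministic", {
  cfg <- transformer_config(L = 2, H = 4, d = 8, n_tokens = 200)
  p <- init_transformer_params(cfg, seed = 7)
  set.seed(36)
  X <- matrix(abs(rnorm(200 * 8)), 200, 8)
  out <- encoder_stack(X, cfg, p)
  expect_length(out$attention, 2)
  expect_equal(dim(out$attention[[1]]), c(200, 200, 4))
  for (l in 1:2) for (h in 1:4)
    expect_equal(rowSums(out$attention[[l]][, , h]), rep(1, 200),
                 tolerance = 1e-5)
  expect_identical(encoder_stack(X, cfg, p)$tokens, out$tokens)

  # zero gates and zero FFN weights: block is the identity
  p0 <- p
  for (l in 1:2) {
    p0$layers[[l]]$alpha <- 0
    p0$layers[[l]]$W2[] <- 0
    p0$layers[[l]]$b2[] <- 0
  }
  expect_equal(encoder_stack(X, cfg, p0)$tokens, X)
  expect_error(encoder_stack(X[1:10, ], cfg, p), "expects")
})

test_that("attention rows are stochastic across 100 random trials", {
  set.seed(37)
  for (trial in 1:100) {
    n <- sample(2:8, 1); dh <- sample(1:4, 1)
    sh <- single_head_attention(matrix(rnorm(n * dh, sd = 2), n),
                                matrix(rnorm(n * dh, sd = 2), n),
                                matrix(rnorm(n * dh), n))
    expect_true(all(abs(rowSums(sh$attention) - 1) < 1e-5))
    expect_true(all(sh$attention >= 0 & sh$attention <= 1))
  }
})
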