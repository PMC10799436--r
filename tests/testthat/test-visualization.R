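test_that("residual augmentation mixes attention with the identity", {
  expect_equal(residual_augment(diag(3)), diag(3))
  expect_equal(residual_augment(matrix(0.5, 2, 2)),
               matrix(c(0.75, 0.25, 0.25, 0.75), 2))
  set.seed(51)
  for (i in 1:10) {
    W <- random_row_stochastic(sample(2:9, 1))
    A <- residual_augment(W)
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-12)
  }
  expect_error(residual_augment(matrix(1, 2, 3)), "square")
})

test_that("attention rollout equals the brute-force augmented product", {
  W <- random_row_stochastic(4)
  expect_equal(attention_rollout(list(W))$rollout, residual_augment(W))
  expect_equal(attention_rollout(list(diag(4), diag(4), diag(4)))$rollout,
               diag(4))
  set.seed(52)
  for (trial in 1:10) {
    L <- sample(1:5, 1); n <- sample(2:16, 1); H <- sample(1:4, 1)
    stack <- lapply(seq_len(L), function(l) {
      a <- array(0, c(n, n, H))
      for (h in seq_len(H)) a[, , h] <- random_row_stochastic(n)
      a
    })
    ro <- attention_rollout(stack)
    expect_equal(ro$rollout, oracle_rollout(stack), tolerance = 1e-12)
    expect_equal(rowSums(ro$rollout), rep(1, n), tolerance = 1e-5)
    for (A in ro$per_layer)
      expect_equal(rowSums(A), rep(1, n), tolerance = 1e-5)
  }
  expect_error(attention_rollout(list(diag(3), diag(4))), "differ")
})

test_that("feature weights are row/column averages with a lowest-index tie rule", {
  fw <- feature_weights(diag(4))
  expect_equal(fw$w, rep(1 / 4, 4))
  expect_equal(fw$argmax, 1L)

  A <- matrix(c(0.6, 0.3, 0.1,
                0.2, 0.5, 0.3,
                0.1, 0.1, 0.8), 3, byrow = TRUE)
  fw <- feature_weights(A)
  expect_equal(fw$w, (colMeans(A) + rowMeans(A)) / 2)
  expect_true(all(fw$w >= 0))
  expect_length(fw$w, 3)

  # multiple samples are averaged
  B <- diag(3)
  fw2 <- feature_weights(list(A, B))
  expect_equal(fw2$w, ((colMeans(A) + rowMeans(A)) / 2 + rep(1 / 3, 3)) / 2)
})

test_that("decoder mirrors the encoder geometry and masks cleanly", {
  enc <- encoder_config(n_blocks = 2, filters = c(4, 8), final_filters = 16)
  dec <- build_deconv(enc, "smri", seed = 2)
  maps <- array(runif(4^3 * 16), c(4, 4, 4, 16))
  sal <- decode_feature(dec, maps, 3)
  expect_s3_class(sal, "salience_volume")
  expect_equal(dim(sal$data), c(16, 16, 16))   # mirror contract: 4 * 2^2
  expect_equal(attr(sal, "feature_index"), 3)

  # zero feature map at the selected index + zero biases -> all-zero salience
  maps0 <- maps; maps0[, , , 5] <- 0
  expect_equal(decode_feature(dec, maps0, 5)$data, array(0, c(16, 16, 16)))
  expect_error(decode_feature(dec, maps, 17), "out of range")
})

test_that("deconv training reduces reconstruction error under its schedule", {
  enc <- tiny_enc_cfg()
  ip <- init_encoder_params(enc, seed = 3)
  set.seed(53)
  vols <- lapply(1:6, function(i) volume(array(runif(8^3), c(8, 8, 8))))
  dec <- build_deconv(enc, "smri", seed = 4)
  cfg <- deconv_config(epochs = 30, batch_size = 3, lr = 2e-3,
                       lr_decay_every = 10, lr_decay_factor = 0.5, seed = 5)
  tr <- train_deconv(dec, ip, vols, cfg)
  h <- tr$history
  expect_lt(h$mse[nrow(h)], h$mse[1])
  # schedule: lr steps down by the decay factor at epochs 11 and 21
  expect_equal(h$lr[1], 2e-3)
  expect_equal(h$lr[11], 1e-3)
  expect_equal(h$lr[21], 5e-4)
  # contract defaults match the visualization protocol
  d <- deconv_config()
  expect_equal(d$epochs, 3000L); expect_equal(d$batch_size, 20L)
  expect_equal(d$lr * d$lr_decay_factor^((501 - 1) %/% d$lr_decay_every), 5e-5)
})

test_that("percentile + size filtering reports the constructed clusters", {
  # single 150-voxel blob above background
  set.seed(54)
  a <- array(runif(20^3, 0, 0.1), c(20, 20, 20))
  a[3:7, 3:8, 3:7] <- 1 + runif(150)   # 5 x 6 x 5 = 150 voxels
  peak_lin <- which.max(a)
  rep1 <- threshold_and_cluster(volume(a), top_pct = 100 * 150 / 20^3,
                                min_size = 100)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$voxels, 150)
  expect_equal(unlist(rep1[1, c("peak_i", "peak_j", "peak_k")],
                      use.names = FALSE),
               as.integer(arrayInd(peak_lin, dim(a))))

  # two blobs (150 and 60 voxels) in the top percentile; only one survives
  b <- array(0, c(30, 30, 30))
  b[2:6, 2:7, 2:6] <- 1          # 5*6*5 = 150 voxels
  b[20:24, 20:23, 20:22] <- 1    # 5*4*3 = 60 voxels
  rep2 <- threshold_and_cluster(volume(b), top_pct = 100 * 210 / 30^3,
                                min_size = 100)
  expect_equal(nrow(rep2), 1)
  expect_equal(rep2$voxels, 150)

  # with both below threshold relaxed, sizes sort descending
  rep3 <- threshold_and_cluster(volume(b), top_pct = 100 * 210 / 30^3,
                                min_size = 10)
  expect_equal(rep3$voxels, c(150, 60))
  expect_equal(rep3$rank, 1:2)

  # no filtering at all: one cluster spanning the whole support
  rep4 <- threshold_and_cluster(volume(a), top_pct = 100, min_size = 0)
  expect_equal(nrow(rep4), 1)
  expect_equal(rep4$voxels, 20^3)

  # 6- vs 26-connectivity: diagonal touching splits under 6
  d6 <- array(0, c(8, 8, 8))
  d6[1:2, 1:2, 1:2] <- 1
  d6[3:4, 3:4, 3:4] <- 1
  r26 <- threshold_and_cluster(volume(d6), top_pct = 100 * 16 / 512,
                               min_size = 0, connectivity = 26)
  r6 <- threshold_and_cluster(volume(d6), top_pct = 100 * 16 / 512,
                              min_size = 0, connectivity = 6)
  expect_equal(nrow(r26), 1)
  expect_equal(nrow(r6), 2)

  expect_error(threshold_and_cluster(volume(array(1, c(4, 4, 4)))),
               "degenerate")
})

test_that("mm coordinates pass through the volume affine", {
  a <- array(0, c(10, 10, 10)); a[4, 5, 6] <- 1
  aff <- diag(4); aff[1:3, 4] <- c(100, -50, 10); aff[2, 2] <- 2
  rep <- threshold_and_cluster(volume(a, aff), top_pct = 0.1, min_size = 0)
  expect_equal(c(rep$peak_x_mm, rep$peak_y_mm, rep$peak_z_mm),
               c(100 + 3, -50 + 2 * 4, 10 + 5))
})

test_that("checkpoints round-trip the whole model", {
  m <- tiny_model(seed = 12)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2$params, m$params)
  s <- tiny_subject(5)
  expect_identical(forward_fused(m, s), forward_fused(m2, s))
  saveRDS(list(x = 1), f)
  expect_error(load_checkpoint(f), "not an adfuse checkpoint")
})
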