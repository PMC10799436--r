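# Shared fixtures and independent brute-force oracles.

# --- tiny model configurations ---------------------------------------------

tiny_enc_cfg <- function() encoder_config(n_blocks = 2L, filters = c(2L, 3L),
                                          final_filters = 4L)
tiny_tx_cfg <- function() transformer_config(L = 2L, H = 2L, d = 8L, D = 8L,
                                             n_tokens = 4L)
tiny_fus_cfg <- function(dropout = 0) fusion_config(mlp_hidden = 5L,
                                                    dropout_p = dropout)

tiny_model <- function(seed = 5L, dropout = 0, ablation = "full") {
  assemble_model(tiny_enc_cfg(), tiny_tx_cfg(),
                 tiny_fus_cfg(dropout = dropout) |>
                   (\(f) { f$ablation <- ablation; f })(),
                 input_edge = 8L, seed = seed)
}

tiny_subject <- function(seed = 1L, edge = 8L) {
  set.seed(seed)
  subject(sprintf("T%03d", seed),
          volume(array(runif(edge^3), c(edge, edge, edge))),
          volume(array(runif(edge^3), c(edge, edge, edge))), "AD")
}

# --- independent oracles ----------------------------------------------------

# Sliding-window sum-of-products 3D convolution ('same' padding, stride 1)
# for a single-sample, single-output-channel check.
oracle_conv3d <- function(x, w, b) {
  # x: (n,n,n,ci); w: (k,k,k,ci,co); returns (n,n,n,co)
  n <- dim(x)[1]; ci <- dim(x)[4]; k <- dim(w)[1]; co <- dim(w)[5]
  pad <- (k - 1) / 2
  xp <- array(0, c(n + 2 * pad, n + 2 * pad, n + 2 * pad, ci))
  xp[pad + 1:n, pad + 1:n, pad + 1:n, ] <- x
  out <- array(0, c(n, n, n, co))
  for (o in 1:co) for (i in 1:n) for (j in 1:n) for (l in 1:n) {
    acc <- b[o]
    for (c in 1:ci)
      acc <- acc + sum(xp[i:(i + k - 1), j:(j + k - 1), l:(l + k - 1), c] *
                         w[, , , c, o])
    out[i, j, l, o] <- acc
  }
  out
}

# Direct softmax attention (independent straight-line formula evaluation).
oracle_attention <- function(Q, K, V, d) {
  S <- Q %*% t(K) / sqrt(d)
  A <- t(apply(S, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
  if (nrow(S) == 1) A <- matrix(A, 1)
  list(output = A %*% V, attention = A)
}

# Explicit product of residual-augmented, head-averaged attention matrices.
oracle_rollout <- function(stack) {
  mats <- lapply(stack, function(a) {
    if (length(dim(a)) == 3) a <- apply(a, c(1, 2), mean)
    0.5 * a + 0.5 * diag(nrow(a))
  })
  acc <- mats[[1]]
  for (l in seq_along(mats)[-1]) acc <- mats[[l]] %*% acc
  acc
}

# AUC by exhaustive pairwise comparison (ties count 1/2).
oracle_auc <- function(scores, labels, positive = "AD") {
  pos <- which(labels == positive); neg <- which(labels != positive)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  100 * tot / (length(pos) * length(neg))
}

random_row_stochastic <- function(n) {
  m <- matrix(runif(n * n), n)
  m / rowSums(m)
}

# --- memoized heavy fixtures (trained models shared across tests) -----------

.acc_env <- new.env(parent = emptyenv())

acc_fixture <- function(name, builder) {
  if (!exists(name, envir = .acc_env)) assign(name, builder(), envir = .acc_env)
  get(name, envir = .acc_env)
}

# The package's reduced-scale planted-lesion experiment: train the scaled
# model on the 30+30 cohort (fold 1 of the tenfold plan) and evaluate on an
# independent 50+50 cohort.
scaled_experiment <- function(effect_size) {
  pr <- desk_profile("scaled", seed = 1L, effect_size = effect_size)
  cohort <- generate_cohort(pr$cohort_cfg)
  labels <- vapply(cohort, `[[`, character(1), "label")
  plan <- make_folds(labels, 10L, seed = pr$train_cfg$seed)
  lp <- plan$loops[[1]]
  model <- assemble_model(pr$enc_cfg, pr$tx_cfg, pr$fus_cfg,
                          input_edge = pr$cohort_cfg$grid, seed = 1L)
  tr <- train_model(model, cohort[lp$train], cohort[lp$validation],
                    pr$train_cfg)
  eval_cohort <- generate_cohort(pr$eval_cohort_cfg)
  pv <- adfuse:::predict_model(tr$model, eval_cohort)
  list(profile = pr, cohort = cohort, plan = plan, train = tr,
       eval_cohort = eval_cohort,
       heldout_acc = mean(pv$labels ==
                            vapply(eval_cohort, `[[`, character(1), "label")))
}
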