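test_that("tenfold plan reproduces the published split arithmetic", {
  labels <- rep(c("AD", "CN"), c(88, 122))
  fp <- make_folds(labels, 10, seed = 1)
  for (lp in fp$loops) {
    expect_length(lp$test, 21)
    expect_length(lp$validation, 21)
    expect_length(lp$train, 168)
  }
})

test_that("fold plan partitions subjects and stratifies classes", {
  # n = 10 subjects over 10 portions -> 1 test / 1 validation / 8 train
  suppressWarnings(fp <- make_folds(rep(c("AD", "CN"), 5), 10, seed = 2))
  expect_equal(lengths(fp$loops[[1]]), c(test = 1L, validation = 1L, train = 8L))

  # 10 AD + 10 CN over 10 portions: every portion has exactly 1 of each
  labels <- rep(c("AD", "CN"), each = 10)
  fp <- make_folds(labels, 10, seed = 3)
  for (p in fp$portions) {
    expect_length(p, 2)
    expect_setequal(labels[p], c("AD", "CN"))
  }

  # partition + single-test-membership properties over random cases
  set.seed(44)
  for (trial in 1:5) {
    n <- sample(25:60, 1)
    labels <- sample(c("AD", "CN"), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    k <- sample(4:8, 1)
    fp <- suppressWarnings(make_folds(labels, k, seed = trial))
    seen <- integer(0)
    for (lp in fp$loops) {
      expect_setequal(c(lp$test, lp$validation, lp$train), seq_len(n))
      expect_length(intersect(lp$test, lp$validation), 0)
      expect_length(intersect(lp$test, lp$train), 0)
      seen <- c(seen, lp$test)
    }
    expect_setequal(seen, seq_len(n))
    expect_length(seen, n)
  }

  expect_error(make_folds(rep("AD", 20), 10), "both classes")
})

test_that("learning-rate schedule steps by the decay factor every 20 epochs", {
  cfg <- train_config()
  expect_equal(cfg$batch_size, 11L)
  expect_equal(cfg$epochs, 60L)
  expect_equal(lr_at_epoch(cfg, 1), 1e-4)
  expect_equal(lr_at_epoch(cfg, 20), 1e-4)
  expect_equal(lr_at_epoch(cfg, 21), 1e-5)
  expect_equal(lr_at_epoch(cfg, 41), 1e-6)
})

test_that("zero-epoch training leaves the model untouched", {
  m <- tiny_model(seed = 10)
  coh <- lapply(1:4, tiny_subject)
  coh[[2]]$label <- "CN"; coh[[4]]$label <- "CN"
  tr <- train_model(m, coh, list(), train_config(epochs = 0))
  expect_identical(tr$model$params, m$params)
  expect_error(train_model(m, list(), list(), train_config(epochs = 1)),
               "empty")
})

test_that("training descends and its history is seed-reproducible", {
  m <- tiny_model(seed = 11, dropout = 0.1)
  set.seed(45)
  coh <- c(lapply(1:6, tiny_subject),
           lapply(7:12, function(i) { s <- tiny_subject(i); s$label <- "CN"; s }))
  cfg <- train_config(batch_size = 4, epochs = 3, lr = 1e-3, seed = 99)
  tr1 <- train_model(m, coh[1:10], coh[11:12], cfg)
  tr2 <- train_model(m, coh[1:10], coh[11:12], cfg)
  expect_identical(tr1$history, tr2$history)
  expect_identical(tr1$model$params, tr2$model$params)
  expect_equal(nrow(tr1$history), 3)
  expect_true(all(c("train_loss", "val_acc", "alpha_1", "alpha_2") %in%
                    names(tr1$history)))
  expect_lt(tr1$history$train_loss[3], tr1$history$train_loss[1])
  # gates start masked and stay in [0, 1]
  expect_true(all(tr1$history$alpha_1 >= 0 & tr1$history$alpha_1 <= 1))
})

test_that("metrics follow the confusion-matrix definitions", {
  labs <- rep(c("AD", "CN"), each = 10)
  m <- evaluate_metrics(labs, labs, scores = c(rep(1, 10), rep(0, 10)))
  expect_equal(unname(m), rep(100, 6))

  # TP=9 FN=1 TN=9 FP=1 -> everything 90%
  pred <- c(rep("AD", 9), "CN", rep("CN", 9), "AD")
  m <- evaluate_metrics(pred, labs)
  expect_equal(unname(m[c("ACC", "PRE", "SPE", "SEN", "F1S")]), rep(90, 5))

  # AUC: separable scores give 100; random scores match the pairwise oracle
  m <- evaluate_metrics(c("AD", "AD", "CN", "CN"), c("AD", "AD", "CN", "CN"),
                        scores = c(0.9, 0.8, 0.3, 0.1))
  expect_equal(unname(m["AUC"]), 100)
  set.seed(46)
  for (i in 1:5) {
    labels <- sample(rep(c("AD", "CN"), c(6, 8)))
    scores <- round(runif(14), 1)  # coarse grid to exercise ties
    pred <- ifelse(scores > 0.5, "AD", "CN")
    got <- evaluate_metrics(pred, labels, scores = scores)
    expect_equal(unname(got["AUC"]), oracle_auc(scores, labels))
    # F1 harmonic identity and ACC identity
    if (!any(is.na(got[c("PRE", "SEN")])))
      expect_equal(unname(got["F1S"]),
                   unname(2 * got["PRE"] * got["SEN"] / (got["PRE"] + got["SEN"])))
  }

  # AUC is invariant under strictly monotone score transforms
  labels <- rep(c("AD", "CN"), 7)
  scores <- runif(14)
  a1 <- evaluate_metrics(ifelse(scores > 0.5, "AD", "CN"), labels,
                         scores = scores)["AUC"]
  a2 <- evaluate_metrics(ifelse(scores > 0.5, "AD", "CN"), labels,
                         scores = exp(3 * scores))["AUC"]
  expect_equal(a1, a2)

  # single-class fold: flagged as NA, not silently zero
  expect_warning(m <- evaluate_metrics(rep("AD", 4), rep("AD", 4)),
                 "undefined")
  expect_true(is.na(m["SPE"]))
})

test_that("permutation p-value formula hits its closed-form extremes", {
  expect_equal(perm_pvalue(0.4, rep(0.6, 25)), 1)
  expect_equal(perm_pvalue(1.0, runif(99, 0, 0.9)), 0.01)
  expect_equal(perm_pvalue(1.0, runif(19, 0, 0.9)), 0.05)
  p <- perm_pvalue(0.7, runif(50))
  expect_gt(p, 0); expect_lte(p, 1)
})
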