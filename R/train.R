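#' Training configuration
#'
#' Defaults follow the end-to-end protocol the model was designed with:
#' Adam with default moments, batch size 11, 60 epochs, learning rate 1e-4
#' decaying by a factor 0.1 every 20 epochs.
#'
#' @param batch_size mini-batch size.
#' @param epochs number of epochs.
#' @param lr initial learning rate.
#' @param lr_decay_every epochs between learning-rate decays.
#' @param lr_decay_factor multiplicative decay factor.
#' @param seed integer seed controlling shuffling, dropout and any other
#'   training randomness.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 11L, epochs = 60L, lr = 1e-4,
                         lr_decay_every = 20L, lr_decay_factor = 0.1,
                         seed = 1L) {
  stopifnot(batch_size >= 1, epochs >= 0, lr > 0, lr_decay_every >= 1)
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 lr = lr, lr_decay_every = as.integer(lr_decay_every),
                 lr_decay_factor = lr_decay_factor, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate in effect at a given epoch
#' @param cfg a [train_config()].
#' @param epoch 1-based epoch index.
#' @return The stepped learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  cfg$lr * cfg$lr_decay_factor^((epoch - 1) %/% cfg$lr_decay_every)
}

label_int <- function(labels) match(labels, c("AD", "CN"))

model_alphas <- function(model) {
  if (is.null(model$params$tx) || !model$tx_cfg$gated) return(numeric(0))
  vapply(model$params$tx$layers, function(l) l$alpha, numeric(1))
}

#' Train the fusion model
#'
#' Mini-batch Adam training with the stepped learning-rate schedule. Each
#' epoch records train loss/accuracy (accumulated over the training batches),
#' validation loss/accuracy (eval mode), and the per-block attention gates
#' `alpha`. The returned model carries the parameters of the epoch with the
#' best validation accuracy (ties broken toward the latest epoch); with no
#' validation subjects the final epoch is kept. Fixed seeds make the whole
#' run reproducible.
#'
#' @param model an `adfuse_model` from [assemble_model()].
#' @param train_subjects,val_subjects disjoint lists of [subject()]s.
#' @param cfg a [train_config()].
#' @return List with `model` (trained), `history` (one row per epoch:
#'   `epoch, lr, train_loss, train_acc, val_loss, val_acc, alpha_*`), and
#'   `best_epoch`.
#' @export
train_model <- function(model, train_subjects, val_subjects = list(),
                        cfg = train_config()) {
  if (length(train_subjects) == 0) stop("train_model: empty training set")
  if (cfg$epochs == 0L)
    return(list(model = model, history = data.frame(), best_epoch = NA_integer_))
  y_train <- label_int(cohort_labels(train_subjects))
  y_val <- if (length(val_subjects)) label_int(cohort_labels(val_subjects)) else integer(0)
  opt <- adam_init(model$params)
  best <- list(acc = -Inf, epoch = 0L, params = model$params, stats = model$stats)
  nL <- length(model_alphas(model))
  hist <- vector("list", cfg$epochs)
  with_local_seed(derive_seed(cfg$seed, 17L), {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_at_epoch(cfg, epoch)
      ord <- sample(length(train_subjects))
      ep_loss <- 0; ep_hit <- 0
      for (start in seq(1L, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        xs <- stack_volumes(train_subjects[idx], "smri")
        xp <- stack_volumes(train_subjects[idx], "pet")
        fw <- model_forward(model, xs, xp, training = TRUE)
        model$stats <- fw$stats
        ce <- softmax_xent(fw$logits, y_train[idx])
        ep_loss <- ep_loss + ce$loss * length(idx)
        ep_hit <- ep_hit + sum(max.col(ce$probs, "first") == y_train[idx])
        grads <- model_backward(model, fw$cache, ce$glogits)
        step <- adam_step(model$params, grads, opt, lr)
        model$params <- step$params
        opt <- step$state
      }
      val_loss <- NA_real_; val_acc <- NA_real_
      if (length(val_subjects)) {
        pv <- predict_model(model, val_subjects)
        val_loss <- cross_entropy_loss(pv$probs, y_val)
        val_acc <- mean(pv$labels == cohort_labels(val_subjects))
        if (val_acc >= best$acc) {
          best <- list(acc = val_acc, epoch = epoch, params = model$params,
                       stats = model$stats)
        }
      }
      row <- data.frame(epoch = epoch, lr = lr,
                        train_loss = ep_loss / length(ord),
                        train_acc = ep_hit / length(ord),
                        val_loss = val_loss, val_acc = val_acc)
      al <- model_alphas(model)
      if (nL) for (l in seq_len(nL)) row[[paste0("alpha_", l)]] <- al[l]
      hist[[epoch]] <- row
    }
  })
  history <- do.call(rbind, hist)
  if (length(val_subjects)) {
    model$params <- best$params
    model$stats <- best$stats
    best_epoch <- best$epoch
  } else best_epoch <- cfg$epochs
  list(model = model, history = history, best_epoch = best_epoch)
}

#' Stratified k-fold cross-validation
#'
#' Trains a freshly initialized model per loop of the fold plan and
#' aggregates the six diagnostic metrics over the test portions.
#'
#' @param cohort list of [subject()]s.
#' @param enc_cfg,tx_cfg,fus_cfg model configurations (see
#'   [assemble_model()]).
#' @param train_cfg a [train_config()].
#' @param n_portions portions/loops of the plan (default 10).
#' @param input_edge cubic input edge (defaults to the cohort's grid).
#' @return A `metrics_report`: list with `folds` (per-loop metric rows),
#'   `mean` and `sd` (across loops), and the `fold_plan` used.
#' @export
cross_validate <- function(cohort, enc_cfg, tx_cfg = transformer_config(),
                           fus_cfg = fusion_config(),
                           train_cfg = train_config(), n_portions = 10L,
                           input_edge = NULL) {
  labels <- cohort_labels(cohort)
  if (is.null(input_edge)) input_edge <- dim(cohort[[1]]$smri$data)[1]
  plan <- make_folds(labels, n_portions, seed = train_cfg$seed)
  rows <- vector("list", length(plan$loops))
  for (i in seq_along(plan$loops)) {
    lp <- plan$loops[[i]]
    model <- assemble_model(enc_cfg, tx_cfg, fus_cfg, input_edge = input_edge,
                            seed = derive_seed(train_cfg$seed, 100L + i))
    cfg_i <- train_cfg
    cfg_i$seed <- derive_seed(train_cfg$seed, 200L + i)
    tr <- train_model(model, cohort[lp$train], cohort[lp$validation], cfg_i)
    pr <- predict_model(tr$model, cohort[lp$test])
    m <- evaluate_metrics(pr$labels, labels[lp$test], "AD",
                          scores = pr$probs[, "AD"])
    rows[[i]] <- c(fold = i, m)
  }
  folds <- as.data.frame(do.call(rbind, rows))
  metric_cols <- setdiff(names(folds), "fold")
  structure(list(folds = folds,
                 mean = colMeans(folds[metric_cols], na.rm = TRUE),
                 sd = apply(folds[metric_cols], 2, sd, na.rm = TRUE),
                 plan = plan),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d folds (mean +/- sd, %%):\n", nrow(x$folds)))
  for (m in names(x$mean))
    cat(sprintf("  %-4s %6.2f +/- %5.2f\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}

#' Label-permutation significance test
#'
#' Fixes one train/validation/test split, trains on the true labels to get
#' the observed test accuracy, then retrains `n_perm` times with the labels
#' of the non-test subjects randomly permuted, always scoring against the
#' untouched true test labels. The null hypothesis is that the classifier
#' cannot learn the label-image relationship.
#'
#' @param cohort list of [subject()]s.
#' @param enc_cfg,tx_cfg,fus_cfg model configurations.
#' @param train_cfg a [train_config()].
#' @param n_perm number of permutations.
#' @param n_portions portions for the underlying split.
#' @return A `permutation_result`: list with `observed` (accuracy, percent),
#'   `permuted` (vector, percent), and `p` (see [perm_pvalue()]).
#' @export
permutation_test <- function(cohort, enc_cfg, tx_cfg = transformer_config(),
                             fus_cfg = fusion_config(),
                             train_cfg = train_config(), n_perm = 1000L,
                             n_portions = 10L) {
  stopifnot(n_perm >= 1)
  labels <- cohort_labels(cohort)
  plan <- make_folds(labels, n_portions, seed = train_cfg$seed)
  lp <- plan$loops[[1]]
  run <- function(lab_override, stream) {
    coh <- cohort
    if (!is.null(lab_override))
      for (j in seq_along(lab_override)) coh[[lab_override[[j]][1]]]$label <-
          c("AD", "CN")[lab_override[[j]][2]]
    model <- assemble_model(enc_cfg, tx_cfg, fus_cfg,
                            input_edge = dim(cohort[[1]]$smri$data)[1],
                            seed = derive_seed(train_cfg$seed, 300L + stream))
    cfg_i <- train_cfg
    cfg_i$seed <- derive_seed(train_cfg$seed, 400L + stream)
    tr <- train_model(model, coh[lp$train], coh[lp$validation], cfg_i)
    pr <- predict_model(tr$model, cohort[lp$test])
    100 * mean(pr$labels == labels[lp$test])
  }
  observed <- run(NULL, 0L)
  fit_idx <- c(lp$train, lp$validation)
  permuted <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    perm <- with_local_seed(derive_seed(train_cfg$seed, 500L + k),
                            sample(fit_idx))
    override <- lapply(seq_along(fit_idx), function(j)
      c(fit_idx[j], label_int(labels[perm[j]])))
    permuted[k] <- run(override, k)
  }
  structure(list(observed = observed, permuted = permuted,
                 p = perm_pvalue(observed, permuted)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed %.1f%%, %d permutations (max %.1f%%), p = %.4g\n",
              x$observed, length(x$permuted), max(x$permuted), x$p))
  invisible(x)
}
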