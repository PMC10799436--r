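#' Build a stratified tenfold cross-validation plan
#'
#' Subjects are divided into `n_portions` near-equal portions with classes
#' dealt round-robin (so AD and CN are evenly distributed). Loop `i` uses
#' portion `i` as the test set, portion `i + 1` (cyclically) as the
#' validation set, and the remainder for training; every subject appears in
#' the test set of exactly one loop.
#'
#' @param labels character vector of subject labels (`"AD"`/`"CN"`).
#' @param n_portions number of portions (and loops).
#' @param seed integer seed for the shuffle.
#' @return A `fold_plan`: list with `portions` (list of index vectors) and
#'   `loops` (list of `list(test, validation, train)` index vectors).
#' @examples
#' fp <- make_folds(rep(c("AD", "CN"), c(88, 122)), seed = 1)
#' lengths(fp$loops[[1]])
#' @export
make_folds <- function(labels, n_portions = 10L, seed = 1L) {
  n <- length(labels)
  if (n < n_portions) stop("make_folds: fewer subjects than portions")
  classes <- unique(labels)
  if (length(classes) < 2L) stop("make_folds: both classes must be present")
  small <- classes[table(labels)[classes] < n_portions]
  if (length(small))
    warning(sprintf("make_folds: class(es) %s have fewer members than portions; split is best-effort",
                    paste(small, collapse = ", ")))
  portions <- rep(list(integer(0)), n_portions)
  # classes are dealt round-robin with a shared slot counter, so portions are
  # near-equal in size and class composition even when a class has fewer
  # members than portions
  slot0 <- 0L
  with_local_seed(seed, {
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      slot <- ((slot0 + seq_along(idx) - 1L) %% n_portions) + 1L
      for (p in seq_len(n_portions))
        portions[[p]] <- c(portions[[p]], idx[slot == p])
      slot0 <- (slot0 + length(idx)) %% n_portions
    }
  })
  portions <- lapply(portions, sort)
  loops <- lapply(seq_len(n_portions), function(i) {
    vi <- (i %% n_portions) + 1L
    list(test = portions[[i]], validation = portions[[vi]],
         train = sort(unlist(portions[-c(i, vi)])))
  })
  structure(list(portions = portions, loops = loops,
                 n_portions = as.integer(n_portions), n = n),
            class = "fold_plan")
}

#' Classification metrics for one fold
#'
#' Standard confusion-matrix metrics on the percent scale: accuracy (ACC),
#' precision (PRE), specificity (SPE), sensitivity/recall (SEN), F1 score
#' (F1S) and AUC (rank statistic over the positive-class scores, ties
#' counted half). Metrics whose denominator is empty (e.g. specificity on a
#' fold without negatives) are returned as `NA` with a warning rather than
#' silently zeroed.
#'
#' @param predictions predicted labels (character).
#' @param labels true labels.
#' @param positive_class label treated as positive (default `"AD"`).
#' @param scores optional positive-class probabilities for AUC.
#' @return Named numeric vector `ACC, PRE, SPE, SEN, F1S, AUC` in percent
#'   (`AUC` is `NA` when `scores` is missing).
#' @export
evaluate_metrics <- function(predictions, labels, positive_class = "AD",
                             scores = NULL) {
  pos <- labels == positive_class
  ppos <- predictions == positive_class
  tp <- sum(ppos & pos); fp <- sum(ppos & !pos)
  tn <- sum(!ppos & !pos); fn <- sum(!ppos & pos)
  rate <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("evaluate_metrics: %s undefined (empty denominator)", what))
      return(NA_real_)
    }
    100 * num / den
  }
  acc <- rate(tp + tn, length(labels), "ACC")
  pre <- rate(tp, tp + fp, "PRE")
  spe <- rate(tn, tn + fp, "SPE")
  sen <- rate(tp, tp + fn, "SEN")
  f1 <- if (is.na(pre) || is.na(sen) || pre + sen == 0) NA_real_
        else 2 * pre * sen / (pre + sen)
  auc <- NA_real_
  if (!is.null(scores)) {
    np <- sum(pos); nn <- sum(!pos)
    if (np > 0 && nn > 0) {
      r <- rank(scores)
      auc <- 100 * (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
    } else {
      warning("evaluate_metrics: AUC undefined (single-class fold)")
    }
  }
  c(ACC = acc, PRE = pre, SPE = spe, SEN = sen, F1S = f1, AUC = auc)
}

#' Empirical permutation p-value
#'
#' `p = (1 + #\{permuted >= observed\}) / (1 + n_perm)`, the standard
#' add-one estimate; always in `(0, 1]`.
#'
#' @param observed observed statistic (e.g. accuracy).
#' @param permuted vector of statistics under permuted labels.
#' @return The p-value.
#' @export
perm_pvalue <- function(observed, permuted) {
  (1 + sum(permuted >= observed)) / (1 + length(permuted))
}
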