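#' Residual-augmented attention matrix
#'
#' `A = 0.5 W + 0.5 I`: the raw attention matrix is mixed equally with the
#' identity to account for the residual connection around the attention
#' sub-block (whose gate approaches 1 late in training). Row-stochasticity is
#' preserved.
#'
#' @param W square row-stochastic attention matrix.
#' @return The augmented matrix `A`.
#' @examples
#' residual_augment(matrix(0.5, 2, 2))
#' @export
residual_augment <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("residual_augment: W must be square")
  0.5 * W + 0.5 * diag(nrow(W))
}

#' Attention rollout over an attention stack
#'
#' Per layer, the head attention matrices are averaged, residual-augmented
#' (see [residual_augment()]), and recursively multiplied:
#' `A~(l_i) = A(l_i) %*% A~(l_{i-1})`, with `A~(l_1) = A(l_1)`. The final
#' layer's product traces output attention back to the input tokens.
#'
#' @param stack an attention stack: list over layers, each an `N x N`
#'   matrix or an `N x N x H` per-head array (as recorded by
#'   [encoder_stack()] / [forward_fused()]).
#' @return A `rollout_map`: list with `rollout` (final `N x N` matrix) and
#'   `per_layer` (the augmented per-layer matrices).
#' @export
attention_rollout <- function(stack) {
  if (!length(stack)) stop("attention_rollout: empty stack")
  aug <- lapply(stack, function(a) {
    if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), mean)
    residual_augment(a)
  })
  n <- vapply(aug, nrow, integer(1))
  if (length(unique(n)) != 1L)
    stop("attention_rollout: layer dimensions differ")
  acc <- aug[[1]]
  if (length(aug) > 1) for (l in 2:length(aug)) acc <- aug[[l]] %*% acc
  structure(list(rollout = acc, per_layer = aug), class = "rollout_map")
}

#' Feature contribution weights from a rollout map
#'
#' Averages the rollout matrix along rows and columns:
#' `w_j = (mean of column j + mean of row j) / 2`, giving one nonnegative
#' contribution weight per input feature (a 200-vector for the default
#' model). When several maps are supplied (one per evaluation subject) the
#' per-sample vectors are averaged. Ties at the maximum resolve to the
#' lowest index.
#'
#' @param rollout a `rollout_map` from [attention_rollout()], a bare square
#'   matrix, or a list of either (multiple samples).
#' @return A `feature_weight_vector`: list with `w` (length `N`) and
#'   `argmax`.
#' @export
feature_weights <- function(rollout) {
  as_mat <- function(r) if (inherits(r, "rollout_map")) r$rollout else as.matrix(r)
  mats <- if (inherits(rollout, "rollout_map") || is.matrix(rollout))
    list(as_mat(rollout)) else lapply(rollout, as_mat)
  ws <- vapply(mats, function(m) (colMeans(m) + rowMeans(m)) / 2,
               numeric(nrow(mats[[1]])))
  w <- rowMeans(ws)
  structure(list(w = w, argmax = which.max(w)), class = "feature_weight_vector")
}

# Per-subject rollout weight vectors for one modality, averaged over
# subjects (optionally only those the model classifies correctly).
cohort_feature_weights <- function(model, subjects, modality = "smri",
                                   correct_only = FALSE) {
  maps <- list()
  for (s in subjects) {
    pred <- forward_fused(model, s)
    if (correct_only && pred$label != s$label) next
    maps[[length(maps) + 1L]] <- attention_rollout(pred$attention[[modality]])
  }
  if (!length(maps)) stop("cohort_feature_weights: no qualifying subjects")
  feature_weights(maps)
}
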