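#' Configuration of the fusion head and ablation mode
#'
#' @param mlp_hidden hidden width of the two-layer MLP classifier.
#' @param dropout_p dropout probability applied after each linear
#'   transformation (training mode only).
#' @param n_classes number of diagnostic classes (2: AD vs CN).
#' @param ablation `"full"` (gated transformer), `"typical_transformer"`
#'   (linear Q/K/V, learned positional embeddings, ungated residual), or
#'   `"cnn_only"` (flattened encoder features straight to the MLP).
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(mlp_hidden = 256L, dropout_p = 0.1, n_classes = 2L,
                          ablation = c("full", "typical_transformer", "cnn_only")) {
  ablation <- match.arg(ablation)
  if (dropout_p < 0 || dropout_p >= 1) stop("fusion_config: dropout_p must be in [0, 1)")
  if (n_classes < 2L) stop("fusion_config: need at least 2 classes")
  structure(list(mlp_hidden = as.integer(mlp_hidden), dropout_p = dropout_p,
                 n_classes = as.integer(n_classes), ablation = ablation),
            class = "fusion_config")
}

model_classes <- function(model) c("AD", "CN")

#' Assemble the end-to-end two-stream model
#'
#' Builds the full architecture: two independent per-modality 3D encoders
#' (same structure, separate parameters), one transformer encoder stack
#' shared by both modalities, and an MLP head over the concatenated flattened
#' streams. Parameters are initialized deterministically from `seed`.
#'
#' @param enc_cfg an [encoder_config()].
#' @param tx_cfg a [transformer_config()]; its token geometry must match the
#'   encoder output (`n_tokens == final_filters`, `d ==` flattened spatial
#'   extent for `input_edge`). Ignored under the `cnn_only` ablation.
#' @param fus_cfg a [fusion_config()].
#' @param input_edge cubic input edge length the model is built for.
#' @param seed integer seed for parameter initialization.
#' @return An `adfuse_model` object.
#' @examples
#' m <- assemble_model(encoder_config(n_blocks = 2, filters = c(4, 8),
#'                                    final_filters = 16),
#'                     transformer_config(n_tokens = 16, d = 8),
#'                     fusion_config(mlp_hidden = 32), input_edge = 8)
#' print(m)
#' @export
assemble_model <- function(enc_cfg, tx_cfg = transformer_config(),
                           fus_cfg = fusion_config(), input_edge = 64L,
                           seed = 1L) {
  edge <- encoder_out_edge(enc_cfg, input_edge)
  d_tok <- edge^3
  if (fus_cfg$ablation == "typical_transformer")
    tx_cfg <- transformer_config(L = tx_cfg$L, H = tx_cfg$H, d = tx_cfg$d,
                                 D = tx_cfg$D, n_tokens = tx_cfg$n_tokens,
                                 scale_dim = tx_cfg$scale_dim,
                                 linear_qkv = TRUE, positional = TRUE,
                                 gated = FALSE)
  if (fus_cfg$ablation != "cnn_only") {
    if (tx_cfg$n_tokens != enc_cfg$final_filters)
      stop(sprintf("assemble_model: %d tokens configured but encoder yields %d feature maps",
                   tx_cfg$n_tokens, enc_cfg$final_filters))
    if (tx_cfg$d != d_tok)
      stop(sprintf("assemble_model: token dim %d configured but encoder maps flatten to %d (edge %d)",
                   tx_cfg$d, d_tok, edge))
  }
  in_dim <- 2L * enc_cfg$final_filters * d_tok
  with_local_seed(seed, {
    enc_s <- init_encoder_params(enc_cfg, 1L, seed = derive_seed(seed, 1L))
    enc_p <- init_encoder_params(enc_cfg, 1L, seed = derive_seed(seed, 2L))
    params <- list(enc_smri = enc_s$params, enc_pet = enc_p$params)
    stats <- list(enc_smri = enc_s$stats, enc_pet = enc_p$stats)
    if (fus_cfg$ablation != "cnn_only")
      params$tx <- init_transformer_params(tx_cfg, seed = derive_seed(seed, 3L))
    set.seed(derive_seed(seed, 4L))
    params$mlp <- list(
      W1 = matrix(rnorm(in_dim * fus_cfg$mlp_hidden, 0, sqrt(2 / in_dim)),
                  in_dim, fus_cfg$mlp_hidden),
      b1 = numeric(fus_cfg$mlp_hidden),
      W2 = matrix(rnorm(fus_cfg$mlp_hidden * fus_cfg$n_classes, 0,
                        sqrt(2 / fus_cfg$mlp_hidden)),
                  fus_cfg$mlp_hidden, fus_cfg$n_classes),
      b2 = numeric(fus_cfg$n_classes))
  })
  structure(list(enc_cfg = enc_cfg, tx_cfg = tx_cfg, fus_cfg = fus_cfg,
                 input_edge = as.integer(input_edge), token_dim = d_tok,
                 params = params, stats = stats, seed = as.integer(seed)),
            class = "adfuse_model")
}

#' Number of trainable parameters
#' @param model an `adfuse_model`.
#' @return Integer count.
#' @export
n_params <- function(model) length(flatten_params(model$params))

#' @export
print.adfuse_model <- function(x, ...) {
  cat(sprintf("<adfuse_model> ablation=%s, input %d^3, %d feature maps -> %d tokens of dim %d\n",
              x$fus_cfg$ablation, x$input_edge, x$enc_cfg$final_filters,
              x$enc_cfg$final_filters, x$token_dim))
  cat(sprintf("  %s trainable parameters\n", format(n_params(x), big.mark = ",")))
  invisible(x)
}

# Stack subject volumes of one modality into a (g,g,g,1,B) array.
stack_volumes <- function(subjects, modality) {
  g <- dim(subjects[[1]][[modality]]$data)
  x <- array(0, c(g, 1L, length(subjects)))
  for (i in seq_along(subjects)) x[, , , 1L, i] <- subjects[[i]][[modality]]$data
  x
}

# Full batched forward pass. xs/xp: (g,g,g,1,B). Returns logits, probs,
# per-modality attention stacks (list of L arrays (N,N,H,B)), cache, and
# updated BN stats.
model_forward <- function(model, xs, xp, training = FALSE) {
  fus <- model$fus_cfg
  B <- dim(xs)[5]
  es <- enc_forward(xs, model$params$enc_smri, model$stats$enc_smri,
                    model$enc_cfg, training)
  ep <- enc_forward(xp, model$params$enc_pet, model$stats$enc_pet,
                    model$enc_cfg, training)
  stats <- list(enc_smri = es$stats, enc_pet = ep$stats)
  tok_s <- maps_to_tokens(es$out)
  tok_p <- maps_to_tokens(ep$out)
  N <- dim(tok_s)[1]; d <- dim(tok_s)[2]
  attn <- NULL
  tx_cache <- NULL
  if (fus$ablation != "cnn_only") {
    cfgt <- model$tx_cfg
    attn <- list(smri = rep(list(array(0, c(N, N, cfgt$H, B))), cfgt$L),
                 pet = rep(list(array(0, c(N, N, cfgt$H, B))), cfgt$L))
    tx_cache <- list(smri = vector("list", B), pet = vector("list", B))
    out_s <- tok_s; out_p <- tok_p
    for (b in seq_len(B)) {
      fs <- tx_forward_one(tok_s[, , b], model$params$tx, cfgt)
      fp <- tx_forward_one(tok_p[, , b], model$params$tx, cfgt)
      out_s[, , b] <- fs$out
      out_p[, , b] <- fp$out
      tx_cache$smri[[b]] <- fs$cache
      tx_cache$pet[[b]] <- fp$cache
      for (l in seq_len(cfgt$L)) {
        attn$smri[[l]][, , , b] <- fs$attn[[l]]
        attn$pet[[l]][, , , b] <- fp$attn[[l]]
      }
    }
  } else {
    out_s <- tok_s; out_p <- tok_p
  }
  feat <- t(rbind(matrix(out_s, N * d, B), matrix(out_p, N * d, B)))
  mlp <- model$params$mlp
  Z1 <- feat %*% mlp$W1 + matrix(mlp$b1, B, length(mlp$b1), byrow = TRUE)
  H1 <- pmax(Z1, 0)
  dp1 <- dropout_fwd(H1, fus$dropout_p, training)
  Z2 <- dp1$y %*% mlp$W2 + matrix(mlp$b2, B, length(mlp$b2), byrow = TRUE)
  dp2 <- dropout_fwd(Z2, fus$dropout_p, training)
  logits <- dp2$y
  m <- apply(logits, 1L, max)
  probs <- exp(logits - m)
  probs <- probs / rowSums(probs)
  cache <- list(enc_s = es$cache, enc_p = ep$cache, tok_s = tok_s,
                tok_p = tok_p, out_s = out_s, out_p = out_p,
                mapdim = dim(es$out), feat = feat, Z1 = Z1, dp1 = dp1,
                dp2 = dp2, tx = tx_cache, B = B, N = N, d = d)
  list(logits = logits, probs = probs, attn = attn, cache = cache,
       stats = stats)
}

# Backward pass from d(loss)/d(logits); returns gradients shaped like
# model$params.
model_backward <- function(model, cache, glogits) {
  fus <- model$fus_cfg
  mlp <- model$params$mlp
  B <- cache$B; N <- cache$N; d <- cache$d
  g <- dropout_bwd(glogits, cache$dp2$mask)
  gmlp <- list(W1 = NULL, b1 = NULL, W2 = t(cache$dp1$y) %*% g, b2 = colSums(g))
  gH1 <- g %*% t(mlp$W2)
  gH1 <- dropout_bwd(gH1, cache$dp1$mask)
  gZ1 <- gH1 * (cache$Z1 > 0)
  gmlp$W1 <- t(cache$feat) %*% gZ1
  gmlp$b1 <- colSums(gZ1)
  gfeat <- gZ1 %*% t(mlp$W1)
  gout_s <- array(t(gfeat[, seq_len(N * d), drop = FALSE]), c(N, d, B))
  gout_p <- array(t(gfeat[, N * d + seq_len(N * d), drop = FALSE]), c(N, d, B))
  grads <- list()
  if (fus$ablation != "cnn_only") {
    cfgt <- model$tx_cfg
    gtx <- zero_like(model$params$tx)
    gtok_s <- gout_s; gtok_p <- gout_p
    for (b in seq_len(B)) {
      bs <- tx_backward_one(cache$tx$smri[[b]], gout_s[, , b],
                            model$params$tx, cfgt, gtx)
      gtx <- bs$acc
      gtok_s[, , b] <- bs$gx
      bp <- tx_backward_one(cache$tx$pet[[b]], gout_p[, , b],
                            model$params$tx, cfgt, gtx)
      gtx <- bp$acc
      gtok_p[, , b] <- bp$gx
    }
    grads$tx <- gtx
  } else {
    gtok_s <- gout_s; gtok_p <- gout_p
  }
  gm_s <- tokens_to_maps(gtok_s, cache$mapdim)
  gm_p <- tokens_to_maps(gtok_p, cache$mapdim)
  grads$enc_smri <- enc_backward(cache$enc_s, gm_s, model$params$enc_smri)$grads
  grads$enc_pet <- enc_backward(cache$enc_p, gm_p, model$params$enc_pet)$grads
  grads$mlp <- gmlp
  grads[names(model$params)]
}

#' Forward one subject through the model
#'
#' Runs the model in eval mode (batch-norm running moments, no dropout) and
#' returns the prediction: class probabilities, the argmax label, and the
#' per-modality attention stacks for rollout.
#'
#' @param model an `adfuse_model` (see [assemble_model()]).
#' @param subj a [subject()] with normalized volumes matching the model's
#'   input edge.
#' @return An `adfuse_prediction`: list with `probs` (named, sums to 1),
#'   `label`, and `attention` (per modality, a list of `L` arrays
#'   `(N, N, H)`; `NULL` under the `cnn_only` ablation).
#' @export
forward_fused <- function(model, subj) {
  rng <- range(subj$smri$data, subj$pet$data)
  if (rng[1] < 0 || rng[2] > 1)
    warning("forward_fused: subject intensities outside [0, 1]; expected normalized volumes")
  xs <- array(subj$smri$data, c(dim(subj$smri$data), 1L, 1L))
  xp <- array(subj$pet$data, c(dim(subj$pet$data), 1L, 1L))
  fw <- model_forward(model, xs, xp, training = FALSE)
  cls <- model_classes(model)
  probs <- as.numeric(fw$probs[1L, ])
  names(probs) <- cls
  attn <- NULL
  if (!is.null(fw$attn)) {
    drop_b <- function(stack) lapply(stack, function(a) array(a, dim(a)[1:3]))
    attn <- list(smri = drop_b(fw$attn$smri), pet = drop_b(fw$attn$pet))
  }
  structure(list(probs = probs, label = cls[which.max(probs)],
                 attention = attn), class = "adfuse_prediction")
}

#' Categorical cross-entropy loss
#'
#' `-log p(true class)`, with probabilities floored at machine epsilon so a
#' degenerate zero probability yields a large finite loss rather than `Inf`.
#'
#' @param pred an `adfuse_prediction`, or a probability vector/matrix (rows
#'   summing to 1).
#' @param label true class label(s): `"AD"`/`"CN"` or 1-based column index.
#' @return Mean loss over the supplied samples (nonnegative scalar).
#' @export
cross_entropy_loss <- function(pred, label) {
  p <- if (inherits(pred, "adfuse_prediction")) matrix(pred$probs, nrow = 1)
       else if (is.matrix(pred)) pred else matrix(pred, nrow = 1)
  if (is.character(label)) label <- match(label, c("AD", "CN"))
  pt <- pmax(p[cbind(seq_len(nrow(p)), label)], .Machine$double.eps)
  mean(-log(pt))
}

# Batched eval-mode prediction over a list of subjects. Returns a matrix of
# probabilities (columns AD, CN) and predicted labels.
predict_model <- function(model, subjects, batch_size = 8L) {
  n <- length(subjects)
  probs <- matrix(0, n, model$fus_cfg$n_classes,
                  dimnames = list(NULL, model_classes(model)))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xs <- stack_volumes(subjects[idx], "smri")
    xp <- stack_volumes(subjects[idx], "pet")
    fw <- model_forward(model, xs, xp, training = FALSE)
    probs[idx, ] <- fw$probs
  }
  list(probs = probs, labels = model_classes(model)[max.col(probs, "first")])
}
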