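#' Configuration of the gated Transformer encoder
#'
#' A stack of `L` pre-normalized encoder blocks. Each block applies
#' multi-head self-attention whose Q/K/V projections are 1x1x1 convolutions
#' over the feature-map channels (per-voxel channel mixing), a residual
#' connection gated by a learnable scalar `alpha` (0 at initialization,
#' clamped to `[0, 1]` after every optimizer step, so attention is unmasked
#' progressively during training), then a two-layer feed-forward network with
#' an ungated residual. No positional embedding is added: the convolutional
#' projections carry position information. The `typical` flavor (linear Q/K/V
#' projections, learned positional embeddings, ungated residual with
#' `alpha = 1`) is available for ablation.
#'
#' @param L number of encoder blocks.
#' @param H number of attention heads; must divide `d`.
#' @param d token embedding dimension (flattened feature-map voxels; 8 for
#'   2x2x2 maps).
#' @param D hidden width of the feed-forward network (default `4 * d`).
#' @param n_tokens token count (one per feature map).
#' @param scale_dim dimension used in the `1/sqrt(d)` attention scaling:
#'   `"head"` (per-head key dimension, default) or `"token"` (full `d`).
#' @param linear_qkv use plain linear `d x d/H` projections instead of the
#'   convolutional channel-mixing ones.
#' @param positional add a learned `n_tokens x d` positional embedding.
#' @param gated gate the attention residual by learnable `alpha`; when
#'   `FALSE`, `alpha` is fixed at 1.
#' @return A `transformer_config` list.
#' @export
transformer_config <- function(L = 2L, H = 4L, d = 8L, D = 4L * d,
                               n_tokens = 200L, scale_dim = c("head", "token"),
                               linear_qkv = FALSE, positional = FALSE,
                               gated = TRUE) {
  scale_dim <- match.arg(scale_dim)
  if (d %% H != 0L)
    stop(sprintf("transformer_config: token dim %d not divisible by %d heads", d, H))
  structure(list(L = as.integer(L), H = as.integer(H), d = as.integer(d),
                 D = as.integer(D), n_tokens = as.integer(n_tokens),
                 scale_dim = scale_dim, linear_qkv = isTRUE(linear_qkv),
                 positional = isTRUE(positional), gated = isTRUE(gated)),
            class = "transformer_config")
}

attn_scale <- function(cfg) sqrt(if (cfg$scale_dim == "head") cfg$d / cfg$H else cfg$d)

#' Initialize transformer parameters
#'
#' @param cfg a [transformer_config()].
#' @param seed integer seed.
#' @return Nested parameter list (`layers`, optionally `pos`).
#' @export
init_transformer_params <- function(cfg, seed = 1L) {
  N <- cfg$n_tokens; d <- cfg$d; dh <- d %/% cfg$H
  with_local_seed(seed, {
    layers <- lapply(seq_len(cfg$L), function(l) {
      heads <- lapply(seq_len(cfg$H), function(h) {
        if (cfg$linear_qkv)
          list(Wq = matrix(rnorm(d * dh, 0, 1 / sqrt(d)), d, dh),
               Wk = matrix(rnorm(d * dh, 0, 1 / sqrt(d)), d, dh),
               Wv = matrix(rnorm(d * dh, 0, 1 / sqrt(d)), d, dh))
        else
          list(Wq = matrix(rnorm(N * N, 0, 1 / sqrt(N)), N, N),
               Wk = matrix(rnorm(N * N, 0, 1 / sqrt(N)), N, N),
               Wv = matrix(rnorm(N * N, 0, 1 / sqrt(N)), N, N))
      })
      lay <- list(ln1_gamma = rep(1, d), ln1_beta = numeric(d), heads = heads,
                  ln2_gamma = rep(1, d), ln2_beta = numeric(d),
                  W1 = matrix(rnorm(d * cfg$D, 0, sqrt(2 / d)), d, cfg$D),
                  b1 = numeric(cfg$D),
                  W2 = matrix(rnorm(cfg$D * d, 0, sqrt(2 / cfg$D)), cfg$D, d),
                  b2 = numeric(d))
      if (cfg$gated) lay$alpha <- 0
      lay
    })
    p <- list(layers = layers)
    if (cfg$positional) p$pos <- matrix(rnorm(N * d, 0, 0.02), N, d)
    p
  })
}

head_slice <- function(h, dh) ((h - 1L) * dh + 1L):(h * dh)

#' Convolutional Q/K/V projection for one head
#'
#' The 1x1x1 convolution over feature-map channels is, per voxel, a linear
#' mix of the `N` channels: with tokens as rows, `Conv(X) = W %*% X` with `W`
#' an `N x N` matrix. Head `i` keeps its `d/H`-column slice of the result.
#'
#' @param maps a `feature_map_set` (from [encode_volume()]) or an `N x d`
#'   token matrix.
#' @param weights list with `Wq`, `Wk`, `Wv`, each `N x N`.
#' @param head head index in `1..n_heads`, or `NULL` for the full projection.
#' @param n_heads total head count.
#' @return List of `Q`, `K`, `V` matrices (`N x d/n_heads`, or `N x d` when
#'   `head` is `NULL`).
#' @export
project_qkv_conv <- function(maps, weights, head = NULL, n_heads = 4L) {
  X <- if (inherits(maps, "feature_map_set")) {
    d <- dim(maps$maps)
    t(matrix(maps$maps, prod(d[1:3]), d[4]))
  } else as.matrix(maps)
  d <- ncol(X)
  sl <- if (is.null(head)) seq_len(d) else {
    if (d %% n_heads != 0L)
      stop("project_qkv_conv: token dim not divisible by head count")
    head_slice(head, d %/% n_heads)
  }
  list(Q = (weights$Wq %*% X)[, sl, drop = FALSE],
       K = (weights$Wk %*% X)[, sl, drop = FALSE],
       V = (weights$Wv %*% X)[, sl, drop = FALSE])
}

#' Scaled dot-product attention for a single head
#'
#' `Attention(Q, K, V) = SoftMax(Q K^T / sqrt(d)) V`. Both the output tokens
#' and the row-stochastic attention matrix are returned (the latter feeds
#' attention rollout).
#'
#' @param Q,K,V conformable matrices (`N x d_head`).
#' @param d scaling dimension (defaults to `ncol(Q)`).
#' @return List with `output` (`N x d_head`) and `attention` (`N x N`).
#' @export
single_head_attention <- function(Q, K, V, d = ncol(Q)) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V))
    stop("single_head_attention: Q, K, V are not conformable")
  A <- softmax_rows(Q %*% t(K) / sqrt(d))
  list(output = A %*% V, attention = A)
}

#' Multi-head self-attention
#'
#' Runs `H` heads (each with its own convolutional Q/K/V projection) on one
#' token matrix and concatenates the head outputs, restoring dimension `d`.
#'
#' @param X `N x d` token matrix.
#' @param layer_params one layer's parameter list (fields `heads`), e.g.
#'   `init_transformer_params(cfg)$layers[[1]]`.
#' @param cfg a [transformer_config()].
#' @return List with `output` (`N x d`) and `attention` (`N x N x H` array).
#' @export
multi_head_attention <- function(X, layer_params, cfg) {
  N <- nrow(X); d <- ncol(X); dh <- d %/% cfg$H
  O <- matrix(0, N, d)
  A <- array(0, c(N, N, cfg$H))
  for (h in seq_len(cfg$H)) {
    hp <- layer_params$heads[[h]]
    qkv <- if (cfg$linear_qkv)
      list(Q = X %*% hp$Wq, K = X %*% hp$Wk, V = X %*% hp$Wv)
    else project_qkv_conv(X, hp, head = h, n_heads = cfg$H)
    sh <- single_head_attention(qkv$Q, qkv$K, qkv$V, d = attn_scale(cfg)^2)
    O[, head_slice(h, dh)] <- sh$output
    A[, , h] <- sh$attention
  }
  list(output = O, attention = A)
}

#' Gated residual connection
#'
#' `X' = alpha * O + X`: the attention branch `O` is scaled by the learnable
#' gate `alpha` before the residual addition, so a freshly initialized block
#' (`alpha = 0`) passes its input through unchanged.
#'
#' @param O attention output tokens.
#' @param X block input tokens (same shape).
#' @param alpha scalar gate in `[0, 1]`.
#' @return `alpha * O + X`.
#' @export
gated_residual <- function(O, X, alpha) {
  if (!identical(dim(O), dim(X)))
    stop("gated_residual: O and X must have the same shape")
  alpha * O + X
}

#' Position-wise feed-forward network
#'
#' `FFN(X) = max(0, X W1 + b1) W2 + b2`. The surrounding residual connection
#' is added by the encoder block, not here.
#'
#' @param X `N x d` token matrix.
#' @param W1 `d x D` weight; `b1` length-`D` bias.
#' @param W2 `D x d` weight; `b2` length-`d` bias.
#' @return `N x d` matrix.
#' @export
feed_forward <- function(X, W1, b1, W2, b2) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(W1) || ncol(W1) != nrow(W2) || ncol(W2) != ncol(X))
    stop("feed_forward: weight shapes do not match the token dimension")
  h <- pmax(X %*% W1 + matrix(b1, nrow(X), length(b1), byrow = TRUE), 0)
  h %*% W2 + matrix(b2, nrow(X), length(b2), byrow = TRUE)
}

# Forward through the transformer stack for one sample (N x d matrix).
# Returns output tokens, the per-layer/per-head attention (list of N x N x H),
# and a cache for backprop.
tx_forward_one <- function(X, params, cfg) {
  N <- nrow(X); d <- ncol(X); dh <- d %/% cfg$H
  sc <- attn_scale(cfg)
  if (cfg$positional) X <- X + params$pos
  layers <- vector("list", cfg$L)
  attn <- vector("list", cfg$L)
  drop_msa <- isTRUE(cfg$drop_msa)   # internal ablation hooks used to verify
  drop_ffn <- isTRUE(cfg$drop_ffn)   # gate-masking equivalences exactly
  for (l in seq_len(cfg$L)) {
    lp <- params$layers[[l]]
    alpha <- if (cfg$gated) lp$alpha else 1
    ln1 <- layernorm_fwd(X, lp$ln1_gamma, lp$ln1_beta)
    Xn <- ln1$y
    heads <- vector("list", cfg$H)
    O <- matrix(0, N, d)
    A <- array(0, c(N, N, cfg$H))
    for (h in if (drop_msa) integer(0) else seq_len(cfg$H)) {
      hp <- lp$heads[[h]]
      sl <- head_slice(h, dh)
      if (cfg$linear_qkv) {
        Qh <- Xn %*% hp$Wq; Kh <- Xn %*% hp$Wk; Vh <- Xn %*% hp$Wv
      } else {
        Qh <- (hp$Wq %*% Xn)[, sl, drop = FALSE]
        Kh <- (hp$Wk %*% Xn)[, sl, drop = FALSE]
        Vh <- (hp$Wv %*% Xn)[, sl, drop = FALSE]
      }
      Ah <- softmax_rows(Qh %*% t(Kh) / sc)
      O[, sl] <- Ah %*% Vh
      A[, , h] <- Ah
      heads[[h]] <- list(Q = Qh, K = Kh, V = Vh, A = Ah)
    }
    X1 <- if (drop_msa) X else alpha * O + X
    ln2 <- layernorm_fwd(X1, lp$ln2_gamma, lp$ln2_beta)
    Z1 <- ln2$y %*% lp$W1 + matrix(lp$b1, N, cfg$D, byrow = TRUE)
    Hh <- pmax(Z1, 0)
    Fo <- Hh %*% lp$W2 + matrix(lp$b2, N, d, byrow = TRUE)
    Xout <- if (drop_ffn) X1 else X1 + Fo
    layers[[l]] <- list(ln1 = ln1$cache, Xn = Xn, heads = heads, O = O,
                        X = X, X1 = X1, ln2 = ln2$cache, Xn2 = ln2$y,
                        Z1 = Z1, Hh = Hh, alpha = alpha)
    attn[[l]] <- A
    X <- Xout
  }
  list(out = X, attn = attn, cache = layers)
}

# Backward for tx_forward_one. Accumulates parameter gradients into `acc`
# (same structure as params, created by zero_like if NULL).
tx_backward_one <- function(cache, gout, params, cfg, acc) {
  d <- cfg$d; dh <- d %/% cfg$H
  sc <- attn_scale(cfg)
  gX <- gout
  drop_msa <- isTRUE(cfg$drop_msa)
  drop_ffn <- isTRUE(cfg$drop_ffn)
  for (l in rev(seq_len(cfg$L))) {
    ly <- cache[[l]]
    lp <- params$layers[[l]]
    ga <- acc$layers[[l]]
    if (drop_ffn) {
      gX1 <- gX
    } else {
      # FFN sub-block: Xout = X1 + FFN(LN2(X1))
      gFo <- gX
      ga$W2 <- ga$W2 + t(ly$Hh) %*% gFo
      ga$b2 <- ga$b2 + colSums(gFo)
      gHh <- gFo %*% t(lp$W2)
      gZ1 <- gHh * (ly$Z1 > 0)
      ga$W1 <- ga$W1 + t(ly$Xn2) %*% gZ1
      ga$b1 <- ga$b1 + colSums(gZ1)
      gXn2 <- gZ1 %*% t(lp$W1)
      lnb <- layernorm_bwd(gXn2, ly$ln2)
      ga$ln2_gamma <- ga$ln2_gamma + lnb$ggamma
      ga$ln2_beta <- ga$ln2_beta + lnb$gbeta
      gX1 <- gX + lnb$gx
    }
    if (drop_msa) {
      gX <- gX1
      acc$layers[[l]] <- ga
      next
    }
    # gated residual: X1 = alpha * O + X
    if (cfg$gated) ga$alpha <- ga$alpha + sum(ly$O * gX1)
    gO <- ly$alpha * gX1
    gXn <- matrix(0, nrow(gX1), d)
    for (h in seq_len(cfg$H)) {
      hc <- ly$heads[[h]]
      hp <- lp$heads[[h]]
      sl <- head_slice(h, dh)
      gOh <- gO[, sl, drop = FALSE]
      gA <- gOh %*% t(hc$V)
      gV <- t(hc$A) %*% gOh
      gS <- softmax_rows_bwd(gA, hc$A)
      gQ <- gS %*% hc$K / sc
      gK <- t(gS) %*% hc$Q / sc
      if (cfg$linear_qkv) {
        ga$heads[[h]]$Wq <- ga$heads[[h]]$Wq + t(ly$Xn) %*% gQ
        ga$heads[[h]]$Wk <- ga$heads[[h]]$Wk + t(ly$Xn) %*% gK
        ga$heads[[h]]$Wv <- ga$heads[[h]]$Wv + t(ly$Xn) %*% gV
        gXn <- gXn + gQ %*% t(hp$Wq) + gK %*% t(hp$Wk) + gV %*% t(hp$Wv)
      } else {
        Xsl <- ly$Xn[, sl, drop = FALSE]
        ga$heads[[h]]$Wq <- ga$heads[[h]]$Wq + gQ %*% t(Xsl)
        ga$heads[[h]]$Wk <- ga$heads[[h]]$Wk + gK %*% t(Xsl)
        ga$heads[[h]]$Wv <- ga$heads[[h]]$Wv + gV %*% t(Xsl)
        gXn[, sl] <- gXn[, sl] + t(hp$Wq) %*% gQ + t(hp$Wk) %*% gK +
          t(hp$Wv) %*% gV
      }
    }
    lnb <- layernorm_bwd(gXn, ly$ln1)
    ga$ln1_gamma <- ga$ln1_gamma + lnb$ggamma
    ga$ln1_beta <- ga$ln1_beta + lnb$gbeta
    gX <- gX1 + lnb$gx
    acc$layers[[l]] <- ga
  }
  if (cfg$positional) acc$pos <- acc$pos + gX
  list(gx = gX, acc = acc)
}

#' Run the transformer encoder stack on one set of feature maps
#'
#' Tokenizes the feature maps (one token per map, voxels flattened), applies
#' the `L` pre-normalized gated encoder blocks, and records every layer's
#' per-head attention matrix for rollout.
#'
#' @param maps a `feature_map_set` from [encode_volume()], or an `N x d`
#'   token matrix.
#' @param cfg a [transformer_config()].
#' @param params output of [init_transformer_params()] (or a trained model's
#'   transformer slice).
#' @return List with `tokens` (`N x d` output matrix) and `attention` — the
#'   attention stack, a list of `L` arrays of shape `(N, N, H)`.
#' @export
encoder_stack <- function(maps, cfg, params) {
  X <- if (inherits(maps, "feature_map_set")) {
    dd <- dim(maps$maps)
    t(matrix(maps$maps, prod(dd[1:3]), dd[4]))
  } else as.matrix(maps)
  if (nrow(X) != cfg$n_tokens || ncol(X) != cfg$d)
    stop(sprintf("encoder_stack: got %d tokens of dim %d, config expects %d x %d",
                 nrow(X), ncol(X), cfg$n_tokens, cfg$d))
  fw <- tx_forward_one(X, params, cfg)
  list(tokens = fw$out, attention = fw$attn)
}
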