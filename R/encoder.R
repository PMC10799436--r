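#' Configuration of the per-modality 3D convolutional encoder
#'
#' The encoder stacks `n_blocks` blocks of (3D convolution, batch
#' normalization, ReLU, 2x2x2 max pooling) and ends with one standalone
#' convolution (+ BN + ReLU) that sets the feature-map count. With the
#' defaults, a 64^3 input contracts by 2^5 to 2x2x2 and yields 200 feature
#' maps — one token of dimension 8 per map downstream.
#'
#' @param n_blocks number of conv+pool blocks.
#' @param filters output channel count of each block's convolution.
#' @param kernel convolution kernel edge (odd; 'same' padding).
#' @param conv_stride convolution stride (1 by default; pooling performs the
#'   spatial contraction).
#' @param pool pooling window and stride.
#' @param final_filters channels of the last standalone convolution.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(n_blocks = 5L, filters = c(15L, 30L, 60L, 120L, 160L),
                           kernel = 3L, conv_stride = 1L, pool = 2L,
                           final_filters = 200L) {
  if (length(filters) != n_blocks)
    stop("encoder_config: `filters` must have one entry per block")
  if (kernel %% 2L == 0L) stop("encoder_config: kernel edge must be odd")
  structure(list(n_blocks = as.integer(n_blocks), filters = as.integer(filters),
                 kernel = as.integer(kernel), conv_stride = as.integer(conv_stride),
                 pool = as.integer(pool), final_filters = as.integer(final_filters)),
            class = "encoder_config")
}

# Spatial extent after the encoder for a cubic input of edge g.
encoder_out_edge <- function(cfg, g) {
  for (i in seq_len(cfg$n_blocks)) {
    g <- ceiling(g / cfg$conv_stride)
    if (g %% cfg$pool != 0L)
      stop(sprintf("encoder: spatial extent %d at block %d not divisible by pool %d",
                   g, i, cfg$pool))
    g <- g %/% cfg$pool
  }
  g <- ceiling(g / cfg$conv_stride)
  if (g < 1L) stop("encoder: input too small for the configured depth")
  g
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

#' Initialize encoder parameters
#'
#' He-normal weights, zero biases, unit BN scale. Deterministic given `seed`.
#'
#' @param cfg an [encoder_config()].
#' @param in_channels input channel count (1 for a raw volume).
#' @param seed integer seed.
#' @return List with `params` (weights) and `stats` (BN running moments).
#' @export
init_encoder_params <- function(cfg, in_channels = 1L, seed = 1L) {
  k <- cfg$kernel
  with_local_seed(seed, {
    chans <- c(in_channels, cfg$filters)
    blocks <- lapply(seq_len(cfg$n_blocks), function(i) {
      ci <- chans[i]; co <- chans[i + 1]
      list(W = he_init(c(k, k, k, ci, co), k^3 * ci), b = numeric(co),
           bn_gamma = rep(1, co), bn_beta = numeric(co))
    })
    ci <- cfg$filters[cfg$n_blocks]; co <- cfg$final_filters
    final <- list(W = he_init(c(k, k, k, ci, co), k^3 * ci), b = numeric(co),
                  bn_gamma = rep(1, co), bn_beta = numeric(co))
    stats <- lapply(c(cfg$filters, cfg$final_filters), function(co)
      list(mean = numeric(co), var = rep(1, co)))
    list(params = list(blocks = blocks, final = final), stats = stats)
  })
}

# Forward pass through the encoder. x: (nx,ny,nz,C_in,B). Returns output maps,
# a cache for backprop, and updated BN running stats.
enc_forward <- function(x, params, stats, cfg, training = FALSE) {
  layers <- vector("list", cfg$n_blocks + 1L)
  for (i in seq_len(cfg$n_blocks)) {
    p <- params$blocks[[i]]
    z <- conv3d_fwd(x, p$W, p$b, cfg$conv_stride)
    bn <- bn_fwd(z, p$bn_gamma, p$bn_beta, stats[[i]], training)
    stats[[i]] <- bn$stats
    a <- relu_fwd(bn$y)
    mp <- maxpool_fwd(a, cfg$pool)
    layers[[i]] <- list(x = x, z = z, bn = bn$cache, a = a,
                        argmax = mp$argmax, adim = dim(a))
    x <- mp$y
  }
  p <- params$final
  z <- conv3d_fwd(x, p$W, p$b, cfg$conv_stride)
  i <- cfg$n_blocks + 1L
  bn <- bn_fwd(z, p$bn_gamma, p$bn_beta, stats[[i]], training)
  stats[[i]] <- bn$stats
  y <- relu_fwd(bn$y)
  layers[[i]] <- list(x = x, z = z, bn = bn$cache, a = y)
  list(out = y, cache = list(layers = layers, cfg = cfg), stats = stats)
}

# Backward pass. gout matches enc_forward()$out. Returns gradients in the
# structure of `params` plus the gradient w.r.t. the input.
enc_backward <- function(cache, gout, params) {
  cfg <- cache$cfg
  i <- cfg$n_blocks + 1L
  ly <- cache$layers[[i]]
  g <- relu_bwd(gout, ly$a)
  bnb <- bn_bwd(g, ly$bn)
  cb <- conv3d_bwd(ly$x, params$final$W, bnb$gx, cfg$conv_stride)
  gfinal <- list(W = cb$gw, b = cb$gb, bn_gamma = bnb$ggamma, bn_beta = bnb$gbeta)
  g <- cb$gx
  gblocks <- vector("list", cfg$n_blocks)
  for (i in rev(seq_len(cfg$n_blocks))) {
    ly <- cache$layers[[i]]
    g <- maxpool_bwd(g, ly$argmax, ly$adim)
    g <- relu_bwd(g, ly$a)
    bnb <- bn_bwd(g, ly$bn)
    cb <- conv3d_bwd(ly$x, params$blocks[[i]]$W, bnb$gx, cfg$conv_stride)
    gblocks[[i]] <- list(W = cb$gw, b = cb$gb, bn_gamma = bnb$ggamma,
                         bn_beta = bnb$gbeta)
    g <- cb$gx
  }
  list(grads = list(blocks = gblocks, final = gfinal), gx = g)
}

#' One convolution + batch-norm + ReLU block
#'
#' Computes `ReLU(BN(conv3d(x, W, b)))` with 'same' padding. With `bn =
#' NULL` the normalization is skipped (plain `ReLU(conv)`).
#'
#' @param x input maps: a 4D array `(nx, ny, nz, channels)` or a 5D array
#'   with a trailing batch dimension.
#' @param W kernel array `(k, k, k, in_channels, out_channels)`.
#' @param b bias vector of length `out_channels`.
#' @param bn optional list with `gamma` and `beta` (and optionally `mean`,
#'   `var` for eval-mode moments; batch moments are used otherwise).
#' @param stride convolution stride.
#' @return Output maps with the same number of dimensions as `x`.
#' @export
conv3d_block <- function(x, W, b, bn = NULL, stride = 1L) {
  was4 <- length(dim(x)) == 4L
  if (was4) dim(x) <- c(dim(x), 1L)
  z <- conv3d_fwd(x, W, b, stride)
  if (!is.null(bn)) {
    if (!is.null(bn$mean)) {
      st <- list(mean = bn$mean, var = bn$var)
      z <- bn_fwd(z, bn$gamma, bn$beta, st, training = FALSE)$y
    } else {
      st <- list(mean = numeric(dim(z)[4]), var = rep(1, dim(z)[4]))
      z <- bn_fwd(z, bn$gamma, bn$beta, st, training = TRUE)$y
    }
  }
  y <- relu_fwd(z)
  if (was4) dim(y) <- dim(y)[1:4]
  y
}

#' Max pooling over non-overlapping cubic windows
#'
#' @param x 4D `(nx, ny, nz, channels)` or 5D (with batch) array; spatial
#'   dims must be divisible by `window`.
#' @param window pooling window edge (equals the stride).
#' @return Pooled array; spatial dims divided by `window`.
#' @export
max_pool <- function(x, window = 2L) {
  was4 <- length(dim(x)) == 4L
  if (was4) dim(x) <- c(dim(x), 1L)
  y <- maxpool_fwd(x, window)$y
  if (was4) dim(y) <- dim(y)[1:4]
  y
}

#' Encode a volume into feature maps
#'
#' Runs the full encoder (eval mode) on one normalized volume and returns a
#' `feature_map_set`: `final_filters` nonnegative feature maps of small
#' spatial extent (200 maps of 2x2x2 under the defaults on a 64^3 input).
#'
#' @param vol an [volume()] (or 3D array) with intensities in `[0, 1]`.
#' @param cfg an [encoder_config()].
#' @param params output of [init_encoder_params()] (or the matching slice of
#'   a trained model).
#' @param modality tag stored on the result (`"smri"` or `"pet"`).
#' @return A `feature_map_set`: list with `maps` `(dx, dy, dz, n_feat)` and
#'   `modality`.
#' @export
encode_volume <- function(vol, cfg, params, modality = "smri") {
  v <- as_volume(vol)
  if (min(v$data) < 0 || max(v$data) > 1)
    warning("encode_volume: input intensities fall outside [0, 1]; did you normalize?")
  g <- dim(v$data)
  if (length(unique(g)) != 1L)
    stop("encode_volume: expected a cubic volume")
  encoder_out_edge(cfg, g[1])  # errors early with layer-by-layer context
  x <- array(v$data, c(g, 1L, 1L))
  out <- enc_forward(x, params$params, params$stats, cfg, training = FALSE)$out
  structure(list(maps = array(out, dim(out)[1:4]), modality = modality),
            class = "feature_map_set")
}

# (N tokens, d, B) from encoder output maps (dx,dy,dz,C,B): token n is the
# flattened spatial content of channel n.
maps_to_tokens <- function(maps) {
  d <- dim(maps)
  S <- prod(d[1:3])
  aperm(array(maps, c(S, d[4], d[5])), c(2, 1, 3))
}

tokens_to_maps <- function(tok, mapdim) {
  array(aperm(tok, c(2, 1, 3)), mapdim)
}
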