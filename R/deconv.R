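#' Deconvolution (decoder) training configuration
#'
#' Defaults follow the visualization protocol the decoder was designed with:
#' Adam, batch 20, 3000 epochs, learning rate 1e-4 halving every 500 epochs,
#' nearest-neighbour upsampling, mean-squared-error reconstruction loss.
#'
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param lr initial learning rate.
#' @param lr_decay_every epochs between decays.
#' @param lr_decay_factor multiplicative decay factor.
#' @param seed integer seed.
#' @return A `deconv_config` list.
#' @export
deconv_config <- function(epochs = 3000L, batch_size = 20L, lr = 1e-4,
                          lr_decay_every = 500L, lr_decay_factor = 0.5,
                          seed = 1L) {
  stopifnot(epochs >= 0, batch_size >= 1, lr > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_decay_every = as.integer(lr_decay_every),
                 lr_decay_factor = lr_decay_factor, seed = as.integer(seed)),
            class = "deconv_config")
}

#' Build a deconvolution decoder mirroring an encoder
#'
#' The decoder inverts the encoder's geometry: a convolution at the feature
#' resolution, then per encoder block one nearest-neighbour 2x upsampling
#' followed by a convolution (ReLU activations; the last convolution outputs
#' a single linear channel at the original resolution). It maps a
#' `feature_map_set` back to image space and is trained to reconstruct the
#' encoder's input.
#'
#' @param enc_cfg the paired [encoder_config()].
#' @param modality modality tag this decoder is trained for.
#' @param seed integer seed for weight initialization.
#' @return An `adfuse_decoder` object.
#' @export
build_deconv <- function(enc_cfg, modality = "smri", seed = 1L) {
  k <- enc_cfg$kernel
  chans <- c(enc_cfg$final_filters, rev(enc_cfg$filters), 1L)
  with_local_seed(seed, {
    layers <- lapply(seq_len(length(chans) - 1L), function(i) {
      ci <- chans[i]; co <- chans[i + 1]
      list(W = he_init(c(k, k, k, ci, co), k^3 * ci), b = numeric(co))
    })
    structure(list(enc_cfg = enc_cfg, modality = modality, layers = layers,
                   pool = enc_cfg$pool),
              class = "adfuse_decoder")
  })
}

# Decoder forward. x: (dx,dy,dz,F,B). First conv at feature resolution, then
# (upsample, conv) per block; ReLU everywhere except the final output conv.
deconv_forward <- function(dec, x) {
  nl <- length(dec$layers)
  cache <- vector("list", nl)
  for (i in seq_len(nl)) {
    if (i > 1L) x <- cpp_upsample_nn_fwd(x, dec$pool)
    z <- conv3d_fwd(x, dec$layers[[i]]$W, dec$layers[[i]]$b, 1L)
    y <- if (i < nl) relu_fwd(z) else z
    cache[[i]] <- list(x = x, z = z)
    x <- y
  }
  list(out = x, cache = cache)
}

deconv_backward <- function(dec, cache, gout) {
  nl <- length(dec$layers)
  grads <- vector("list", nl)
  g <- gout
  for (i in rev(seq_len(nl))) {
    if (i < nl) g <- relu_bwd(g, cache[[i]]$z)
    cb <- conv3d_bwd(cache[[i]]$x, dec$layers[[i]]$W, g, 1L)
    grads[[i]] <- list(W = cb$gw, b = cb$gb)
    g <- cb$gx
    if (i > 1L) g <- cpp_upsample_nn_bwd(g, dec$pool)
  }
  grads
}

#' Train a deconvolution decoder against a frozen encoder
#'
#' Encodes the supplied volumes once with the frozen encoder (eval mode),
#' then trains the decoder by Adam to minimize the mean squared error
#' between `decoder(encoder(x))` and `x`, under the [deconv_config()]
#' learning-rate schedule.
#'
#' @param dec an `adfuse_decoder` from [build_deconv()].
#' @param enc_params encoder parameters+stats (e.g.
#'   `list(params = model$params$enc_smri, stats = model$stats$enc_smri)`
#'   or the result of [init_encoder_params()]).
#' @param volumes list of [volume()]s (or 3D arrays) of the decoder's
#'   modality.
#' @param cfg a [deconv_config()].
#' @return List with `decoder` (trained), and `history` (epoch, lr, mse).
#' @export
train_deconv <- function(dec, enc_params, volumes, cfg = deconv_config()) {
  g <- dim(as_volume(volumes[[1]])$data)[1]
  n <- length(volumes)
  xs <- array(0, c(g, g, g, 1L, n))
  for (i in seq_len(n)) xs[, , , 1L, i] <- as_volume(volumes[[i]])$data
  feats <- enc_forward(xs, enc_params$params, enc_params$stats, dec$enc_cfg,
                       training = FALSE)$out
  params <- lapply(dec$layers, function(l) list(W = l$W, b = l$b))
  opt <- adam_init(params)
  hist <- vector("list", cfg$epochs)
  with_local_seed(derive_seed(cfg$seed, 23L), {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cfg$lr * cfg$lr_decay_factor^((epoch - 1) %/% cfg$lr_decay_every)
      ord <- sample(n)
      ep_mse <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        dec$layers <- params
        fw <- deconv_forward(dec, feats[, , , , idx, drop = FALSE])
        resid <- fw$out - xs[, , , , idx, drop = FALSE]
        mse <- mean(resid^2)
        ep_mse <- ep_mse + mse * length(idx)
        grads <- deconv_backward(dec, fw$cache, 2 * resid / length(resid))
        step <- adam_step(params, grads, opt, lr)
        params <- step$params
        opt <- step$state
      }
      hist[[epoch]] <- data.frame(epoch = epoch, lr = lr, mse = ep_mse / n)
    }
  })
  dec$layers <- params
  list(decoder = dec, history = do.call(rbind, hist))
}

#' Decode a single feature into image space
#'
#' Zero-masks every feature map except `index` and runs the decoder,
#' producing a salience volume of the encoder's input shape: the image-space
#' footprint of that one feature.
#'
#' @param dec a trained `adfuse_decoder`.
#' @param features a `feature_map_set` (from [encode_volume()]) or a bare
#'   `(dx, dy, dz, n_feat)` array.
#' @param index feature index in `1..n_feat`.
#' @param affine affine to attach to the salience volume.
#' @return A `salience_volume`: an [volume()] with attributes `modality`
#'   and `feature_index`.
#' @export
decode_feature <- function(dec, features, index, affine = diag(4)) {
  maps <- if (inherits(features, "feature_map_set")) features$maps else features
  nf <- dim(maps)[4]
  if (index < 1 || index > nf)
    stop(sprintf("decode_feature: index %d out of range 1..%d", index, nf))
  masked <- array(0, c(dim(maps), 1L))
  masked[, , , index, 1L] <- maps[, , , index]
  out <- deconv_forward(dec, masked)$out
  sal <- volume(array(out, dim(out)[1:3]), affine)
  attr(sal, "modality") <- dec$modality
  attr(sal, "feature_index") <- index
  class(sal) <- c("salience_volume", class(sal))
  sal
}
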