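# Low-level differentiable layer math. Volumetric activations are 5-D arrays
# laid out (x, y, z, channel, batch); token matrices are N x d. Every *_fwd
# returns a cache consumed by the matching *_bwd.

conv3d_fwd <- function(x, w, b, stride = 1L) {
  stopifnot(length(dim(x)) == 5L, length(dim(w)) == 5L)
  if (dim(w)[1] %% 2L == 0L) stop("conv3d: kernel edge must be odd for 'same' padding")
  if (dim(x)[4] != dim(w)[4])
    stop(sprintf("conv3d: input has %d channels but kernel expects %d",
                 dim(x)[4], dim(w)[4]))
  if (length(b) != dim(w)[5]) stop("conv3d: bias length must equal output channels")
  cpp_conv3d_fwd_gemm(x, w, as.numeric(b), as.integer(stride))
}

conv3d_bwd <- function(x, w, gy, stride = 1L) {
  cpp_conv3d_bwd_gemm(x, w, gy, as.integer(stride))
}

# Direct (non-BLAS) reference kernels, kept as independent oracles.
conv3d_fwd_ref <- function(x, w, b, stride = 1L) {
  cpp_conv3d_fwd(x, w, as.numeric(b), as.integer(stride))
}

conv3d_bwd_ref <- function(x, w, gy, stride = 1L) {
  cpp_conv3d_bwd(x, w, gy, as.integer(stride))
}

maxpool_fwd <- function(x, win = 2L) {
  d <- dim(x)
  if (any(d[1:3] %% win != 0L))
    stop(sprintf("max_pool: spatial dims (%s) not divisible by window %d",
                 paste(d[1:3], collapse = "x"), win))
  cpp_maxpool_fwd(x, as.integer(win))
}

maxpool_bwd <- function(gy, argmax, xdim) {
  cpp_maxpool_bwd(gy, argmax, as.integer(xdim))
}

relu_fwd <- function(x) {
  y <- pmax(x, 0)
  dim(y) <- dim(x)
  y
}

relu_bwd <- function(gy, x) {
  g <- gy * (x > 0)
  dim(g) <- dim(x)
  g
}

# Batch normalization over (spatial, batch) per channel. `stats` carries the
# running moments used in eval mode; training mode uses batch moments and
# returns updated running moments.
bn_fwd <- function(x, gamma, beta, stats, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  S <- prod(d[1:3]); C <- d[4]; B <- d[5]
  if (training) {
    xm <- matrix(x, nrow = S)
    sums <- rowSums(matrix(colSums(xm), nrow = C))
    sq <- rowSums(matrix(colSums(xm * xm), nrow = C))
    mu <- sums / (S * B)
    v <- pmax(sq / (S * B) - mu^2, 0)
    stats$mean <- (1 - momentum) * stats$mean + momentum * mu
    stats$var <- (1 - momentum) * stats$var + momentum * v
  } else {
    mu <- stats$mean
    v <- stats$var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (x - rep(mu, each = S)) * rep(istd, each = S)
  y <- xhat * rep(gamma, each = S) + rep(beta, each = S)
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, istd = istd, gamma = gamma, d = d,
                           training = training),
       stats = stats)
}

bn_bwd <- function(gy, cache) {
  d <- cache$d
  S <- prod(d[1:3]); C <- d[4]; B <- d[5]
  xhat <- cache$xhat
  gym <- matrix(gy, nrow = S)
  sum_gy <- rowSums(matrix(colSums(gym), nrow = C))
  sum_gyx <- rowSums(matrix(colSums(gym * matrix(xhat, nrow = S)), nrow = C))
  ggamma <- sum_gyx
  gbeta <- sum_gy
  if (cache$training) {
    m <- S * B
    gx <- rep(cache$gamma * cache$istd, each = S) *
      (gy - rep(sum_gy / m, each = S) - xhat * rep(sum_gyx / m, each = S))
  } else {
    gx <- gy * rep(cache$gamma * cache$istd, each = S)
  }
  dim(gx) <- d
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

# Layer normalization of each token (row) over the embedding dimension.
layernorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  n <- nrow(x); d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  g <- matrix(gamma, n, d, byrow = TRUE)
  y <- xhat * g + matrix(beta, n, d, byrow = TRUE)
  list(y = y, cache = list(xhat = xhat, istd = istd, gamma = gamma))
}

layernorm_bwd <- function(gy, cache) {
  xhat <- cache$xhat
  n <- nrow(gy); d <- ncol(gy)
  g <- matrix(cache$gamma, n, d, byrow = TRUE)
  gxhat <- gy * g
  gx <- cache$istd * (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat))
  list(gx = gx, ggamma = colSums(gy * xhat), gbeta = colSums(gy))
}

softmax_rows <- function(s) {
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  e / rowSums(e)
}

# Backward of row softmax: gS = A * (gA - rowSums(gA * A)).
softmax_rows_bwd <- function(ga, a) {
  a * (ga - rowSums(ga * a))
}

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  mask <- (runif(length(x)) >= p) / (1 - p)
  dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}

dropout_bwd <- function(gy, mask) {
  if (is.null(mask)) gy else gy * mask
}

# Numerically stable softmax cross-entropy on a logit matrix (B x K) with
# 1-based integer class labels. Returns mean loss, probabilities, and the
# gradient of the mean loss w.r.t. the logits.
softmax_xent <- function(logits, labels) {
  B <- nrow(logits)
  m <- apply(logits, 1L, max)
  z <- logits - m
  lse <- log(rowSums(exp(z)))
  logp <- z - lse
  idx <- cbind(seq_len(B), labels)
  loss <- -mean(logp[idx])
  probs <- exp(logp)
  glog <- probs
  glog[idx] <- glog[idx] - 1
  list(loss = loss, probs = probs, glogits = glog / B)
}
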