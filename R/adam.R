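# Adam optimizer over arbitrarily nested parameter lists (leaves are numeric
# vectors/matrices/arrays). Gradient and moment structures mirror the
# parameter structure.

zero_like <- function(p) {
  if (is.list(p)) return(lapply(p, zero_like))
  z <- p
  z[] <- 0
  z
}

map2_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(map2_params, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    return(out)
  }
  f(a, b)
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

# One Adam step with default moments (beta1 = 0.9, beta2 = 0.999, eps = 1e-8).
# Any leaf named "alpha" is clamped to [0, 1] after the update (the gate
# contract: 0 at init, capped at 1).
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v, name = "") {
    if (is.list(p)) {
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]], nm)
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      if (is.null(names(p))) {
        for (i in seq_along(p)) {
          r <- walk(p[[i]], g[[i]], m[[i]], v[[i]], name)
          p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
        }
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p <- p - lr * mhat / (sqrt(vhat) + eps)
    if (identical(name, "alpha")) p <- pmin(pmax(p, 0), 1)
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# Elementwise sum of two gradient structures.
add_grads <- function(a, b) map2_params(a, b, `+`)

# Scale a gradient structure by a scalar.
scale_grads <- function(a, s) {
  if (is.list(a)) return(lapply(a, scale_grads, s = s))
  a * s
}

# Flatten all leaves to one numeric vector (diagnostics / tests).
flatten_params <- function(p) {
  if (is.list(p)) return(unlist(lapply(p, flatten_params), use.names = FALSE))
  as.numeric(p)
}
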