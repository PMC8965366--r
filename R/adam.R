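# Adam optimizer over nested parameter lists (mirrors the parameter
# structure; moment estimates are kept per array).

adam_init <- function(lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L, m = NULL, v = NULL)
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  step <- function(p, g, m, v, name) {
    if (!is.null(name) && name %in% .non_trainable) {
      return(list(p = p, m = m, v = v))
    }
    if (is.list(p)) {
      nm <- names(p)
      if (is.null(m)) { m <- vector("list", length(p)); v <- vector("list", length(p)) }
      for (i in seq_along(p)) {
        r <- step(p[[i]], if (is.null(g)) NULL else g[[i]], m[[i]], v[[i]],
                  if (is.null(nm)) NULL else nm[i])
        # single-bracket assignment: NULL results must not delete elements
        p[i] <- list(r$p); m[i] <- list(r$m); v[i] <- list(r$v)
      }
      return(list(p = p, m = m, v = v))
    }
    if (!is.numeric(p) || is.null(g)) return(list(p = p, m = m, v = v))
    if (is.null(m)) { m <- p * 0; v <- p * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    p <- p - state$lr * (m / bc1) / (sqrt(v / bc2) + state$eps)
    list(p = p, m = m, v = v)
  }
  cls <- class(params)
  r <- step(unclass(params), grads, state$m, state$v, NULL)
  state$m <- r$m; state$v <- r$v
  params <- r$p
  class(params) <- cls
  list(state = state, params = params)
}
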