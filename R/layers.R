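# 3-D network layers over 5-D arrays laid out (x, y, z, channel, sample).
#
# Convolutions are computed as im2col gathers followed by one BLAS matmul;
# the gather index matrices depend only on (edge, kernel, stride, pad) and
# are cached per geometry. Transposed convolution is implemented as the exact
# adjoint of the corresponding strided convolution, so extract/upsample
# geometries stay consistent by construction.

.geom_cache <- new.env(parent = emptyenv())

# Sliding-window geometry on a padded cube. Returns the output edge and the
# (out_voxels x kernel_voxels) matrix of linear spatial indices into the
# padded volume.
conv_geom <- function(edge, k, stride, pad) {
  key <- paste(edge, k, stride, pad, sep = "_")
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  pe <- edge + 2L * pad
  oe <- (pe - k) %/% stride + 1L
  if (oe < 1L) stop("kernel larger than padded input")
  starts <- (seq_len(oe) - 1L) * stride            # 0-based window origins
  o3 <- oe^3L; k3 <- k^3L
  koff <- as.matrix(expand.grid(kx = 0:(k - 1L), ky = 0:(k - 1L), kz = 0:(k - 1L)))
  org <- as.matrix(expand.grid(x = starts, y = starts, z = starts))
  # linear index (1-based) of padded voxel (x,y,z): 1 + x + pe*y + pe^2*z
  idx <- matrix(0L, o3, k3)
  for (j in seq_len(k3)) {
    x <- org[, 1L] + koff[j, 1L]
    y <- org[, 2L] + koff[j, 2L]
    z <- org[, 3L] + koff[j, 3L]
    idx[, j] <- 1L + x + pe * y + pe * pe * z
  }
  g <- list(edge = edge, k = k, stride = stride, pad = pad,
            pe = pe, oe = oe, o3 = o3, k3 = k3, idx = idx)
  .geom_cache[[key]] <- g
  g
}

pad3d <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x); e <- d[1L]; pe <- e + 2L * pad
  out <- array(0, c(pe, pe, pe, d[4L], d[5L]))
  out[pad + seq_len(e), pad + seq_len(e), pad + seq_len(e), , ] <- x
  out
}

crop3d <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x); e <- d[1L] - 2L * pad
  x[pad + seq_len(e), pad + seq_len(e), pad + seq_len(e), , , drop = FALSE]
}

# Full gather index for channels C and batch N: matrix (o3*N) x (k3*C),
# rows ordered voxel-fastest-then-sample, cols kernel-fastest-then-channel.
full_idx <- function(geom, C, N) {
  p3 <- geom$pe^3L
  base <- geom$idx[rep(seq_len(geom$o3), N), rep(seq_len(geom$k3), C), drop = FALSE]
  coff <- rep((seq_len(C) - 1L) * p3, each = geom$k3)
  noff <- rep((seq_len(N) - 1L) * p3 * C, each = geom$o3)
  base + matrix(noff, nrow = geom$o3 * N, ncol = geom$k3 * C) +
    matrix(coff, nrow = geom$o3 * N, ncol = geom$k3 * C, byrow = TRUE)
}

im2col <- function(xpad, geom) {
  d <- dim(xpad)
  ii <- full_idx(geom, d[4L], d[5L])
  matrix(xpad[ii], nrow = nrow(ii))
}

# Adjoint of im2col: scatter-add column values back into a padded volume.
# Uses a cached sparse scatter matrix over the spatial pattern; channels and
# samples are handled as dense columns.
col2im <- function(colmat, geom, C, N) {
  S <- scatter_matrix(geom)
  a <- array(colmat, c(geom$o3, N, geom$k3, C))
  m <- matrix(aperm(a, c(1L, 3L, 4L, 2L)), nrow = geom$o3 * geom$k3)
  out <- as.matrix(S %*% m)
  array(out, c(geom$pe, geom$pe, geom$pe, C, N))
}

scatter_matrix <- function(geom) {
  key <- paste("S", geom$edge, geom$k, geom$stride, geom$pad, sep = "_")
  S <- .geom_cache[[key]]
  if (is.null(S)) {
    S <- Matrix::sparseMatrix(i = as.integer(geom$idx),
                              j = seq_len(geom$o3 * geom$k3),
                              x = 1, dims = c(geom$pe^3L, geom$o3 * geom$k3))
    .geom_cache[[key]] <- S
  }
  S
}

# Reorder between the matmul layout (rows = voxel-then-sample, cols = channel)
# and the 5-D array layout.
mat_to_arr <- function(m, oe, Cout, N) {
  a <- array(m, c(oe^3L, N, Cout))
  array(aperm(a, c(1L, 3L, 2L)), c(oe, oe, oe, Cout, N))
}

arr_to_mat <- function(x) {
  d <- dim(x); o3 <- d[1L] * d[2L] * d[3L]
  a <- aperm(array(x, c(o3, d[4L], d[5L])), c(1L, 3L, 2L))
  matrix(a, nrow = o3 * d[5L])
}

# ---- strided 3-D convolution ----------------------------------------------
# W: (k^3 * Cin) x Cout matrix, kernel index fastest; b: length-Cout bias.
conv3d <- function(x, W, b, stride, pad = 1L, k = 3L) {
  xv <- vof(x); Wv <- vof(W); bv <- vof(b)
  d <- dim(xv); Cin <- d[4L]; N <- d[5L]
  geom <- conv_geom(d[1L], k, stride, pad)
  Xc <- im2col(pad3d(xv, pad), geom)
  Ym <- Xc %*% Wv
  Ym <- sweep(Ym, 2L, bv, `+`)
  val <- mat_to_arr(Ym, geom$oe, ncol(Wv), N)
  need_gx <- is_tp(x)
  tp_op(val, list(x, W, b), function(g) {
    gm <- arr_to_mat(g)
    gx <- if (need_gx) crop3d(col2im(gm %*% t(Wv), geom, Cin, N), pad) else NULL
    list(gx, crossprod(Xc, gm), colSums(gm))
  })
}

# ---- transposed 3-D convolution (stride 2, kernel 3, pad 1, out = 2*in) ----
# Defined as the adjoint of conv3d(k=3, stride=2, pad=1) mapping 2e -> e.
# W: (k^3 * Cout) x Cin matrix; b: length-Cout bias.
convt3d <- function(x, W, b, k = 3L, stride = 2L, pad = 1L) {
  xv <- vof(x); Wv <- vof(W); bv <- vof(b)
  d <- dim(xv); Cin <- d[4L]; N <- d[5L]; e <- d[1L]
  oe <- e * stride
  geom <- conv_geom(oe, k, stride, pad)
  stopifnot(geom$oe == e)
  Cout <- nrow(Wv) %/% (k^3L)
  Um <- arr_to_mat(xv)                       # (e^3*N) x Cin
  colmat <- Um %*% t(Wv)                     # (e^3*N) x (k^3*Cout)
  val <- crop3d(col2im(colmat, geom, Cout, N), pad)
  val <- sweep(val, 4L, bv, `+`)
  need_gx <- is_tp(x)
  tp_op(val, list(x, W, b), function(g) {
    Gc <- im2col(pad3d(g, pad), geom)        # (e^3*N) x (k^3*Cout)
    gx <- if (need_gx) mat_to_arr(Gc %*% Wv, e, Cin, N) else NULL
    gW <- crossprod(Gc, Um)
    gb <- as.numeric(apply(g, 4L, sum))
    list(gx, gW, gb)
  })
}

# ---- batch normalization over (space, sample) per channel ------------------
# In training mode uses batch statistics; running statistics are reported to
# `collect` (an environment) so the optimizer step can refresh them outside
# the tape. In eval mode uses the stored running statistics.
batchnorm3d <- function(x, gamma, beta, rmean, rvar, training,
                        eps = 1e-5, momentum = 0.9, collect = NULL, key = NULL) {
  xv <- vof(x); gv <- vof(gamma); bv <- vof(beta)
  d <- dim(xv); C <- d[4L]
  m <- prod(d) / C                           # elements per channel
  xm <- matrix(aperm(xv, c(1L, 2L, 3L, 5L, 4L)), ncol = C)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2              # population variance
    if (!is.null(collect)) {
      collect[[key]] <- list(rmean = momentum * rmean + (1 - momentum) * mu,
                             rvar  = momentum * rvar  + (1 - momentum) * va)
    }
  } else {
    mu <- rmean; va <- rvar
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2L, mu, `-`), 2L, istd, `*`)
  ym <- sweep(sweep(xhat, 2L, gv, `*`), 2L, bv, `+`)
  back_shape <- function(mm) {               # channel-major matrix -> 5-D
    aperm(array(mm, c(d[1L], d[2L], d[3L], d[5L], d[4L])), c(1L, 2L, 3L, 5L, 4L))
  }
  val <- back_shape(ym)
  tp_op(val, list(x, gamma, beta), function(g) {
    gm <- matrix(aperm(g, c(1L, 2L, 3L, 5L, 4L)), ncol = C)
    ggamma <- colSums(gm * xhat)
    gbeta <- colSums(gm)
    gxh <- sweep(gm, 2L, gv, `*`)
    if (training) {
      # full batch-norm backward through mu and va
      t1 <- sweep(gxh, 2L, colMeans(gxh), `-`)
      t2 <- sweep(xhat, 2L, colMeans(gxh * xhat), `*`)
      gx <- sweep(t1 - t2, 2L, istd, `*`)
    } else {
      gx <- sweep(gxh, 2L, istd, `*`)
    }
    list(back_shape(gx), ggamma, gbeta)
  })
}

# ---- dropout ---------------------------------------------------------------
dropout3d <- function(x, rate, training) {
  if (!training || rate <= 0) return(x)
  xv <- vof(x)
  mask <- array(stats::rbinom(length(xv), 1L, 1 - rate), dim(xv)) / (1 - rate)
  tp_op(xv * mask, list(x), function(g) list(g * mask))
}

# ---- channel concatenation / residual add ---------------------------------
concat_ch <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  da <- dim(av); db <- dim(bv)
  stopifnot(all(da[c(1:3, 5)] == db[c(1:3, 5)]))
  val <- array(0, c(da[1:3], da[4L] + db[4L], da[5L]))
  val[, , , seq_len(da[4L]), ] <- av
  val[, , , da[4L] + seq_len(db[4L]), ] <- bv
  tp_op(val, list(a, b), function(g) {
    list(g[, , , seq_len(da[4L]), , drop = FALSE],
         g[, , , da[4L] + seq_len(db[4L]), , drop = FALSE])
  })
}

# ---- flatten + dense -------------------------------------------------------
flatten5d <- function(x) {                   # (e,e,e,C,N) -> N x features
  xv <- vof(x); d <- dim(xv); f <- prod(d[1:4])
  val <- t(matrix(xv, nrow = f))
  tp_op(val, list(x), function(g) list(array(t(g), d)))
}

dense <- function(x, W, b) {                 # x: N x in, W: in x out
  xv <- vof(x); Wv <- vof(W); bv <- vof(b)
  val <- sweep(xv %*% Wv, 2L, bv, `+`)
  tp_op(val, list(x, W, b), function(g) {
    list(g %*% t(Wv), crossprod(xv, g), colSums(g))
  })
}
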