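# Internal tensor primitives.
#
# Feature maps are dense double arrays with dim = c(H, W, C, N): spatial
# height, width, channels, batch.  Convolution kernels have
# dim = c(kh, kw, C_in, C_out).  Convolutions are lowered to a single BLAS
# matrix multiply via im2col; backward passes reuse the cached patch matrix.
# Everything is double precision; "lossless" reparameterization claims are
# therefore limited by accumulation order, not storage precision.

#' @noRd
as_feature_map <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 4L)
  x
}

# Gather 3x3 (or 1x1) patches into a (kh*kw*C) x (Ho*Wo*N) matrix whose row
# order matches the column-major flattening of a (kh, kw, C_in, C_out) kernel.
#' @noRd
im2col <- function(xp, kh, kw, stride, ho, wo) {
  d <- dim(xp)
  cc <- d[3]; n <- d[4]
  p <- array(0, c(kh, kw, cc, ho, wo, n))
  for (ki in seq_len(kh)) {
    rs <- ki + stride * (seq_len(ho) - 1L)
    for (kj in seq_len(kw)) {
      cs <- kj + stride * (seq_len(wo) - 1L)
      sub <- xp[rs, cs, , , drop = FALSE]
      p[ki, kj, , , , ] <- aperm(sub, c(3L, 1L, 2L, 4L))
    }
  }
  dim(p) <- c(kh * kw * cc, ho * wo * n)
  p
}

#' @noRd
pad_spatial <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

# Forward convolution.  Returns the output map; when `keep_cols` the patch
# matrix and padded-input geometry are attached for the backward pass.
#' @noRd
conv2d <- function(x, w, bias = NULL, stride = 1L, pad = 0L, keep_cols = FALSE) {
  x <- as_feature_map(x)
  d <- dim(x); kd <- dim(w)
  if (kd[3] != d[3]) {
    stop("conv2d: input has ", d[3], " channels but kernel expects ", kd[3])
  }
  kh <- kd[1]; kw <- kd[2]; o <- kd[4]
  xp <- pad_spatial(x, pad)
  ho <- (d[1] + 2L * pad - kh) %/% stride + 1L
  wo <- (d[2] + 2L * pad - kw) %/% stride + 1L
  if (ho < 1L || wo < 1L) stop("conv2d: input spatially smaller than kernel")
  cols <- im2col(xp, kh, kw, stride, ho, wo)
  y <- crossprod(matrix(w, ncol = o), cols)       # o x (ho*wo*n)
  if (!is.null(bias)) y <- y + bias
  y <- aperm(array(y, c(o, ho, wo, d[4])), c(2L, 3L, 1L, 4L))
  if (keep_cols) {
    attr(y, "cols") <- cols
    attr(y, "geom") <- list(kh = kh, kw = kw, stride = stride, pad = pad,
                            ho = ho, wo = wo, in_dim = d)
  }
  y
}

# Gradients of conv2d.  `cols`/`geom` come from the cached forward.
#' @noRd
conv2d_backward <- function(dy, w, cols, geom) {
  kd <- dim(w); o <- kd[4]
  dym <- matrix(aperm(dy, c(3L, 1L, 2L, 4L)), nrow = o)
  dw <- tcrossprod(cols, dym)                      # (kh*kw*C) x o
  dim(dw) <- kd
  db <- rowSums(dym)
  dcols <- matrix(w, ncol = o) %*% dym
  d <- geom$in_dim
  kh <- geom$kh; kw <- geom$kw; pad <- geom$pad; stride <- geom$stride
  dxp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  dim(dcols) <- c(kh, kw, d[3], geom$ho, geom$wo, d[4])
  for (ki in seq_len(kh)) {
    rs <- ki + stride * (seq_len(geom$ho) - 1L)
    for (kj in seq_len(kw)) {
      cs <- kj + stride * (seq_len(geom$wo) - 1L)
      sl <- dcols[ki, kj, , , , , drop = FALSE]
      dim(sl) <- c(d[3], geom$ho, geom$wo, d[4])
      prev <- dxp[rs, cs, , , drop = FALSE]
      dxp[rs, cs, , ] <- prev + aperm(sl, c(2L, 3L, 1L, 4L))
    }
  }
  dx <- if (pad > 0L) {
    dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE]
  } else dxp
  list(dx = dx, dw = dw, db = db)
}

# Broadcast a per-channel vector over an (H, W, C, N) map.
#' @noRd
ch_bcast <- function(v, d) {
  array(rep(rep(v, each = d[1] * d[2]), times = d[4]), d)
}

#' @noRd
ch_sum <- function(x) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = d[3])
  colSums(m)
}

# Batch normalization, inference arithmetic: fixed mean/var.
#' @noRd
bn_inference <- function(x, bn) {
  d <- dim(x)
  sd_ <- sqrt(bn$var + bn$eps)
  scale <- bn$gamma / sd_
  shift <- bn$beta - bn$mu * scale
  x * ch_bcast(scale, d) + ch_bcast(shift, d)
}

# Batch normalization with batch statistics (training mode).  Returns the
# normalised map, a cache for the backward pass, and momentum-updated
# running statistics.
#' @noRd
bn_train_forward <- function(x, bn, momentum = 0.1) {
  d <- dim(x)
  m <- d[1] * d[2] * d[4]
  mu <- ch_sum(x) / m
  xc <- x - ch_bcast(mu, d)
  var <- ch_sum(xc * xc) / m
  inv_sd <- 1 / sqrt(var + bn$eps)
  xhat <- xc * ch_bcast(inv_sd, d)
  y <- xhat * ch_bcast(bn$gamma, d) + ch_bcast(bn$beta, d)
  unbias <- if (m > 1L) m / (m - 1L) else 1
  bn$mu <- (1 - momentum) * bn$mu + momentum * mu
  bn$var <- (1 - momentum) * bn$var + momentum * var * unbias
  list(y = y, bn = bn,
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = bn$gamma, m = m))
}

#' @noRd
bn_train_backward <- function(dy, cache) {
  d <- dim(dy)
  dgamma <- ch_sum(dy * cache$xhat)
  dbeta <- ch_sum(dy)
  m <- cache$m
  g <- ch_bcast(cache$gamma * cache$inv_sd, d)
  dx <- g * (dy - ch_bcast(dbeta / m, d) - cache$xhat * ch_bcast(dgamma / m, d))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' @noRd
relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Global average pooling: (H, W, C, N) -> C x N matrix.
#' @noRd
global_avg_pool <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])
  matrix(colMeans(m), nrow = d[3], ncol = d[4])
}

#' @noRd
gap_backward <- function(dpool, d) {
  array(rep(as.vector(dpool), each = d[1] * d[2]) / (d[1] * d[2]), d)
}

#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable softmax cross-entropy.  logits: K x N; labels in 1..K.
# Returns mean loss and d(loss)/d(logits).
#' @noRd
softmax_xent <- function(logits, labels) {
  n <- ncol(logits)
  mx <- apply(logits, 2L, max)
  z <- exp(sweep(logits, 2L, mx))
  p <- sweep(z, 2L, colSums(z), "/")
  idx <- cbind(labels, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}
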