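#' Shuffle-attention parameters
#'
#' Parameters of one shuffle-attention (SA) module acting on `channels`
#' channels split into `groups` groups.  Each group is halved: the first
#' half receives a channel-attention gate computed from global average
#' pooling, the second a spatial-attention gate computed from group
#' normalization.  Parameter vectors have length `channels / (2 * groups)`
#' and are shared across groups.  `groups` is clamped so that this
#' sub-channel width is at least 1 at narrow stages.
#'
#' @param channels Number of channels C (must be divisible by `2 * groups`
#'   after clamping).
#' @param groups Requested group count G (default 32).
#' @return List of class `"sa_params"`: `groups`, gate scale/shift `w1`,
#'   `b1` (channel branch) and `w2`, `b2` (spatial branch), group-norm
#'   affine `gn_gamma`, `gn_beta`, and `eps`.
#' @export
sa_params <- function(channels, groups = 32L) {
  groups <- min(as.integer(groups), channels %/% 2L)
  if (groups < 1L || channels %% (2L * groups) != 0L) {
    stop("sa_params: channels (", channels,
         ") must be divisible by 2 * groups (groups = ", groups, ")")
  }
  l <- channels %/% (2L * groups)
  structure(
    list(channels = as.integer(channels), groups = groups, width = l,
         w1 = rep(0, l), b1 = rep(1, l),
         w2 = rep(0, l), b2 = rep(1, l),
         gn_gamma = rep(1, l), gn_beta = rep(0, l), eps = 1e-5),
    class = "sa_params"
  )
}

#' Channel shuffle
#'
#' Permutes channels by the reshape–transpose trick: channels are viewed as
#' a `groups x (C/groups)` grid and read out transposed, mixing information
#' across groups.  A bijection on channel indices; shape is preserved.
#'
#' @param x Feature map, dim `c(H, W, C, N)`.
#' @param groups Group count; C must be divisible by it.
#' @return Shuffled feature map, same dim.
#' @export
channel_shuffle <- function(x, groups) {
  x <- as_feature_map(x)
  cc <- dim(x)[3]
  x[, , channel_shuffle_perm(cc, groups), , drop = FALSE]
}

# Source index vector: output channel j reads input channel perm[j].
#' @noRd
channel_shuffle_perm <- function(channels, groups) {
  groups <- as.integer(groups)
  if (groups < 1L || channels %% groups != 0L) {
    stop("channel_shuffle: channel count (", channels,
         ") not divisible by groups (", groups, ")")
  }
  as.vector(matrix(seq_len(channels), ncol = groups, byrow = TRUE))
}

#' Shuffle-attention forward pass
#'
#' Splits the input into `G` channel groups and each group into two halves.
#' The first half is gated per channel by
#' `sigmoid(w1 * GAP(x) + b1)`; the second per element by
#' `sigmoid(w2 * GN(x) + b2)` where GN is group normalization (one
#' normalization group over the sub-channels) with affine parameters
#' `gn_gamma`/`gn_beta`.  Halves are re-concatenated, the groups
#' aggregated, and a channel shuffle with two groups cross-swaps the
#' feature information in the channel dimension.  Output shape equals
#' input shape.
#'
#' @param x Feature map, dim `c(H, W, C, N)`.
#' @param params An [sa_params()] for C channels.
#' @return Feature map of identical dim.
#' @export
sa_forward <- function(x, params) {
  sa_forward_cached(x, params)$y
}

# Forward with caches for backprop.  Channel layout within the map:
# group-major, halves contiguous: c = (k-1)*2L + (half-1)*L + l.
#' @noRd
sa_forward_cached <- function(x, params) {
  x <- as_feature_map(x)
  d <- dim(x)
  h <- d[1]; w <- d[2]; cc <- d[3]; n <- d[4]
  g <- params$groups; l <- params$width
  if (cc != params$channels) {
    stop("sa_forward: input has ", cc, " channels, params expect ",
         params$channels)
  }
  xg <- x
  dim(xg) <- c(h, w, l, 2L, g, n)
  x1 <- xg[, , , 1L, , , drop = FALSE]; dim(x1) <- c(h, w, l, g, n)
  x2 <- xg[, , , 2L, , , drop = FALSE]; dim(x2) <- c(h, w, l, g, n)

  # channel branch: gate per (l, k, n) from global average pooling
  s <- matrix(colMeans(matrix(x1, nrow = h * w)), nrow = l)   # l x (g*n)
  a1 <- params$w1 * s + params$b1
  g1 <- sigmoid(a1)                                           # l x (g*n)
  y1 <- x1 * array(rep(as.vector(g1), each = h * w), dim(x1))

  # spatial branch: group norm over (h, w, l) per (k, n), then affine gate
  m <- h * w * l
  x2m <- matrix(x2, nrow = m)                                 # m x (g*n)
  mu <- colMeans(x2m)
  xc <- sweep(x2m, 2L, mu)
  va <- colMeans(xc * xc)
  inv_sd <- 1 / sqrt(va + params$eps)
  xhat <- sweep(xc, 2L, inv_sd, "*")                          # m x (g*n)
  gnb <- rep(params$gn_gamma, each = h * w)                   # length m
  t_ <- xhat * gnb + rep(params$gn_beta, each = h * w)
  a2 <- t_ * rep(params$w2, each = h * w) + rep(params$b2, each = h * w)
  g2 <- sigmoid(a2)
  y2 <- x2m * g2

  yg <- array(0, c(h, w, l, 2L, g, n))
  yg[, , , 1L, , ] <- y1
  yg[, , , 2L, , ] <- array(y2, c(h, w, l, g, n))
  dim(yg) <- d
  perm <- channel_shuffle_perm(cc, 2L)
  y <- yg[, , perm, , drop = FALSE]
  list(y = y,
       cache = list(d = d, l = l, g = g, perm = perm, x1 = x1, s = s, g1 = g1,
                    x2m = x2m, xhat = xhat, inv_sd = inv_sd, t_ = t_, g2 = g2,
                    params = params))
}

# Backward pass; returns dx and parameter gradients.
#' @noRd
sa_backward <- function(dy, cache) {
  d <- cache$d
  h <- d[1]; w <- d[2]; n <- d[4]
  l <- cache$l; g <- cache$g
  p <- cache$params
  inv <- order(cache$perm)
  dyg <- dy[, , inv, , drop = FALSE]
  dim(dyg) <- c(h, w, l, 2L, g, n)
  dy1 <- dyg[, , , 1L, , , drop = FALSE]; dim(dy1) <- c(h, w, l, g, n)
  dy2 <- dyg[, , , 2L, , , drop = FALSE]; dim(dy2) <- c(h * w * l, g * n)

  # channel branch
  g1b <- array(rep(as.vector(cache$g1), each = h * w), dim(cache$x1))
  dx1 <- dy1 * g1b
  dg1 <- matrix(colSums(matrix(dy1 * cache$x1, nrow = h * w)), nrow = l)
  da1 <- dg1 * cache$g1 * (1 - cache$g1)                      # l x (g*n)
  dw1 <- rowSums(da1 * cache$s)
  db1 <- rowSums(da1)
  ds <- da1 * p$w1
  dx1 <- dx1 + array(rep(as.vector(ds), each = h * w) / (h * w), dim(dx1))

  # spatial branch
  m <- h * w * l
  dxm_direct <- dy2 * cache$g2
  dg2 <- dy2 * cache$x2m
  da2 <- dg2 * cache$g2 * (1 - cache$g2)
  w2b <- rep(p$w2, each = h * w)
  # per-sub-channel sums: over the spatial block within each row chunk and
  # over all (group, sample) columns
  sum_per_l <- function(mat) {
    rs <- rowSums(mat)                  # length m, ordered (h*w, l)
    colSums(matrix(rs, nrow = h * w))
  }
  dw2 <- sum_per_l(da2 * cache$t_)
  db2 <- sum_per_l(da2)
  dt <- da2 * w2b
  gnb <- rep(p$gn_gamma, each = h * w)
  dgn_gamma <- sum_per_l(dt * cache$xhat)
  dgn_beta <- sum_per_l(dt)
  dxhat <- dt * gnb
  mean1 <- colMeans(dxhat)
  mean2 <- colMeans(dxhat * cache$xhat)
  dxm_gn <- sweep(dxhat, 2L, mean1) - sweep(cache$xhat, 2L, mean2, "*")
  dxm_gn <- sweep(dxm_gn, 2L, cache$inv_sd, "*")
  dx2 <- dxm_direct + dxm_gn

  dxg <- array(0, c(h, w, l, 2L, g, n))
  dxg[, , , 1L, , ] <- dx1
  dxg[, , , 2L, , ] <- array(dx2, c(h, w, l, g, n))
  dim(dxg) <- d
  list(dx = dxg,
       grads = list(w1 = dw1, b1 = db1, w2 = dw2, b2 = db2,
                    gn_gamma = dgn_gamma, gn_beta = dgn_beta))
}

#' @export
print.sa_params <- function(x, ...) {
  cat(sprintf("Shuffle attention: %d channels, %d groups, sub-channel width %d\n",
              x$channels, x$groups, x$width))
  invisible(x)
}
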