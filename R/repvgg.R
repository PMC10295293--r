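#' Batch-normalization parameter set
#'
#' Per-channel inference-time batch-norm parameters: running mean `mu`,
#' running variance `var`, scale `gamma`, shift `beta`, and `eps`.  The
#' standard deviation used everywhere is `sqrt(var + eps)`.
#'
#' @param channels Number of channels.
#' @param gamma,beta,mu,var Per-channel vectors (recycled if scalar).
#' @param eps Small positive stabilizer (default 1e-5).
#' @return List of class `"bn_params"`.
#' @export
bn_params <- function(channels, gamma = 1, beta = 0, mu = 0, var = 1,
                      eps = 1e-5) {
  if (any(var + eps <= 0)) stop("bn_params: variance + eps must be positive")
  structure(
    list(gamma = rep_len(gamma, channels), beta = rep_len(beta, channels),
         mu = rep_len(mu, channels), var = rep_len(var, channels), eps = eps),
    class = "bn_params"
  )
}

#' Construct a RepVGG block (training form)
#'
#' A RepVGG block sums three batch-normalised branches before a ReLU:
#' a 3x3 convolution (padding 1), a 1x1 convolution (padding 0), and — only
#' when the input and output shapes match (`in_ch == out_ch`, stride 1) —
#' an identity branch consisting of batch norm alone.  Convolutions carry
#' no bias (the batch-norm shift plays that role).  Weights are He-normal
#' initialised from R's global RNG.
#'
#' @param in_ch,out_ch Channel counts.
#' @param stride 1 or 2 (stride 2 downsamples and disables the identity
#'   branch).
#' @return List of class `"repvgg_block"` with `form = "train"`.
#' @seealso [reparameterize()] for conversion to the inference form.
#' @export
repvgg_block <- function(in_ch, out_ch, stride = 1L) {
  if (!stride %in% c(1L, 2L)) stop("repvgg_block: stride must be 1 or 2")
  if (in_ch < 1L || out_ch < 1L) stop("repvgg_block: channel counts must be positive")
  he <- function(kh, kw) {
    array(stats::rnorm(kh * kw * in_ch * out_ch,
                       sd = sqrt(2 / (kh * kw * in_ch))),
          c(kh, kw, in_ch, out_ch))
  }
  has_id <- (in_ch == out_ch) && stride == 1L
  structure(
    list(w3 = he(3L, 3L), bn3 = bn_params(out_ch),
         w1 = he(1L, 1L), bn1 = bn_params(out_ch),
         bn0 = if (has_id) bn_params(in_ch) else NULL,
         stride = as.integer(stride), in_ch = as.integer(in_ch),
         out_ch = as.integer(out_ch), form = "train"),
    class = "repvgg_block"
  )
}

#' Forward pass through a RepVGG block
#'
#' Training form: `ReLU(BN3(conv3(x)) + BN1(conv1(x)) + BN0(x))` with the
#' identity term present only when the block has one; batch norm uses the
#' stored running statistics (inference arithmetic).  Deploy form:
#' `ReLU(conv3(x) + b)`.
#'
#' @param block A `"repvgg_block"` in either form.
#' @param x Feature map, dim `c(H, W, in_ch, N)` (lower-dim inputs are
#'   promoted).
#' @param activation Apply the trailing ReLU (default TRUE); FALSE exposes
#'   the pre-activation sum, useful for equivalence checks.
#' @return Feature map `c(H', W', out_ch, N)`.
#' @export
block_forward <- function(block, x, activation = TRUE) {
  x <- as_feature_map(x)
  if (dim(x)[3] != block$in_ch) {
    stop("block_forward: input has ", dim(x)[3], " channels, block expects ",
         block$in_ch)
  }
  out <- if (identical(block$form, "deploy")) {
    conv2d(x, block$w, block$b, stride = block$stride, pad = 1L)
  } else {
    y <- bn_inference(conv2d(x, block$w3, stride = block$stride, pad = 1L),
                      block$bn3) +
      bn_inference(conv2d(x, block$w1, stride = block$stride, pad = 0L),
                   block$bn1)
    if (!is.null(block$bn0)) {
      y <- y + bn_inference(strided_identity(x, block$stride), block$bn0)
    }
    y
  }
  if (activation) relu(out) else out
}

#' @noRd
strided_identity <- function(x, stride) {
  if (stride == 1L) return(x)
  d <- dim(x)
  x[seq(1L, d[1], by = stride), seq(1L, d[2], by = stride), , , drop = FALSE]
}

#' Fold batch normalization into a preceding convolution
#'
#' Returns the kernel/bias pair `(W', b')` with
#' `W'[,,,o] = gamma_o / sd_o * W[,,,o]` and
#' `b'_o = beta_o - gamma_o * mu_o / sd_o`, `sd = sqrt(var + eps)`, so that
#' `conv(x, W') + b' == BN(conv(x, W))` for every input.
#'
#' @param w Kernel, dim `c(kh, kw, in_ch, out_ch)`.
#' @param bn A [bn_params()] for the `out_ch` channels.
#' @return List with elements `w` and `b`.
#' @export
fuse_conv_bn <- function(w, bn) {
  if (any(!is.finite(bn$var)) || any(bn$var + bn$eps <= 0)) {
    stop("fuse_conv_bn: batch-norm standard deviation must be positive")
  }
  sd_ <- sqrt(bn$var + bn$eps)
  kd <- dim(w)
  scale <- bn$gamma / sd_
  wf <- w * array(rep(scale, each = prod(kd[1:3])), kd)
  list(w = wf, b = bn$beta - bn$gamma * bn$mu / sd_)
}

#' Embed a 1x1 kernel at the centre of a 3x3 kernel
#'
#' Zero-pads a 1x1 convolution kernel to 3x3 so that, with padding 1, it
#' computes the same map the 1x1 convolution computes with padding 0.
#'
#' @param w1 Kernel of spatial size 1x1, dim `c(1, 1, in_ch, out_ch)`.
#' @return Kernel of dim `c(3, 3, in_ch, out_ch)`.
#' @export
pad_1x1_to_3x3 <- function(w1) {
  kd <- dim(w1)
  if (is.null(kd) || length(kd) != 4L || kd[1] != 1L || kd[2] != 1L) {
    stop("pad_1x1_to_3x3: kernel must have spatial size 1x1")
  }
  w3 <- array(0, c(3L, 3L, kd[3], kd[4]))
  w3[2L, 2L, , ] <- w1[1L, 1L, , ]
  w3
}

#' Identity map as a 3x3 convolution kernel
#'
#' The delta kernel `K[c, c]` centred at the 3x3 spatial centre:
#' `conv(x, K, padding = 1)` reproduces `x` exactly.  Expresses the
#' residual branch of a RepVGG block as a convolution so that its batch
#' norm can be folded like the others.
#'
#' @param channels Number of channels C (kernel is C x C).
#' @return Kernel of dim `c(3, 3, channels, channels)`.
#' @export
identity_to_3x3 <- function(channels) {
  k <- array(0, c(3L, 3L, channels, channels))
  for (c_ in seq_len(channels)) k[2L, 2L, c_, c_] <- 1
  k
}

#' Structural reparameterization
#'
#' Converts a multi-branch training-form object into its single-convolution
#' inference (deploy) form.  For a block, the three branches are folded
#' (conv+BN fusion; 1x1 kernel padded to 3x3; identity branch expressed as
#' a delta kernel) and summed into one 3x3 kernel and bias.  The transform
#' is algebraically lossless: training- and deploy-form outputs agree up to
#' floating-point accumulation error.
#'
#' @param x A `"repvgg_block"` or `"repb_net"` in training form.
#' @param ... Unused.
#' @return The same object in deploy form.
#' @export
reparameterize <- function(x, ...) UseMethod("reparameterize")

#' @rdname reparameterize
#' @export
reparameterize.repvgg_block <- function(x, ...) {
  if (identical(x$form, "deploy")) {
    warning("block is already in deploy form; returning unchanged")
    return(x)
  }
  f3 <- fuse_conv_bn(x$w3, x$bn3)
  f1 <- fuse_conv_bn(x$w1, x$bn1)
  w <- f3$w + pad_1x1_to_3x3(f1$w)
  b <- f3$b + f1$b
  if (!is.null(x$bn0)) {
    f0 <- fuse_conv_bn(identity_to_3x3(x$in_ch), x$bn0)
    w <- w + f0$w
    b <- b + f0$b
  }
  structure(
    list(w = w, b = b, stride = x$stride, in_ch = x$in_ch, out_ch = x$out_ch,
         form = "deploy"),
    class = "repvgg_block"
  )
}

#' @export
print.repvgg_block <- function(x, ...) {
  cat(sprintf("RepVGG block [%s]: %d -> %d channels, stride %d%s\n",
              x$form, x$in_ch, x$out_ch, x$stride,
              if (!is.null(x$bn0)) ", identity branch" else ""))
  invisible(x)
}

#' @noRd
block_param_count <- function(block) {
  if (identical(block$form, "deploy")) {
    length(block$w) + length(block$b)
  } else {
    n <- length(block$w3) + length(block$w1) + 4L * block$out_ch
    if (!is.null(block$bn0)) n <- n + 2L * block$in_ch
    as.integer(n)
  }
}
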