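# Independent oracles and fixture builders used across the suite.

# Brute-force direct convolution: quadruple loop, no im2col.  Serves as the
# independent forward oracle for all convolution-based layers.
naive_conv <- function(x, w, bias = NULL, stride = 1, pad = 0) {
  d <- dim(x); kd <- dim(w)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  ho <- (d[1] + 2 * pad - kd[1]) %/% stride + 1
  wo <- (d[2] + 2 * pad - kd[2]) %/% stride + 1
  y <- array(0, c(ho, wo, kd[4], d[4]))
  for (n in seq_len(d[4])) for (o in seq_len(kd[4])) {
    for (i in seq_len(ho)) for (j in seq_len(wo)) {
      acc <- 0
      for (ki in seq_len(kd[1])) for (kj in seq_len(kd[2])) {
        for (c_ in seq_len(d[3])) {
          acc <- acc + xp[(i - 1) * stride + ki, (j - 1) * stride + kj, c_, n] *
            w[ki, kj, c_, o]
        }
      }
      y[i, j, o, n] <- acc + if (is.null(bias)) 0 else bias[o]
    }
  }
  y
}

# Per-channel batch norm with fixed statistics, written as a plain loop.
naive_bn <- function(x, bn) {
  d <- dim(x)
  y <- x
  for (c_ in seq_len(d[3])) {
    sd_ <- sqrt(bn$var[c_] + bn$eps)
    y[, , c_, ] <- bn$gamma[c_] * (x[, , c_, ] - bn$mu[c_]) / sd_ + bn$beta[c_]
  }
  y
}

# Direct-summation histogram similarity, coded independently of the
# vectorised implementation (explicit loop, explicit 0/0 handling).
naive_similarity <- function(g, s) {
  gv <- g$values; sv <- s$values
  total <- 0
  for (i in seq_along(gv)) {
    m <- max(gv[i], sv[i])
    total <- total + if (m == 0) 1 else 1 - abs(gv[i] - sv[i]) / m
  }
  total / length(gv)
}

# A RepVGG block with randomised (non-degenerate) batch-norm statistics, as
# they would look after training.
random_trained_block <- function(in_ch, out_ch, stride) {
  rand_bn <- function(bn) {
    n <- length(bn$gamma)
    bn$gamma <- stats::rnorm(n, 1, 0.3)
    bn$beta <- stats::rnorm(n, 0, 0.3)
    bn$mu <- stats::rnorm(n, 0, 0.5)
    bn$var <- stats::runif(n, 0.2, 2)
    bn
  }
  bl <- repvgg_block(in_ch, out_ch, stride)
  bl$bn3 <- rand_bn(bl$bn3)
  bl$bn1 <- rand_bn(bl$bn1)
  if (!is.null(bl$bn0)) bl$bn0 <- rand_bn(bl$bn0)
  bl
}

# Randomise batch-norm statistics throughout a network (fresh networks have
# mu = 0, var = 1, which would make reparameterization checks too easy).
randomize_network_stats <- function(model) {
  model$branches <- lapply(model$branches, function(branch) {
    lapply(branch, function(stage) {
      stage$blocks <- lapply(stage$blocks, function(bl) {
        b2 <- random_trained_block(bl$in_ch, bl$out_ch, bl$stride)
        b2$w3 <- bl$w3
        b2$w1 <- bl$w1
        b2
      })
      stage
    })
  })
  model
}

tiny_config <- function(bilinear = TRUE, use_sa = TRUE, fusion = "sum",
                        num_classes = 4L, in_channels = 3L) {
  network_config(stage_depths = rep(1L, 5),
                 stage_widths = c(8L, 8L, 16L, 16L, 32L),
                 num_classes = num_classes, input_size = 32L,
                 in_channels = in_channels, bilinear = bilinear,
                 use_sa = use_sa, fusion = fusion)
}

rand_image_batch <- function(size, channels, n) {
  array(stats::rnorm(size * size * channels * n), c(size, size, channels, n))
}
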