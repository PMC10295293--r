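#' Network configuration
#'
#' Architecture hyper-parameters of the bilinear RepVGG recognition
#' network: five stages of RepVGG blocks whose first block downsamples
#' with stride 2, a shuffle-attention module after each stage, two
#' independent (non-weight-sharing) branches when `bilinear = TRUE`,
#' element-wise feature fusion, global average pooling, and a fully
#' connected classifier.
#'
#' The default stage depths (1, 2, 4, 14, 1) and widths
#' (64, 64, 128, 256, 1280) are the A1-scale configuration: at 40 classes
#' they give 12.86 M trainable parameters for a single branch and
#' 25.67 M / 23.07 M (training / deploy form) for the full bilinear model
#' with shuffle attention.
#'
#' @param stage_depths Integer 5-vector: RepVGG blocks per stage.
#' @param stage_widths Integer 5-vector: output channels per stage.
#' @param num_classes Number of identities (default 40).
#' @param input_size Square input side in pixels (default 224); must be
#'   divisible by 32 so that five stride-2 stages land on an integer grid.
#' @param in_channels Input image channels (default 3).
#' @param bilinear Two branches with fused features (TRUE) or a plain
#'   single-branch classifier (FALSE).
#' @param use_sa Embed a shuffle-attention module after each stage.
#' @param fusion `"sum"`, `"product"`, or `"concat"`.
#' @param sa_groups Shuffle-attention group count (default 32, clamped per
#'   stage; see [sa_params()]).
#' @return List of class `"network_config"`.
#' @export
network_config <- function(stage_depths = c(1L, 2L, 4L, 14L, 1L),
                           stage_widths = c(64L, 64L, 128L, 256L, 1280L),
                           num_classes = 40L,
                           input_size = 224L,
                           in_channels = 3L,
                           bilinear = TRUE,
                           use_sa = TRUE,
                           fusion = c("sum", "product", "concat"),
                           sa_groups = 32L) {
  fusion <- match.arg(fusion)
  if (length(stage_depths) != 5L || length(stage_widths) != 5L) {
    stop("network_config: stage_depths and stage_widths must have length 5")
  }
  if (any(stage_depths < 1L) || any(stage_widths < 1L)) {
    stop("network_config: depths and widths must be positive")
  }
  if (num_classes < 2L) stop("network_config: need at least 2 classes")
  if (input_size %% 32L != 0L) {
    stop("network_config: input_size must be divisible by 32")
  }
  structure(
    list(stage_depths = as.integer(stage_depths),
         stage_widths = as.integer(stage_widths),
         num_classes = as.integer(num_classes),
         input_size = as.integer(input_size),
         in_channels = as.integer(in_channels),
         bilinear = isTRUE(bilinear), use_sa = isTRUE(use_sa),
         fusion = fusion, sa_groups = as.integer(sa_groups)),
    class = "network_config"
  )
}

#' Build a recognition network
#'
#' Instantiates the network described by a [network_config()] in training
#' form.  Every stage is a run of RepVGG blocks whose first block has
#' stride 2 (five stages reduce 224 to 7), optionally followed by a
#' shuffle-attention module.  Bilinear networks hold two structurally
#' identical branches with independent weights; their final feature maps
#' are fused, pooled and classified by one fully connected layer.
#'
#' @param config A [network_config()].
#' @param seed Optional integer seed for weight initialisation.
#' @return Object of class `"repb_net"`.
#' @export
build_network <- function(config = network_config(), seed = NULL) {
  stopifnot(inherits(config, "network_config"))
  if (!is.null(seed)) set.seed(seed)
  make_branch <- function() {
    in_ch <- config$in_channels
    stages <- vector("list", 5L)
    for (s in 1:5) {
      width <- config$stage_widths[s]
      blocks <- vector("list", config$stage_depths[s])
      for (b in seq_len(config$stage_depths[s])) {
        blocks[[b]] <- repvgg_block(in_ch, width,
                                    stride = if (b == 1L) 2L else 1L)
        in_ch <- width
      }
      stages[[s]] <- list(
        blocks = blocks,
        sa = if (config$use_sa) sa_params(width, config$sa_groups) else NULL
      )
    }
    stages
  }
  branches <- if (config$bilinear) {
    list(front = make_branch(), side = make_branch())
  } else {
    list(single = make_branch())
  }
  feat <- config$stage_widths[5L]
  fc_in <- if (config$bilinear && config$fusion == "concat") 2L * feat else feat
  classifier <- list(
    w = matrix(stats::rnorm(config$num_classes * fc_in, sd = sqrt(1 / fc_in)),
               nrow = config$num_classes),
    b = rep(0, config$num_classes)
  )
  structure(
    list(config = config, branches = branches, classifier = classifier,
         normalization = list(mean = 0.5, sd = 0.25), form = "train"),
    class = "repb_net"
  )
}

#' Fuse two feature maps
#'
#' Combines the final feature maps of the two branches: element-wise sum
#' (default), element-wise product, or channel concatenation.
#'
#' @param f1,f2 Feature maps of identical dim `c(H, W, C, N)`.
#' @param method `"sum"`, `"product"`, or `"concat"`.
#' @return The fused map (C or 2C channels).
#' @export
fuse_features <- function(f1, f2, method = c("sum", "product", "concat")) {
  method <- match.arg(method)
  f1 <- as_feature_map(f1); f2 <- as_feature_map(f2)
  if (!identical(dim(f1), dim(f2))) {
    stop("fuse_features: feature maps must have identical shape")
  }
  switch(method,
         sum = f1 + f2,
         product = f1 * f2,
         concat = {
           d <- dim(f1)
           out <- array(0, c(d[1], d[2], 2L * d[3], d[4]))
           out[, , seq_len(d[3]), ] <- f1
           out[, , d[3] + seq_len(d[3]), ] <- f2
           out
         })
}

#' @noRd
branch_forward <- function(branch, x) {
  for (stage in branch) {
    for (block in stage$blocks) x <- block_forward(block, x)
    if (!is.null(stage$sa)) x <- sa_forward(x, stage$sa)
  }
  x
}

#' Network forward pass (inference arithmetic)
#'
#' Runs the network on a batch, using running batch-norm statistics
#' (deterministic evaluation mode).  For bilinear networks both inputs are
#' required; single-branch networks take `xa` only.
#'
#' @param model A `"repb_net"`.
#' @param xa,xb Input maps, dim `c(H, W, in_channels, N)` with
#'   `H == W == config$input_size`.
#' @return Class-score matrix, `num_classes x N`.
#' @export
network_forward <- function(model, xa, xb = NULL) {
  cfg <- model$config
  xa <- check_input_size(as_feature_map(xa), cfg)
  if (cfg$bilinear) {
    if (is.null(xb)) stop("network_forward: bilinear model needs two inputs")
    xb <- check_input_size(as_feature_map(xb), cfg)
    fa <- branch_forward(model$branches[[1L]], xa)
    fb <- branch_forward(model$branches[[2L]], xb)
    f <- fuse_features(fa, fb, cfg$fusion)
  } else {
    f <- branch_forward(model$branches[[1L]], xa)
  }
  pooled <- global_avg_pool(f)
  model$classifier$w %*% pooled + model$classifier$b
}

#' @noRd
check_input_size <- function(x, cfg) {
  d <- dim(x)
  if (d[1] != cfg$input_size || d[2] != cfg$input_size) {
    stop("input is ", d[1], "x", d[2], " but the network expects ",
         cfg$input_size, "x", cfg$input_size)
  }
  if (d[3] != cfg$in_channels) {
    stop("input has ", d[3], " channels but the network expects ",
         cfg$in_channels)
  }
  x
}

#' @rdname reparameterize
#' @export
reparameterize.repb_net <- function(x, ...) {
  if (identical(x$form, "deploy")) {
    warning("model is already in deploy form; returning unchanged")
    return(x)
  }
  x$branches <- lapply(x$branches, function(branch) {
    lapply(branch, function(stage) {
      stage$blocks <- lapply(stage$blocks, reparameterize)
      stage
    })
  })
  x$form <- "deploy"
  x
}

#' Count trainable parameters
#'
#' Counts every trainable weight and bias: convolution kernels, batch-norm
#' scale/shift (training form), fused biases (deploy form),
#' shuffle-attention gate and group-norm parameters, and the classifier.
#' Batch-norm running statistics are not trainable and are excluded.
#'
#' @param model A `"repb_net"` or `"repvgg_block"`.
#' @return Integer parameter count.  `format_params()` renders it in
#'   millions to two decimals, the conventional reporting unit.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "repvgg_block")) return(block_param_count(model))
  stopifnot(inherits(model, "repb_net"))
  n <- 0
  for (branch in model$branches) {
    for (stage in branch) {
      for (block in stage$blocks) n <- n + block_param_count(block)
      if (!is.null(stage$sa)) {
        sa <- stage$sa
        n <- n + length(sa$w1) + length(sa$b1) + length(sa$w2) +
          length(sa$b2) + length(sa$gn_gamma) + length(sa$gn_beta)
      }
    }
  }
  as.integer(n + length(model$classifier$w) + length(model$classifier$b))
}

#' @rdname count_parameters
#' @param n Raw parameter count.
#' @export
format_params <- function(n) round(n / 1e6, 2)

#' @export
print.repb_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Bilinear RepVGG recognition network [%s form]\n", x$form))
  cat(sprintf("  branches: %d%s | stages: depths %s, widths %s\n",
              length(x$branches),
              if (cfg$use_sa) " (+ shuffle attention)" else "",
              paste(cfg$stage_depths, collapse = ","),
              paste(cfg$stage_widths, collapse = ",")))
  cat(sprintf("  input %dx%dx%d -> %d classes (fusion: %s)\n",
              cfg$input_size, cfg$input_size, cfg$in_channels,
              cfg$num_classes, if (cfg$bilinear) cfg$fusion else "none"))
  cat(sprintf("  trainable parameters: %s (%.2f M)\n",
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6))
  invisible(x)
}

#' @export
summary.repb_net <- function(object, ...) {
  cfg <- object$config
  rows <- do.call(rbind, lapply(seq_along(object$branches), function(bi) {
    branch <- object$branches[[bi]]
    do.call(rbind, lapply(1:5, function(s) {
      stage <- branch[[s]]
      data.frame(
        branch = names(object$branches)[bi], stage = s,
        blocks = length(stage$blocks),
        width = cfg$stage_widths[s],
        sa = !is.null(stage$sa),
        params = sum(vapply(stage$blocks, block_param_count, numeric(1))) +
          if (!is.null(stage$sa)) 6L * stage$sa$width else 0L
      )
    }))
  }))
  out <- list(layers = rows, total = count_parameters(object),
              form = object$form)
  class(out) <- "summary.repb_net"
  out
}

#' @export
print.summary.repb_net <- function(x, ...) {
  print(x$layers, row.names = FALSE)
  cat(sprintf("form: %s | total trainable parameters: %s (%.2f M)\n",
              x$form, format(x$total, big.mark = ","), x$total / 1e6))
  invisible(x)
}

#' Predict identities from images
#'
#' @param object A `"repb_net"`.
#' @param img_a Image or batch (H x W x C or H x W x C x N), raw \[0, 255\]
#'   intensities; normalised internally with the model's stored statistics.
#' @param img_b Second-view image(s) for bilinear models.
#' @param type `"class"` (argmax index), `"scores"`, or `"prob"` (softmax).
#' @param ... Unused.
#' @return Predicted class indices, or a `num_classes x N` matrix.
#' @export
predict.repb_net <- function(object, img_a, img_b = NULL,
                             type = c("class", "scores", "prob"), ...) {
  type <- match.arg(type)
  xa <- normalize_input(img_a, object$normalization)
  xb <- if (!is.null(img_b)) normalize_input(img_b, object$normalization)
  scores <- network_forward(object, xa, xb)
  switch(type,
         class = apply(scores, 2L, which.max),
         scores = scores,
         prob = apply(scores, 2L, function(s) {
           e <- exp(s - max(s)); e / sum(e)
         }))
}

# Raw [0,255] image -> scaled-and-standardised network input.
#' @noRd
normalize_input <- function(img, norm) {
  x <- as_feature_map(img)
  (x / 255 - norm$mean) / norm$sd
}

#' Save / load a network checkpoint
#'
#' Checkpoints are RDS archives holding the config, the form flag
#' (train/deploy), all named parameter arrays and the normalization
#' statistics.
#'
#' @param model A `"repb_net"`.
#' @param path File path (`.rds`).
#' @return `load_checkpoint` returns the model; `save_checkpoint` the path,
#'   invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "repb_net"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "repb_net")) stop("not a network checkpoint: ", path)
  model
}
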