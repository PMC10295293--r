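#' Cosine-annealed learning rate
#'
#' `lr = lr0 * (1 + cos(pi * epoch / total_epochs)) / 2`: starts at `lr0`
#' at epoch 0 and anneals to 0 at `total_epochs`.
#'
#' @param epoch Current epoch, `0 <= epoch <= total_epochs`.
#' @param total_epochs Schedule length.
#' @param lr0 Initial learning rate.
#' @return The learning rate for `epoch`.
#' @export
cosine_lr <- function(epoch, total_epochs, lr0) {
  if (any(epoch < 0) || any(epoch > total_epochs)) {
    stop("cosine_lr: epoch must lie in [0, total_epochs]")
  }
  lr0 * (1 + cos(pi * epoch / total_epochs)) / 2
}

#' Training configuration
#'
#' Optimisation hyper-parameters: Adam with an initial learning rate of
#' 1e-4 annealed to zero by a half-cosine over the training run, batches
#' of 32, 150 epochs.  Scale `epochs`/`batch_size` down for small
#' experiments.
#'
#' @param lr0 Initial learning rate (default 1e-4).
#' @param epochs Training epochs (default 150).
#' @param batch_size Samples per batch (default 32).
#' @param val_fraction Held-out fraction for the stratified validation
#'   split (default 0.2).
#' @param seed Integer seed controlling the split, shuffling and any
#'   augmentation randomness (default 42).
#' @param augment Optional [augment_config()] applied online to each
#'   training image; `NULL` disables augmentation.
#' @param verbose Print per-epoch progress.
#' @return List of class `"train_config"`.
#' @export
train_config <- function(lr0 = 1e-4, epochs = 150L, batch_size = 32L,
                         val_fraction = 0.2, seed = 42L, augment = NULL,
                         verbose = FALSE) {
  if (lr0 <= 0) stop("train_config: lr0 must be positive")
  if (epochs < 1L) stop("train_config: epochs must be >= 1")
  if (batch_size < 1L) stop("train_config: batch_size must be >= 1")
  if (val_fraction < 0 || val_fraction >= 1) {
    stop("train_config: val_fraction must lie in [0, 1)")
  }
  structure(
    list(lr0 = lr0, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), val_fraction = val_fraction,
         seed = as.integer(seed), augment = augment,
         verbose = isTRUE(verbose)),
    class = "train_config"
  )
}

#' Build paired two-view samples from a manifest
#'
#' Pairs images of the same identity for the two-input network.
#' Strategies:
#' * `"front_side"`: one front and one side image per pair (random
#'   matching of `min(n_front, n_side)` pairs per identity, or all
#'   `n_front * n_side` combinations with `exhaustive = TRUE`);
#' * `"same_view"`: two distinct images of the same identity and view —
#'   the mechanism for running single-view datasets through the two-input
#'   model;
#' * `"fixed"`: deterministic frame-index-ordered front/side matching for
#'   evaluation.
#'
#' Identities with too few images for the strategy are skipped with a
#' warning.  Deterministic given `seed`.
#'
#' @param manifest Data frame with `identity`, `view`, `frame_index`
#'   columns (row order defines the image indices returned).
#' @param strategy Pairing strategy.
#' @param seed Optional integer seed.
#' @param exhaustive All front x side combinations (front_side only).
#' @return Data frame with columns `identity`, `a`, `b` (row indices into
#'   `manifest`), `view_a`, `view_b`.
#' @export
make_pairs <- function(manifest,
                       strategy = c("front_side", "same_view", "fixed"),
                       seed = NULL, exhaustive = FALSE) {
  strategy <- match.arg(strategy)
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (id in unique(manifest$identity)) {
    rows <- which(manifest$identity == id)
    if (strategy %in% c("front_side", "fixed")) {
      f <- rows[manifest$view[rows] == "front"]
      s <- rows[manifest$view[rows] == "side"]
      if (length(f) == 0L || length(s) == 0L) {
        warning("identity ", id, " lacks a front or side image; skipped")
        next
      }
      if (strategy == "fixed") {
        f <- f[order(manifest$frame_index[f])]
        s <- s[order(manifest$frame_index[s])]
        n <- min(length(f), length(s))
        a <- f[seq_len(n)]; b <- s[seq_len(n)]
      } else if (exhaustive) {
        grid <- expand.grid(a = f, b = s)
        a <- grid$a; b <- grid$b
      } else {
        n <- min(length(f), length(s))
        a <- f[sample.int(length(f))][seq_len(n)]
        b <- s[sample.int(length(s))][seq_len(n)]
      }
    } else {
      a <- integer(0); b <- integer(0)
      for (v in unique(manifest$view[rows])) {
        vr <- rows[manifest$view[rows] == v]
        if (length(vr) < 2L) {
          warning("identity ", id, " has fewer than 2 '", v,
                  "' images; skipped for same_view pairing")
          next
        }
        partner <- vapply(seq_along(vr), function(i) {
          vr[-i][sample.int(length(vr) - 1L, 1L)]
        }, integer(1))
        a <- c(a, vr); b <- c(b, partner)
      }
      if (length(a) == 0L) next
    }
    out[[length(out) + 1L]] <- data.frame(
      identity = id, a = a, b = b,
      view_a = manifest$view[a], view_b = manifest$view[b],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(identity = character(), a = integer(), b = integer(),
                      view_a = character(), view_b = character()))
  }
  do.call(rbind, out)
}

#' Assemble in-memory training samples
#'
#' `paired_samples` materialises [make_pairs()] output against a synthetic
#' dataset's image list; `single_samples` turns every image into its own
#' one-input sample for single-branch (non-bilinear) models.
#'
#' @param dataset A [synthetic_dataset()] (list with `images`, `manifest`).
#' @param pairs Data frame from [make_pairs()].
#' @return List of samples, each `list(img_a, img_b, identity)`.
#' @export
paired_samples <- function(dataset, pairs) {
  lapply(seq_len(nrow(pairs)), function(i) {
    list(img_a = dataset$images[[pairs$a[i]]],
         img_b = dataset$images[[pairs$b[i]]],
         identity = pairs$identity[i])
  })
}

#' @rdname paired_samples
#' @export
single_samples <- function(dataset) {
  lapply(seq_len(nrow(dataset$manifest)), function(i) {
    list(img_a = dataset$images[[i]], img_b = NULL,
         identity = dataset$manifest$identity[i])
  })
}

#' @noRd
stack_batch <- function(samples, idx, which = c("img_a", "img_b"),
                        augment = NULL) {
  which <- match.arg(which)
  imgs <- lapply(samples[idx], function(s) {
    im <- s[[which]]
    if (!is.null(augment)) im <- random_augment(im, augment)
    as_feature_map(im)
  })
  d <- dim(imgs[[1L]])
  out <- array(0, c(d[1], d[2], d[3], length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- imgs[[i]]
  out
}

#' Train a recognition network
#'
#' The fitting entry point: trains a `"repb_net"` on labelled samples with
#' Adam under a cosine-annealed learning rate and a softmax cross-entropy
#' objective, using batch statistics in every batch norm and updating the
#' running statistics used at evaluation time.  A stratified fraction of
#' the samples is held out and its accuracy logged each epoch.  Fully
#' deterministic given `config$seed`.
#'
#' @param model A training-form `"repb_net"` from [build_network()].
#' @param samples List of samples (`list(img_a, img_b, identity)`), e.g.
#'   from [paired_samples()]; `img_b` is ignored by single-branch models.
#' @param config A [train_config()].
#' @param val_samples Optional explicit validation set; overrides the
#'   internal split.
#' @return Object of class `"repb_fit"`: the trained `model`, per-epoch
#'   `history` (epoch, lr, train_loss, val_accuracy), the label map
#'   `classes`, final `val_metrics`, and the `config`.
#' @export
train_network <- function(model, samples, config = train_config(),
                          val_samples = NULL) {
  stopifnot(inherits(model, "repb_net"), inherits(config, "train_config"))
  if (!identical(model$form, "train")) {
    stop("train_network: model must be in training form")
  }
  if (length(samples) == 0L) stop("train_network: no training samples")
  set.seed(config$seed)

  classes <- sort(unique(vapply(samples, function(s) as.character(s$identity),
                                character(1))))
  if (length(classes) > model$config$num_classes) {
    stop("train_network: more identities than classifier outputs")
  }
  labels <- match(vapply(samples, function(s) as.character(s$identity),
                         character(1)), classes)

  # dataset intensity statistics on the [0, 1] scale, used to standardise
  px <- unlist(lapply(samples[seq_len(min(64L, length(samples)))],
                      function(s) as.vector(s$img_a))) / 255
  model$normalization <- list(mean = mean(px), sd = max(stats::sd(px), 1e-3))

  if (is.null(val_samples)) {
    val_idx <- integer(0)
    if (config$val_fraction > 0) {
      for (c_ in seq_along(classes)) {
        rows <- which(labels == c_)
        n_val <- max(1L, round(length(rows) * config$val_fraction))
        val_idx <- c(val_idx, rows[sample.int(length(rows), n_val)])
      }
    }
    train_idx <- setdiff(seq_along(samples), val_idx)
    val_samples <- samples[val_idx]
  } else {
    train_idx <- seq_along(samples)
  }

  bilinear <- model$config$bilinear
  n_train <- length(train_idx)
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), val_accuracy = numeric())

  theta <- unlist(param_tree(model), use.names = FALSE)
  adam_m <- numeric(length(theta))
  adam_v <- numeric(length(theta))
  adam_t <- 0L

  for (epoch in seq_len(config$epochs)) {
    lr <- cosine_lr(epoch - 1L, config$epochs, config$lr0)
    order_ <- sample(train_idx)
    losses <- numeric(0)
    for (start in seq(1L, n_train, by = config$batch_size)) {
      idx <- order_[start:min(start + config$batch_size - 1L, n_train)]
      xa <- normalize_input(
        stack_batch(samples, idx, "img_a", config$augment),
        model$normalization)
      xb <- if (bilinear) {
        normalize_input(stack_batch(samples, idx, "img_b", config$augment),
                        model$normalization)
      }
      fwd <- net_forward_cached(model, xa, xb)
      model <- fwd$model                      # running BN stats advanced
      ce <- softmax_xent(fwd$logits, labels[idx])
      losses <- c(losses, ce$loss)
      grads <- net_backward_cached(model, fwd$cache, ce$dlogits)
      g <- unlist(grad_tree(grads, model), use.names = FALSE)
      theta <- unlist(param_tree(model), use.names = FALSE)
      adam_t <- adam_t + 1L
      adam_m <- 0.9 * adam_m + 0.1 * g
      adam_v <- 0.999 * adam_v + 0.001 * g * g
      mhat <- adam_m / (1 - 0.9^adam_t)
      vhat <- adam_v / (1 - 0.999^adam_t)
      theta <- theta - lr * mhat / (sqrt(vhat) + 1e-8)
      model <- set_param_tree(model, tree_relist(theta, param_tree(model)))
    }
    val_acc <- if (length(val_samples) > 0L) {
      evaluate_network(model, val_samples, classes = classes)$accuracy
    } else NA_real_
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss = mean(losses),
      val_accuracy = val_acc))
    if (config$verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  val acc %s",
                      epoch, lr, mean(losses),
                      ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
    }
  }

  val_metrics <- if (length(val_samples) > 0L) {
    evaluate_network(model, val_samples, classes = classes)
  }
  structure(
    list(model = model, history = history, classes = classes,
         val_metrics = val_metrics, config = config),
    class = "repb_fit"
  )
}

#' Evaluate a network on labelled samples
#'
#' Deterministic evaluation: forward passes in inference mode, argmax over
#' class scores, macro-averaged metrics.  Train-form and deploy-form
#' versions of the same model give identical reports (reparameterization
#' equivalence).
#'
#' @param model A `"repb_net"` in either form.
#' @param samples List of samples (`list(img_a, img_b, identity)`).
#' @param classes Character vector mapping class index to identity label;
#'   defaults to the sorted identities present.
#' @param batch_size Evaluation batch size (default 32).
#' @return A [classification_metrics()] report.
#' @export
evaluate_network <- function(model, samples, classes = NULL,
                             batch_size = 32L) {
  ids <- vapply(samples, function(s) as.character(s$identity), character(1))
  if (is.null(classes)) classes <- sort(unique(ids))
  labels <- match(ids, classes)
  if (anyNA(labels)) stop("evaluate_network: sample identity not in classes")
  bilinear <- model$config$bilinear
  preds <- integer(length(samples))
  for (start in seq(1L, length(samples), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(samples))
    xa <- normalize_input(stack_batch(samples, idx, "img_a"),
                          model$normalization)
    xb <- if (bilinear) {
      normalize_input(stack_batch(samples, idx, "img_b"), model$normalization)
    }
    scores <- network_forward(model, xa, xb)
    preds[idx] <- apply(scores, 2L, which.max)
  }
  classification_metrics(
    confusion_counts(preds, labels, length(classes)))
}

#' @export
print.repb_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("Trained recognition network: %d classes, %d epochs\n",
              length(x$classes), nrow(h)))
  cat(sprintf("  final train loss %.4f | held-out accuracy %s\n",
              h$train_loss[nrow(h)],
              ifelse(is.na(h$val_accuracy[nrow(h)]), "-",
                     sprintf("%.3f", h$val_accuracy[nrow(h)]))))
  invisible(x)
}

#' @export
summary.repb_fit <- function(object, ...) {
  cat("Model:\n")
  print(object$model)
  cat("\nHeld-out metrics:\n")
  if (!is.null(object$val_metrics)) print(object$val_metrics)
  else cat("  (no validation split)\n")
  invisible(object)
}

#' @export
plot.repb_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
       ylab = "training loss", main = "Loss", ...)
  plot(h$epoch, h$val_accuracy, type = "l", xlab = "epoch",
       ylab = "held-out accuracy", ylim = c(0, 1), main = "Accuracy", ...)
  invisible(x)
}

#' @export
predict.repb_fit <- function(object, img_a, img_b = NULL,
                             type = c("identity", "class", "scores", "prob"),
                             ...) {
  type <- match.arg(type)
  if (type == "identity") {
    idx <- predict(object$model, img_a, img_b, type = "class")
    object$classes[idx]
  } else {
    predict(object$model, img_a, img_b, type = type)
  }
}

#' @export
coef.repb_fit <- function(object, ...) {
  unlist(param_tree(object$model), use.names = FALSE)
}
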