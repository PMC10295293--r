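# Training-mode forward/backward passes.
#
# The training forward mirrors the inference forward but uses batch
# statistics in every batch-norm (updating the running statistics in
# place, functionally) and records per-layer caches.  The backward pass
# walks the caches in reverse and produces a gradient tree whose shape
# mirrors param_tree(model); gradients are checked against central finite
# differences in the test suite.

#' @noRd
block_forward_cached <- function(block, x) {
  c3 <- conv2d(x, block$w3, stride = block$stride, pad = 1L, keep_cols = TRUE)
  g3 <- attr(c3, "geom"); k3 <- attr(c3, "cols")
  attributes(c3)[c("cols", "geom")] <- NULL
  b3 <- bn_train_forward(c3, block$bn3)
  c1 <- conv2d(x, block$w1, stride = block$stride, pad = 0L, keep_cols = TRUE)
  g1 <- attr(c1, "geom"); k1 <- attr(c1, "cols")
  attributes(c1)[c("cols", "geom")] <- NULL
  b1 <- bn_train_forward(c1, block$bn1)
  pre <- b3$y + b1$y
  b0 <- NULL
  if (!is.null(block$bn0)) {
    b0 <- bn_train_forward(x, block$bn0)
    pre <- pre + b0$y
  }
  block$bn3 <- b3$bn
  block$bn1 <- b1$bn
  if (!is.null(b0)) block$bn0 <- b0$bn
  mask <- pre > 0
  list(y = relu(pre), block = block,
       cache = list(cols3 = k3, geom3 = g3, bn3 = b3$cache,
                    cols1 = k1, geom1 = g1, bn1 = b1$cache,
                    bn0 = if (!is.null(b0)) b0$cache, mask = mask))
}

#' @noRd
block_backward_cached <- function(block, cache, dy) {
  dpre <- dy * cache$mask
  g3 <- bn_train_backward(dpre, cache$bn3)
  c3 <- conv2d_backward(g3$dx, block$w3, cache$cols3, cache$geom3)
  g1 <- bn_train_backward(dpre, cache$bn1)
  c1 <- conv2d_backward(g1$dx, block$w1, cache$cols1, cache$geom1)
  dx <- c3$dx + c1$dx
  grads <- list(w3 = c3$dw, g3 = g3$dgamma, b3 = g3$dbeta,
                w1 = c1$dw, g1 = g1$dgamma, b1 = g1$dbeta)
  if (!is.null(cache$bn0)) {
    g0 <- bn_train_backward(dpre, cache$bn0)
    dx <- dx + g0$dx
    grads$g0 <- g0$dgamma
    grads$b0 <- g0$dbeta
  }
  list(dx = dx, grads = grads)
}

#' @noRd
branch_forward_cached <- function(branch, x) {
  caches <- vector("list", length(branch))
  for (s in seq_along(branch)) {
    blocks <- branch[[s]]$blocks
    bl_caches <- vector("list", length(blocks))
    for (b in seq_along(blocks)) {
      out <- block_forward_cached(blocks[[b]], x)
      x <- out$y
      blocks[[b]] <- out$block
      bl_caches[[b]] <- out$cache
    }
    branch[[s]]$blocks <- blocks
    sa_cache <- NULL
    if (!is.null(branch[[s]]$sa)) {
      out <- sa_forward_cached(x, branch[[s]]$sa)
      x <- out$y
      sa_cache <- out$cache
    }
    caches[[s]] <- list(blocks = bl_caches, sa = sa_cache)
  }
  list(y = x, branch = branch, caches = caches)
}

#' @noRd
branch_backward_cached <- function(branch, caches, dy) {
  grads <- vector("list", length(branch))
  for (s in rev(seq_along(branch))) {
    stage_grads <- list()
    if (!is.null(caches[[s]]$sa)) {
      out <- sa_backward(dy, caches[[s]]$sa)
      dy <- out$dx
      stage_grads$sa <- out$grads
    }
    blocks <- branch[[s]]$blocks
    bl_grads <- vector("list", length(blocks))
    for (b in rev(seq_along(blocks))) {
      out <- block_backward_cached(blocks[[b]], caches[[s]]$blocks[[b]], dy)
      dy <- out$dx
      bl_grads[[b]] <- out$grads
    }
    stage_grads$blocks <- bl_grads
    grads[[s]] <- stage_grads
  }
  list(dx = dy, grads = grads)
}

# Full training-mode forward: returns logits, caches, and the model with
# updated batch-norm running statistics.
#' @noRd
net_forward_cached <- function(model, xa, xb = NULL) {
  cfg <- model$config
  if (cfg$bilinear) {
    oa <- branch_forward_cached(model$branches[[1L]], xa)
    ob <- branch_forward_cached(model$branches[[2L]], xb)
    model$branches[[1L]] <- oa$branch
    model$branches[[2L]] <- ob$branch
    f <- fuse_features(oa$y, ob$y, cfg$fusion)
    fuse_cache <- list(fa = oa$y, fb = ob$y)
    caches <- list(oa$caches, ob$caches)
  } else {
    oa <- branch_forward_cached(model$branches[[1L]], xa)
    model$branches[[1L]] <- oa$branch
    f <- oa$y
    fuse_cache <- NULL
    caches <- list(oa$caches)
  }
  pooled <- global_avg_pool(f)
  logits <- model$classifier$w %*% pooled + model$classifier$b
  list(logits = logits, model = model,
       cache = list(branch = caches, fuse = fuse_cache, pooled = pooled,
                    fdim = dim(f)))
}

#' @noRd
net_backward_cached <- function(model, cache, dlogits) {
  cfg <- model$config
  dw_fc <- tcrossprod(dlogits, cache$pooled)
  db_fc <- rowSums(dlogits)
  dpooled <- crossprod(model$classifier$w, dlogits)
  df <- gap_backward(dpooled, cache$fdim)
  branch_grads <- vector("list", length(model$branches))
  if (cfg$bilinear) {
    cw <- cfg$stage_widths[5L]
    if (cfg$fusion == "sum") {
      dfa <- df; dfb <- df
    } else if (cfg$fusion == "product") {
      dfa <- df * cache$fuse$fb
      dfb <- df * cache$fuse$fa
    } else {
      dfa <- df[, , seq_len(cw), , drop = FALSE]
      dfb <- df[, , cw + seq_len(cw), , drop = FALSE]
    }
    oa <- branch_backward_cached(model$branches[[1L]], cache$branch[[1L]], dfa)
    ob <- branch_backward_cached(model$branches[[2L]], cache$branch[[2L]], dfb)
    branch_grads[[1L]] <- oa$grads
    branch_grads[[2L]] <- ob$grads
  } else {
    oa <- branch_backward_cached(model$branches[[1L]], cache$branch[[1L]], df)
    branch_grads[[1L]] <- oa$grads
  }
  list(branches = branch_grads, fc = list(w = dw_fc, b = db_fc))
}

# Trainable parameters of the model as a nested list whose leaves are the
# arrays Adam updates; structure matches the gradient tree exactly.
#' @noRd
param_tree <- function(model) {
  branches <- lapply(model$branches, function(branch) {
    lapply(branch, function(stage) {
      st <- list()
      if (!is.null(stage$sa)) {
        sa <- stage$sa
        st$sa <- list(w1 = sa$w1, b1 = sa$b1, w2 = sa$w2, b2 = sa$b2,
                      gn_gamma = sa$gn_gamma, gn_beta = sa$gn_beta)
      }
      st$blocks <- lapply(stage$blocks, function(bl) {
        g <- list(w3 = bl$w3, g3 = bl$bn3$gamma, b3 = bl$bn3$beta,
                  w1 = bl$w1, g1 = bl$bn1$gamma, b1 = bl$bn1$beta)
        if (!is.null(bl$bn0)) {
          g$g0 <- bl$bn0$gamma
          g$b0 <- bl$bn0$beta
        }
        g
      })
      st
    })
  })
  list(branches = branches,
       fc = list(w = model$classifier$w, b = model$classifier$b))
}

# Reorder a gradient tree to param_tree order (sa before blocks) so that
# unlist() flattens both identically.
#' @noRd
grad_tree <- function(grads, model) {
  branches <- lapply(seq_along(grads$branches), function(bi) {
    lapply(seq_along(grads$branches[[bi]]), function(si) {
      sg <- grads$branches[[bi]][[si]]
      st <- list()
      if (!is.null(sg$sa)) st$sa <- sg$sa
      st$blocks <- sg$blocks
      st
    })
  })
  list(branches = branches, fc = grads$fc)
}

# Inverse of unlist() for a parameter tree; restores array dims (which
# utils::relist drops for arrays of rank > 2).
#' @noRd
tree_relist <- function(flesh, skeleton) {
  if (is.list(skeleton)) {
    ind <- 0L
    out <- skeleton
    for (i in seq_along(skeleton)) {
      size <- length(unlist(skeleton[[i]], use.names = FALSE))
      out[[i]] <- tree_relist(flesh[ind + seq_len(size)], skeleton[[i]])
      ind <- ind + size
    }
    out
  } else {
    attributes(flesh) <- attributes(skeleton)
    flesh
  }
}

#' @noRd
set_param_tree <- function(model, tree) {
  for (bi in seq_along(model$branches)) {
    for (si in seq_along(model$branches[[bi]])) {
      st <- tree$branches[[bi]][[si]]
      if (!is.null(st$sa)) {
        sa <- model$branches[[bi]][[si]]$sa
        sa$w1 <- st$sa$w1; sa$b1 <- st$sa$b1
        sa$w2 <- st$sa$w2; sa$b2 <- st$sa$b2
        sa$gn_gamma <- st$sa$gn_gamma; sa$gn_beta <- st$sa$gn_beta
        model$branches[[bi]][[si]]$sa <- sa
      }
      for (b in seq_along(st$blocks)) {
        bl <- model$branches[[bi]][[si]]$blocks[[b]]
        g <- st$blocks[[b]]
        bl$w3 <- g$w3; bl$bn3$gamma <- g$g3; bl$bn3$beta <- g$b3
        bl$w1 <- g$w1; bl$bn1$gamma <- g$g1; bl$bn1$beta <- g$b1
        if (!is.null(bl$bn0)) {
          bl$bn0$gamma <- g$g0
          bl$bn0$beta <- g$b0
        }
        model$branches[[bi]][[si]]$blocks[[b]] <- bl
      }
    }
  }
  model$classifier$w <- tree$fc$w
  model$classifier$b <- tree$fc$b
  model
}
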