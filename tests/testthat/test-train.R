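test_that("cosine annealing follows its closed form", {
  expect_equal(cosine_lr(0, 150, 1e-4), 1e-4)
  expect_equal(cosine_lr(150, 150, 1e-4), 0, tolerance = 1e-20)
  expect_equal(cosine_lr(75, 150, 1e-4), 5e-5)
  expect_equal(cosine_lr(30, 120, 2e-3), 2e-3 * (1 + cos(pi / 4)) / 2)
  expect_error(cosine_lr(-1, 10, 1e-3), "epoch")
  expect_error(cosine_lr(11, 10, 1e-3), "epoch")
})

test_that("pairing strategies respect identity, views, and seeding", {
  manifest <- data.frame(
    path = sprintf("im%02d.png", 1:10),
    identity = rep(c("a", "b"), each = 5),
    view = c("front", "front", "front", "side", "side",
             "front", "side", "side", "side", "side"),
    frame_index = c(1:5, 1:5),
    stringsAsFactors = FALSE
  )
  p <- make_pairs(manifest, "front_side", seed = 61)
  expect_true(all(manifest$view[p$a] == "front"))
  expect_true(all(manifest$view[p$b] == "side"))
  expect_true(all(manifest$identity[p$a] == manifest$identity[p$b]))
  # min(n_front, n_side) pairs per identity
  expect_equal(as.vector(table(p$identity)), c(2L, 1L))
  expect_identical(make_pairs(manifest, "front_side", seed = 61), p)
  # exhaustive mode: n_front * n_side combinations
  pe <- make_pairs(manifest, "front_side", seed = 61, exhaustive = TRUE)
  expect_equal(nrow(pe), 3 * 2 + 1 * 4)
  # one front + one side -> exactly one pair
  m1 <- manifest[c(1, 4), ]
  expect_equal(nrow(make_pairs(m1, "front_side", seed = 1)), 1)
  # same-view pairing never crosses views or identities (identity b has a
  # single front image, which the strategy skips with a warning)
  ps <- suppressWarnings(make_pairs(manifest, "same_view", seed = 62))
  expect_true(all(manifest$view[ps$a] == manifest$view[ps$b]))
  expect_true(all(ps$a != ps$b))
  expect_true(all(manifest$identity[ps$a] == manifest$identity[ps$b]))
  # fixed pairing is deterministic without a seed and frame-ordered
  pf1 <- make_pairs(manifest, "fixed")
  pf2 <- make_pairs(manifest, "fixed")
  expect_identical(pf1, pf2)
  # identities lacking a view are skipped with a warning
  front_a <- manifest[manifest$view == "front" & manifest$identity == "a", ]
  expect_warning(make_pairs(front_a, "front_side"), "skipped")
})

test_that("confusion counts match hand enumeration", {
  # labels 0,0,1,2 / predictions 0,1,1,2 in 1-based indexing
  counts <- confusion_counts(c(1, 2, 2, 3), c(1, 1, 2, 3), 3)
  expect_equal(counts[1, ], c(TP = 1L, FP = 0L, FN = 1L, TN = 2L))
  expect_equal(counts[2, ], c(TP = 1L, FP = 1L, FN = 0L, TN = 2L))
  expect_equal(counts[3, ], c(TP = 1L, FP = 0L, FN = 0L, TN = 3L))
  expect_equal(sum(counts[, "TP"]), 3L)   # number of correct predictions
  expect_true(all(rowSums(counts) == 4L))
  perfect <- confusion_counts(1:4, 1:4, 4)
  expect_true(all(perfect[, c("FP", "FN")] == 0L))
  expect_error(confusion_counts(c(1, 5), c(1, 2), 4), "outside")
})

test_that("macro metrics match hand-computed values", {
  rep_ <- classification_metrics(confusion_counts(c(1, 2, 2, 3), c(1, 1, 2, 3), 3))
  expect_equal(rep_$precision, (1 / 1 + 1 / 2 + 1 / 1) / 3)
  expect_equal(rep_$recall, (1 / 2 + 1 / 1 + 1 / 1) / 3)
  expect_equal(rep_$accuracy, 3 / 4)
  perfect <- classification_metrics(confusion_counts(1:5, 1:5, 5))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  # precision 0.5, recall 1 -> F1 = 2/3 (one positive class)
  counts <- matrix(c(1L, 1L, 0L, 2L), 1, dimnames = list(NULL, c("TP", "FP", "FN", "TN")))
  expect_equal(classification_metrics(counts)$f1, 2 / 3)
  # all-one-class predictions on balanced two-class data
  rep2 <- classification_metrics(confusion_counts(rep(1, 10), rep(1:2, 5), 2))
  expect_equal(rep2$per_class$recall, c(1, 0))
  # degenerate denominators contribute 0, never NaN
  expect_false(anyNA(unlist(rep2[c("accuracy", "precision", "recall", "f1")])))
})

test_that("an untrained network predicts at chance on balanced data", {
  set.seed(63)
  ds <- synthetic_dataset(n_ids = 8, per_id_per_view = 6, size = 32, seed = 63)
  model <- build_network(tiny_config(num_classes = 8L), seed = 63)
  samples <- paired_samples(ds, make_pairs(ds$manifest, "fixed"))
  rep_ <- evaluate_network(model, samples)
  # 48 pairs at chance 1/8: binomial 99.9% envelope
  expect_lt(abs(rep_$accuracy - 1 / 8), 3.3 * sqrt(0.125 * 0.875 / 48))
})

test_that("evaluation is deterministic and invariant under reparameterization", {
  set.seed(64)
  ds <- synthetic_dataset(n_ids = 4, per_id_per_view = 4, size = 32, seed = 64)
  model <- randomize_network_stats(
    build_network(tiny_config(num_classes = 4L), seed = 64))
  samples <- paired_samples(ds, make_pairs(ds$manifest, "fixed"))
  r1 <- evaluate_network(model, samples)
  r2 <- evaluate_network(model, samples)
  expect_identical(r1, r2)
  r3 <- evaluate_network(reparameterize(model), samples)
  expect_identical(r1$per_class, r3$per_class)
})

test_that("training runs, is seeded, and reduces the loss on separable data", {
  ds <- synthetic_dataset(n_ids = 4, per_id_per_view = 6, size = 32, seed = 65)
  samples <- paired_samples(ds, make_pairs(ds$manifest, "front_side", seed = 65))
  cfg <- train_config(lr0 = 1e-3, epochs = 2, batch_size = 8, seed = 65)
  model <- build_network(tiny_config(num_classes = 4L), seed = 65)
  fit <- train_network(model, samples, cfg)
  expect_s3_class(fit, "repb_fit")
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_equal(nrow(fit$history), 2)
  # identical seed, identical history
  fit2 <- train_network(build_network(tiny_config(num_classes = 4L), seed = 65),
                        samples, cfg)
  expect_identical(fit$history, fit2$history)
  # over 20 epochs the loss trend on separable data is downward
  fit20 <- train_network(build_network(tiny_config(num_classes = 4L), seed = 66),
                         samples,
                         train_config(lr0 = 1e-3, epochs = 20, batch_size = 8,
                                      seed = 66))
  h <- fit20$history$train_loss
  expect_lt(median(tail(h, 5)), median(head(h, 5)))
  expect_error(train_network(model, list(), cfg), "no training samples")
})
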