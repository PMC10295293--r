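test_that("network construction follows the configuration contract", {
  cfg <- tiny_config()
  model <- build_network(cfg, seed = 41)
  expect_s3_class(model, "repb_net")
  expect_length(model$branches, 2)
  expect_length(model$branches[[1]], 5)
  # branches are structurally identical but do not share weights
  expect_identical(dim(model$branches[[1]][[1]]$blocks[[1]]$w3),
                   dim(model$branches[[2]][[1]]$blocks[[1]]$w3))
  expect_false(identical(model$branches[[1]][[1]]$blocks[[1]]$w3,
                         model$branches[[2]][[1]]$blocks[[1]]$w3))
  # first block of every stage has stride 2
  for (s in 1:5) {
    expect_identical(model$branches[[1]][[s]]$blocks[[1]]$stride, 2L)
  }
  single <- build_network(tiny_config(bilinear = FALSE, use_sa = FALSE), seed = 41)
  expect_length(single$branches, 1)
  expect_null(single$branches[[1]][[1]]$sa)
  expect_error(network_config(stage_depths = 1:4), "length 5")
  expect_error(network_config(input_size = 100), "divisible by 32")
})

test_that("five stride-2 stages contract the spatial grid 32-fold", {
  # 224 -> 7 with a narrow network to keep the check cheap
  cfg <- network_config(stage_depths = rep(1L, 5),
                        stage_widths = c(2L, 2L, 2L, 2L, 4L),
                        num_classes = 2L, input_size = 224L, in_channels = 1L,
                        bilinear = FALSE, use_sa = FALSE)
  model <- build_network(cfg, seed = 42)
  f <- repbnet:::branch_forward(model$branches[[1]],
                                rand_image_batch(224, 1, 1))
  expect_identical(dim(f), c(7L, 7L, 4L, 1L))
  # and 32 -> 1 for the tiny test scale
  tiny <- build_network(tiny_config(), seed = 42)
  f2 <- repbnet:::branch_forward(tiny$branches[[1]], rand_image_batch(32, 3, 2))
  expect_identical(dim(f2), c(1L, 1L, 32L, 2L))
})

test_that("feature fusion operators behave algebraically", {
  f1 <- rand_image_batch(3, 4, 2)
  f2 <- rand_image_batch(3, 4, 2)
  zero <- array(0, dim(f1))
  ones <- array(1, dim(f1))
  expect_identical(fuse_features(f1, zero, "sum"), f1)
  expect_identical(fuse_features(f1, f2, "sum"), fuse_features(f2, f1, "sum"))
  expect_identical(fuse_features(f1, ones, "product"), f1)
  cc <- fuse_features(f1, f2, "concat")
  expect_identical(dim(cc)[3], 8L)
  expect_identical(cc[, , 1:4, , drop = FALSE], f1)
  expect_error(fuse_features(f1, rand_image_batch(3, 5, 2), "sum"), "shape")
})

test_that("class scores are classifier-equivariant and fusion-linear", {
  set.seed(43)
  model <- build_network(tiny_config(num_classes = 4L), seed = 43)
  xa <- rand_image_batch(32, 3, 2)
  xb <- rand_image_batch(32, 3, 2)
  scores <- network_forward(model, xa, xb)
  expect_identical(dim(scores), c(4L, 2L))
  # permuting classifier rows permutes scores identically
  perm <- c(3L, 1L, 4L, 2L)
  m2 <- model
  m2$classifier$w <- model$classifier$w[perm, ]
  m2$classifier$b <- model$classifier$b[perm]
  expect_equal(network_forward(m2, xa, xb), scores[perm, ], tolerance = 1e-12)
  # identical branches + identical inputs + sum fusion = doubled branch feature
  m3 <- model
  m3$branches[[2]] <- m3$branches[[1]]
  f <- repbnet:::branch_forward(m3$branches[[1]],
                                repbnet:::as_feature_map(xa))
  expected <- m3$classifier$w %*% (2 * repbnet:::global_avg_pool(f)) +
    m3$classifier$b
  expect_equal(network_forward(m3, xa, xa), expected, tolerance = 1e-10)
})

test_that("whole-network reparameterization preserves outputs and predictions", {
  set.seed(44)
  for (cfg in list(tiny_config(TRUE, TRUE), tiny_config(TRUE, FALSE),
                   tiny_config(FALSE, TRUE), tiny_config(FALSE, FALSE))) {
    model <- randomize_network_stats(build_network(cfg, seed = 44))
    dep <- reparameterize(model)
    expect_identical(dep$form, "deploy")
    expect_lt(count_parameters(dep), count_parameters(model))
    # deploy backbone holds no batch norm and no 1x1 kernels
    for (branch in dep$branches) for (stage in branch) {
      for (bl in stage$blocks) {
        expect_identical(bl$form, "deploy")
        expect_null(bl$bn3); expect_null(bl$w1); expect_null(bl$bn0)
      }
    }
    worst <- 0
    for (r in 1:10) {
      xa <- rand_image_batch(32, 3, 2)
      xb <- if (cfg$bilinear) rand_image_batch(32, 3, 2)
      s1 <- network_forward(model, xa, xb)
      s2 <- network_forward(dep, xa, xb)
      worst <- max(worst, max(abs(s1 - s2)))
      expect_identical(apply(s1, 2, which.max), apply(s2, 2, which.max))
    }
    expect_lt(worst, 1e-3)
  }
  expect_warning(reparameterize(reparameterize(build_network(tiny_config(), 1))),
                 "already")
})

test_that("reparameterization stays lossless at the full-scale architecture", {
  # A1 depths/widths with trained-looking statistics, checked on a reduced
  # spatial grid (the fusion algebra is independent of input size)
  set.seed(47)
  cfg <- network_config(input_size = 64L, num_classes = 8L)
  model <- randomize_network_stats(build_network(cfg, seed = 47))
  dep <- reparameterize(model)
  xa <- rand_image_batch(64, 3, 1)
  xb <- rand_image_batch(64, 3, 1)
  s1 <- network_forward(model, xa, xb)
  s2 <- network_forward(dep, xa, xb)
  expect_lt(max(abs(s1 - s2)), 1e-3)
  expect_identical(which.max(s1), which.max(s2))
  rm(model, dep)
  gc(verbose = FALSE)
})

test_that("parameter counting matches the closed-form block arithmetic", {
  cfg <- tiny_config(bilinear = FALSE, use_sa = FALSE, num_classes = 4L)
  model <- build_network(cfg, seed = 45)
  widths <- c(8, 8, 16, 16, 32)
  manual <- 0
  in_ch <- 3
  for (s in 1:5) {
    manual <- manual + 9 * in_ch * widths[s] + in_ch * widths[s] + 4 * widths[s]
    in_ch <- widths[s]
  }
  manual <- manual + 32 * 4 + 4          # classifier
  expect_identical(count_parameters(model), as.integer(manual))
  expect_equal(format_params(12862504), 12.86)
  # deploy form: 9*in*out + out per block
  dep <- reparameterize(model)
  manual_dep <- sum(9 * c(3, widths[-5]) * widths + widths) + 32 * 4 + 4
  expect_identical(count_parameters(dep), as.integer(manual_dep))
})

test_that("checkpoints round-trip through disk", {
  model <- build_network(tiny_config(), seed = 46)
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  save_checkpoint(model, tmp)
  back <- load_checkpoint(tmp)
  expect_identical(back, model)
  xa <- rand_image_batch(32, 3, 1); xb <- rand_image_batch(32, 3, 1)
  expect_identical(network_forward(model, xa, xb), network_forward(back, xa, xb))
})
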