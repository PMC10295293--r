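test_that("image histograms are normalized and bin correctly", {
  # all mass in one bin
  h <- image_histogram(matrix(0, 4, 4), n_bins = 2)
  expect_equal(h$values, c(1, 0))
  # symmetric two-value image
  h <- image_histogram(matrix(c(0, 255), 2, 1), n_bins = 2)
  expect_equal(h$values, c(0.5, 0.5))
  # hand-binned 4-pixel case, bin edge at 128
  h <- image_histogram(matrix(c(10, 10, 200, 250), 2, 2), n_bins = 2)
  expect_equal(h$values, c(0.5, 0.5))
  # normalization holds for arbitrary images and bin counts
  set.seed(1)
  for (bins in c(16, 64, 256)) {
    h <- image_histogram(matrix(runif(400, 0, 255), 20), n_bins = bins)
    expect_equal(sum(h$values), 1, tolerance = 1e-9)
    expect_true(all(h$values >= 0))
  }
  # colour images are reduced via BT.601 luma
  img <- array(0, c(2, 2, 3)); img[, , 1] <- 255   # pure red
  h <- image_histogram(img, n_bins = 256)
  expect_equal(which(h$values > 0), floor(0.299 * 255 / 1) + 1)
  expect_error(image_histogram(matrix(numeric(0), 0, 0)), "empty")
  expect_error(image_histogram(matrix(300, 2, 2)), "0, 255")
})

test_that("histogram similarity matches hand-computed values and the oracle", {
  h <- function(v) structure(list(values = v, n_bins = length(v)),
                             class = "repb_histogram")
  expect_identical(histogram_similarity(h(c(0.5, 0.5)), h(c(0.5, 0.5))), 1)
  expect_identical(histogram_similarity(h(c(1, 0)), h(c(0, 1))), 0)
  # (1 - 0.25/0.5)/1 terms: (0.5 + 2/3) / 2
  expect_equal(histogram_similarity(h(c(0.5, 0.5)), h(c(0.25, 0.75))),
               (0.5 + 2 / 3) / 2, tolerance = 1e-12)
  expect_error(histogram_similarity(h(c(1, 0)), h(c(1, 0, 0))), "bin")
})

test_that("similarity is symmetric, bounded, and agrees with direct summation", {
  set.seed(42)
  for (rep_ in 1:250) {
    n <- sample(c(8, 32, 256), 1)
    gv <- runif(n) * rbinom(n, 1, 0.7)   # include exact-zero bins
    sv <- runif(n) * rbinom(n, 1, 0.7)
    g <- structure(list(values = gv / max(sum(gv), 1), n_bins = n),
                   class = "repb_histogram")
    s <- structure(list(values = sv / max(sum(sv), 1), n_bins = n),
                   class = "repb_histogram")
    s1 <- histogram_similarity(g, s)
    expect_equal(s1, naive_similarity(g, s), tolerance = 1e-12)
    expect_equal(s1, histogram_similarity(s, g), tolerance = 1e-15)
    expect_gte(s1, 0); expect_lte(s1, 1)
    expect_equal(histogram_similarity(g, g), 1)
  }
})

test_that("frame filtering retains the first frame and drops near-duplicates", {
  img <- matrix(runif(64, 0, 255), 8)
  expect_identical(filter_frames(list()), list())
  expect_length(filter_frames(list(img)), 1)
  # three identical frames: S = 1 > 0.8 for both successors
  expect_length(filter_frames(list(img, img, img)), 1)
  # S exactly at the threshold keeps the frame (strict inequality):
  # histograms [0.5, 0.5] vs [1, 0] give S = (0.5 + 0)/2 = 0.25
  a <- matrix(c(10, 10, 200, 200), 2)
  b <- matrix(10, 2, 2)
  s_ab <- histogram_similarity(image_histogram(a, 2), image_histogram(b, 2))
  expect_equal(s_ab, 0.25)
  expect_length(filter_frames(list(a, b), threshold = 0.25, n_bins = 2), 2)
  expect_length(filter_frames(list(a, b), threshold = 0.2499, n_bins = 2), 1)
  expect_error(filter_frames(list(img), threshold = 1.2), "threshold")
})

test_that("alternating dissimilar frames are all retained and filtering is idempotent", {
  # two images with disjoint gray levels; with 2 bins their similarity is 0
  # (note: with many bins, shared empty bins would inflate S — the sparse-
  # histogram pathology of the per-bin statistic)
  a <- matrix(10, 6, 6)
  b <- matrix(200, 6, 6)
  s <- histogram_similarity(image_histogram(a, 2), image_histogram(b, 2))
  expect_equal(s, 0)
  frames <- rep(list(a, b), 5)
  kept <- filter_frames(frames, threshold = 0.8, n_bins = 2)
  expect_length(kept, 10)
  # idempotence on a sequence that does get thinned
  set.seed(5)
  drift <- lapply(seq(0, 240, by = 16), function(m) {
    matrix(pmin(pmax(m + rnorm(256, sd = 12), 0), 255), 16)
  })
  once <- filter_frames(drift, n_bins = 32)
  twice <- filter_frames(once, n_bins = 32)
  expect_identical(twice, once)
  # every adjacent retained pair is at or below the threshold
  if (length(once) > 1) {
    for (i in seq_len(length(once) - 1)) {
      s_adj <- histogram_similarity(image_histogram(once[[i]], 32),
                                    image_histogram(once[[i + 1]], 32))
      expect_lte(s_adj, 0.8)
    }
  }
})

test_that("manifests round-trip losslessly", {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  # empty manifest: header only
  write_manifest(list(), tmp)
  expect_identical(nrow(read_manifest(tmp)), 0L)
  recs <- list(
    frame_record(matrix(0, 2, 2), "id01", "front", 1, "a/im1.png"),
    frame_record(matrix(0, 2, 2), "id01", "side", 2, "a/im2.png"),
    frame_record(matrix(0, 2, 2), "id02", "front", 7, "b/im7.png")
  )
  write_manifest(recs, tmp)
  back <- read_manifest(tmp)
  expect_equal(back$path, c("a/im1.png", "a/im2.png", "b/im7.png"))
  expect_equal(back$identity, c("id01", "id01", "id02"))
  expect_equal(back$view, c("front", "side", "front"))
  expect_equal(back$frame_index, c(1L, 2L, 7L))
  # round-trip again through the data-frame interface
  write_manifest(back, tmp)
  expect_equal(read_manifest(tmp), back)
})
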