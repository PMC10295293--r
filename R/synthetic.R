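# Procedural synthetic two-view face images.
#
# Each identity is a low-dimensional appearance signature with two parts:
# a stripe configuration (base gray, frequency, orientation, phase) shown
# in the front view and a Gaussian-blob constellation (own base gray,
# positions, amplitudes) shown in the side view, rendered inside face-like
# ellipses.  The parts are deliberately shared between identities — pairs
# of identities share a stripe configuration, a *shifted* pairing shares
# each blob configuration — so that either view alone is ambiguous
# (roughly two candidate identities) while the combination of views is
# unique.  Fusing both views is therefore strictly more informative than
# either alone, emulating the complementarity of front/side face crops
# without any animal imagery.

#' Generate a bank of synthetic identities
#'
#' Draws `ceiling(n/2)` stripe configurations and `ceiling(n/2)` blob
#' configurations on evenly spaced, randomly permuted parameter grids.
#' Identity `i` shows stripe configuration `ceiling(i/2)` in its front
#' view and blob configuration `ceiling((1 + (i mod n)) / 2)` in its side
#' view; for every `n >= 3` the combination is unique per identity, so
#' signatures are pairwise distinct (with grid-enforced separation)
#' although single views collide in pairs.  For `n = 2` both parts are
#' drawn per identity (views are then individually identifying).
#'
#' @param n_ids Number of identities (>= 2; the study scale is 40).
#' @param seed Optional integer seed.
#' @return List of class `"identity_bank"`; each element is an
#'   `"identity_spec"` with fields `identity_id`, `stripe_group`,
#'   `blob_group`, `stripe` (base_gray, freq, angle, phase) and `blob`
#'   (base_gray, blobs data frame x, y, amp, sigma).
#' @export
identity_bank <- function(n_ids, seed = NULL) {
  if (n_ids < 2L) stop("identity_bank: need at least 2 identities")
  if (!is.null(seed)) set.seed(seed)
  n_cfg <- if (n_ids == 2L) 2L else as.integer(ceiling(n_ids / 2))
  grid_of <- function(n, lo, hi) (sample.int(n) - 1) / max(n - 1, 1) *
    (hi - lo) + lo
  stripes <- list(
    base_gray = grid_of(n_cfg, 100, 170),
    freq = grid_of(n_cfg, 2.5, 7),
    angle = (sample.int(n_cfg) - 1) / n_cfg * pi,
    phase = stats::runif(n_cfg, 0, 2 * pi)
  )
  blob_gray <- grid_of(n_cfg, 100, 170)
  blob_cfgs <- lapply(seq_len(n_cfg), function(j) {
    data.frame(
      x = stats::runif(3, 0.2, 0.8),
      y = stats::runif(3, 0.2, 0.8),
      amp = sample(c(-1, 1), 3, replace = TRUE) * stats::runif(3, 35, 60),
      sigma = stats::runif(3, 0.06, 0.12)
    )
  })
  idx <- seq_len(n_ids)
  g1 <- if (n_ids == 2L) idx else as.integer(ceiling(idx / 2))
  g2 <- if (n_ids == 2L) idx else as.integer(ceiling((1 + (idx %% n_ids)) / 2))
  bank <- vector("list", n_ids)
  for (i in idx) {
    bank[[i]] <- structure(
      list(identity_id = sprintf("id%02d", i),
           stripe_group = g1[i], blob_group = g2[i],
           stripe = list(base_gray = stripes$base_gray[g1[i]],
                         freq = stripes$freq[g1[i]],
                         angle = stripes$angle[g1[i]],
                         phase = stripes$phase[g1[i]]),
           blob = list(base_gray = blob_gray[g2[i]],
                       blobs = blob_cfgs[[g2[i]]])),
      class = "identity_spec"
    )
  }
  structure(bank, class = c("identity_bank", "list"))
}

#' Numeric signature vector of an identity (for separation checks)
#' @param spec An `"identity_spec"`.
#' @return Numeric vector on comparable scales (front part then side part).
#' @export
signature_vector <- function(spec) {
  c(spec$stripe$base_gray / 70, spec$stripe$freq / 4.5,
    cos(2 * spec$stripe$angle), sin(2 * spec$stripe$angle),
    spec$blob$base_gray / 70,
    spec$blob$blobs$x, spec$blob$blobs$y, spec$blob$blobs$amp / 60)
}

#' @noRd
stripe_field <- function(spec, u, v, phase_jit = 0) {
  a <- spec$stripe$angle
  sin(2 * pi * spec$stripe$freq * (u * cos(a) + v * sin(a)) +
        spec$stripe$phase + phase_jit)
}

#' @noRd
blob_field <- function(spec, u, v, dx = 0, dy = 0) {
  f <- 0
  blobs <- spec$blob$blobs
  for (k in seq_len(nrow(blobs))) {
    b <- blobs[k, ]
    f <- f + b$amp * exp(-((u - b$x - dx)^2 + (v - b$y - dy)^2) /
                           (2 * b$sigma^2))
  }
  f
}

#' Render one view of a synthetic identity
#'
#' Renders the identity's signature into a `size x size` grayscale image
#' replicated to 3 channels, values in \[0, 255\].  The front view is a
#' wide centred ellipse dominated by the stripe pattern; the side view a
#' narrower off-centre ellipse with mirrored coordinates dominated by the
#' blob pattern.  `jitter` scales the photometric and geometric
#' perturbations (phase shift, blob displacement, brightness offset,
#' pixel noise) that distinguish repeated renders.
#'
#' @param spec An `"identity_spec"` from [identity_bank()].
#' @param view `"front"` or `"side"`.
#' @param jitter Perturbation magnitude, >= 0 (0 gives a deterministic
#'   canonical render; default 0.5).
#' @param size Image side in pixels (default 224).
#' @param seed Optional integer seed.
#' @return `size x size x 3` array in \[0, 255\].
#' @export
render_view <- function(spec, view = c("front", "side"), jitter = 0.5,
                        size = 224L, seed = NULL) {
  view <- match.arg(view)
  if (jitter < 0) stop("render_view: jitter must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  ax <- seq(0, 1, length.out = size)
  u <- matrix(ax, size, size)               # column coordinate
  v <- matrix(ax, size, size, byrow = TRUE) # row coordinate
  phase_jit <- jitter * stats::rnorm(1, sd = 0.6)
  dx <- jitter * stats::rnorm(1, sd = 0.03)
  dy <- jitter * stats::rnorm(1, sd = 0.03)
  bright <- jitter * stats::rnorm(1, sd = 8)
  if (view == "front") {
    mask <- ((u - 0.5) / 0.42)^2 + ((v - 0.5) / 0.48)^2 <= 1
    img <- spec$stripe$base_gray + bright +
      45 * stripe_field(spec, u, v, phase_jit)
  } else {
    um <- 1 - u                              # mirrored projection
    mask <- ((um - 0.62) / 0.30)^2 + ((v - 0.5) / 0.46)^2 <= 1
    img <- spec$blob$base_gray + bright +
      blob_field(spec, um, v, dx, dy)
  }
  img[!mask] <- 30
  noise_sd <- 3 + 4 * jitter
  img <- img + stats::rnorm(length(img), sd = noise_sd)
  img <- clip255(img)
  array(rep(img, 3L), c(size, size, 3L))
}

#' Generate a balanced synthetic two-view dataset
#'
#' Renders `per_id_per_view` images of each view for each of `n_ids`
#' identities.  Exactly balanced class and view frequencies; deterministic
#' under `seed`.
#'
#' @param n_ids Number of identities (default 8).
#' @param per_id_per_view Images per identity per view (default 25).
#' @param jitter Render perturbation magnitude (default 0.5).
#' @param size Image side in pixels (default 224).
#' @param seed Integer seed (default 1).
#' @return List of class `"repb_dataset"`: `images` (list of arrays),
#'   `manifest` (path, identity, view, frame_index), and `bank`.
#' @export
synthetic_dataset <- function(n_ids = 8L, per_id_per_view = 25L,
                              jitter = 0.5, size = 224L, seed = 1L) {
  if (n_ids < 2L || per_id_per_view < 1L) {
    stop("synthetic_dataset: need >= 2 identities and >= 1 image per view")
  }
  set.seed(seed)
  bank <- identity_bank(n_ids)
  images <- list()
  rows <- list()
  for (i in seq_len(n_ids)) {
    for (view in c("front", "side")) {
      for (k in seq_len(per_id_per_view)) {
        images[[length(images) + 1L]] <-
          render_view(bank[[i]], view, jitter = jitter, size = size)
        rows[[length(rows) + 1L]] <- data.frame(
          path = sprintf("%s_%s_%03d.png", bank[[i]]$identity_id, view, k),
          identity = bank[[i]]$identity_id, view = view,
          frame_index = k, stringsAsFactors = FALSE)
      }
    }
  }
  structure(
    list(images = images, manifest = do.call(rbind, rows), bank = bank),
    class = "repb_dataset"
  )
}

#' @export
print.repb_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Synthetic two-view dataset: %d images, %d identities (%s)\n",
              nrow(m), length(unique(m$identity)),
              paste(sprintf("%d %s", table(m$view), names(table(m$view))),
                    collapse = ", ")))
  invisible(x)
}

#' Generate a near-duplicate frame sequence
#'
#' Emulates consecutive video frames of one animal: a canonical render
#' whose intensities drift by `drift_per_frame` gray levels per frame
#' (cyclically, so the histogram shape is preserved while its location
#' moves).  Consecutive-frame histogram similarity is a decreasing
#' function of the drift; at drift 0 all frames are identical (S = 1).
#'
#' @param spec An `"identity_spec"`.
#' @param n_frames Number of frames (>= 1).
#' @param drift_per_frame Gray levels of drift per frame, >= 0 (cumulative
#'   shifts are rounded to whole levels so frames stay on the 8-bit grid).
#' @param size Image side in pixels (default 64).
#' @param seed Optional integer seed.
#' @return List of [frame_record()]s with increasing `frame_index`.
#' @export
frame_sequence <- function(spec, n_frames, drift_per_frame, size = 64L,
                           seed = NULL) {
  if (n_frames < 1L) stop("frame_sequence: n_frames must be >= 1")
  if (drift_per_frame < 0) stop("frame_sequence: drift must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  base <- round(render_view(spec, "front", jitter = 0.3, size = size))
  lapply(seq_len(n_frames), function(t_) {
    img <- (base + round((t_ - 1L) * drift_per_frame)) %% 256
    frame_record(img, identity = spec$identity_id, view = "front",
                 frame_index = t_)
  })
}

#' Read / write an image file
#'
#' PNG I/O on the package's \[0, 255\] intensity convention.
#'
#' @param path PNG file path.
#' @return `read_image` returns an H x W x 3 array in \[0, 255\].
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (is.matrix(x)) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  x * 255
}

#' @rdname read_image
#' @param image Image array with values in \[0, 255\].
#' @export
write_image <- function(image, path) {
  png::writePNG(clip255(image) / 255, path)
  invisible(path)
}

#' Write a dataset to disk in the standard layout
#'
#' Writes every image as a PNG under `dir` and a `manifest.csv` alongside.
#'
#' @param dataset A [synthetic_dataset()].
#' @param dir Output directory (created if missing).
#' @return The manifest with paths rewritten to the written files,
#'   invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- dataset$manifest
  m$path <- file.path(dir, m$path)
  for (i in seq_len(nrow(m))) write_image(dataset$images[[i]], m$path[i])
  write_manifest(m, file.path(dir, "manifest.csv"))
  invisible(m)
}
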