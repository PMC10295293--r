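# Photometric training-time augmentations.  All operate on numeric images
# (grayscale matrix or H x W x 3 array) with values in [0, 255], preserve
# shape, and clip back into range.

#' @noRd
clip255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

#' Horizontal flip
#'
#' Reverses the column (width) order; an involution.
#' @param image Grayscale matrix or H x W x C array.
#' @return Flipped image, same shape.
#' @export
hflip <- function(image) {
  if (length(image) == 0L) stop("hflip: empty image")
  d <- dim(image)
  if (length(d) == 2L) {
    image[, rev(seq_len(d[2])), drop = FALSE]
  } else {
    image[, rev(seq_len(d[2])), , drop = FALSE]
  }
}

#' Photometric adjustments: brightness, saturation, contrast
#'
#' Multiplicative photometric transforms, each the identity at `factor = 1`
#' and clipped to \[0, 255\]:
#' * brightness: `factor * x` (factor must be positive);
#' * saturation: blend between the per-pixel BT.601 grayscale and the
#'   original, `gray + factor * (x - gray)` (factor 0 desaturates fully);
#' * contrast: scaling about the image's mean gray level,
#'   `mean + factor * (x - mean)` (factor 0 collapses the image to its mean).
#'
#' Saturation and contrast accept factor 0 (full desaturation / collapse);
#' negative factors are rejected everywhere.
#'
#' @param image Image with values in \[0, 255\].
#' @param factor Non-negative multiplier.
#' @return Adjusted image, same shape.
#' @name photometric
NULL

#' @rdname photometric
#' @export
adjust_brightness <- function(image, factor) {
  check_factor(factor)
  clip255(image * factor)
}

#' @rdname photometric
#' @export
adjust_saturation <- function(image, factor) {
  check_factor(factor, allow_zero = TRUE)
  d <- dim(image)
  if (length(d) != 3L || d[3] < 3L) return(image)  # saturation of gray is a no-op
  gray <- to_gray(image)
  out <- image
  for (ch in 1:3) out[, , ch] <- gray + factor * (image[, , ch] - gray)
  clip255(out)
}

#' @rdname photometric
#' @export
adjust_contrast <- function(image, factor) {
  check_factor(factor, allow_zero = TRUE)
  m <- mean(to_gray(image))
  clip255(m + factor * (image - m))
}

#' @noRd
check_factor <- function(factor, allow_zero = FALSE) {
  ok <- is.numeric(factor) && length(factor) == 1L && is.finite(factor) &&
    (factor > 0 || (allow_zero && factor == 0))
  if (!ok) stop("adjustment factor must be a positive number")
  invisible(TRUE)
}

#' Additive Gaussian noise
#'
#' Adds zero-mean Gaussian noise of standard deviation `sigma` (intensity
#' units) and clips to \[0, 255\].  `sigma = 0` is the identity.  Uses R's
#' global RNG stream: seed with [set.seed()] for repeatability.
#'
#' @param image Image with values in \[0, 255\].
#' @param sigma Noise standard deviation, >= 0.
#' @return Noisy image, same shape.
#' @export
add_gaussian_noise <- function(image, sigma) {
  if (sigma < 0) stop("add_gaussian_noise: sigma must be >= 0")
  if (sigma == 0) return(image)
  out <- image + stats::rnorm(length(image), sd = sigma)
  dim(out) <- dim(image)
  clip255(out)
}

#' Augmentation configuration
#'
#' Bundles the magnitudes of the five training-time augmentations: Gaussian
#' noise, brightness, horizontal flip, saturation and contrast.  Factor
#' ranges must contain 1 (the identity).  Each augmentation is applied
#' independently with probability `apply_prob` (the flip with `hflip_prob`).
#'
#' @param noise_sigma Noise std dev in intensity units (default 10).
#' @param brightness_range,saturation_range,contrast_range Length-2 numeric
#'   intervals for the multiplicative factor (default `c(0.8, 1.2)`).
#' @param hflip_prob Probability of a horizontal flip (default 0.5).
#' @param apply_prob Probability that each photometric augmentation fires
#'   (default 0.5).
#' @param seed Optional integer seed recorded in the config.
#' @return List of class `"augment_config"`.
#' @export
augment_config <- function(noise_sigma = 10,
                           brightness_range = c(0.8, 1.2),
                           saturation_range = c(0.8, 1.2),
                           contrast_range = c(0.8, 1.2),
                           hflip_prob = 0.5,
                           apply_prob = 0.5,
                           seed = NULL) {
  chk_range <- function(r, what) {
    if (length(r) != 2L || r[1] > r[2] || r[1] > 1 || r[2] < 1) {
      stop("augment_config: ", what, " must be an interval containing 1")
    }
  }
  chk_range(brightness_range, "brightness_range")
  chk_range(saturation_range, "saturation_range")
  chk_range(contrast_range, "contrast_range")
  if (hflip_prob < 0 || hflip_prob > 1 || apply_prob < 0 || apply_prob > 1) {
    stop("augment_config: probabilities must lie in [0, 1]")
  }
  if (noise_sigma < 0) stop("augment_config: noise_sigma must be >= 0")
  structure(
    list(noise_sigma = noise_sigma, brightness_range = brightness_range,
         saturation_range = saturation_range, contrast_range = contrast_range,
         hflip_prob = hflip_prob, apply_prob = apply_prob, seed = seed),
    class = "augment_config"
  )
}

#' Apply a random augmentation pipeline to one image
#'
#' Applies, in a fixed order (flip, brightness, saturation, contrast,
#' noise), each augmentation independently at its configured probability
#' with a factor sampled uniformly from its range.  Deterministic given the
#' RNG state; if `config$seed` is set the global seed is set first.
#'
#' @param image Image with values in \[0, 255\].
#' @param config An [augment_config()].
#' @return Augmented image, same shape.
#' @export
random_augment <- function(image, config = augment_config()) {
  stopifnot(inherits(config, "augment_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (stats::runif(1) < config$hflip_prob) image <- hflip(image)
  if (stats::runif(1) < config$apply_prob) {
    image <- adjust_brightness(image, stats::runif(1, config$brightness_range[1],
                                                   config$brightness_range[2]))
  }
  if (stats::runif(1) < config$apply_prob) {
    image <- adjust_saturation(image, stats::runif(1, config$saturation_range[1],
                                                   config$saturation_range[2]))
  }
  if (stats::runif(1) < config$apply_prob) {
    image <- adjust_contrast(image, stats::runif(1, config$contrast_range[1],
                                                 config$contrast_range[2]))
  }
  if (config$noise_sigma > 0 && stats::runif(1) < config$apply_prob) {
    image <- add_gaussian_noise(image, config$noise_sigma)
  }
  image
}
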