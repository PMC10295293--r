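#' Normalized intensity histogram of an image
#'
#' Converts an image to a normalized luminance histogram, the operand of the
#' histogram-similarity statistic used for frame deduplication.  Colour
#' images are first reduced to grayscale with ITU-R BT.601 luma weights
#' (0.299, 0.587, 0.114); intensities are then binned into `n_bins` uniform
#' bins over \[0, 256) and the counts normalized to proportions.
#'
#' @param image Numeric matrix (grayscale) or H x W x 3 array with values in
#'   \[0, 255\].
#' @param n_bins Number of uniform bins (default 256, one per 8-bit level).
#' @param source_id Optional opaque reference to the source image.
#' @return An object of class `"repb_histogram"`: a list with `values`
#'   (proportions summing to 1), `n_bins`, and `source_id`.
#' @examples
#' h <- image_histogram(matrix(c(10, 10, 200, 250), 2), n_bins = 2)
#' h$values  # 0.5 0.5
#' @export
image_histogram <- function(image, n_bins = 256L, source_id = NULL) {
  if (is.null(image) || length(image) == 0L) {
    stop("image_histogram: empty image")
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("image_histogram: n_bins must be positive")
  gray <- to_gray(image)
  if (any(gray < 0 | gray > 255)) {
    stop("image_histogram: pixel values must lie in [0, 255]")
  }
  idx <- pmin(floor(gray / (256 / n_bins)) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(
    list(values = counts / length(gray), n_bins = n_bins, source_id = source_id),
    class = "repb_histogram"
  )
}

#' @noRd
to_gray <- function(image) {
  d <- dim(image)
  if (!is.null(d) && length(d) == 3L && d[3] >= 3L) {
    0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
  } else if (!is.null(d) && length(d) == 3L) {
    image[, , 1L]
  } else {
    image
  }
}

#' @export
print.repb_histogram <- function(x, ...) {
  cat("Normalized image histogram:", x$n_bins, "bins",
      if (!is.null(x$source_id)) paste0("(", x$source_id, ")"), "\n")
  invisible(x)
}

#' Histogram similarity between two images
#'
#' The per-bin relative-agreement statistic
#' \deqn{S = \frac{1}{N}\sum_{i=1}^{N}\left(1 -
#'   \frac{|g_i - s_i|}{\max(g_i, s_i)}\right)}
#' where \eqn{g_i, s_i} are the normalized histogram values of the two images
#' in bin \eqn{i}.  A bin where both histograms are zero contributes 1 (the
#' values are equal, so there is no dissimilarity).  `S` is symmetric, lies
#' in \[0, 1\], and equals 1 exactly on identical histograms.
#'
#' @param g,s Objects of class `"repb_histogram"` with equal `n_bins`.
#' @return Similarity in \[0, 1\].
#' @export
histogram_similarity <- function(g, s) {
  gv <- if (inherits(g, "repb_histogram")) g$values else as.numeric(g)
  sv <- if (inherits(s, "repb_histogram")) s$values else as.numeric(s)
  if (length(gv) != length(sv)) {
    stop("histogram_similarity: histograms have different bin counts (",
         length(gv), " vs ", length(sv), ")")
  }
  mx <- pmax(gv, sv)
  term <- ifelse(mx == 0, 1, 1 - abs(gv - sv) / mx)
  mean(term)
}

#' Construct a frame record
#'
#' One extracted video frame with its labels, the unit the deduplication
#' filter operates on.
#'
#' @param image Grayscale matrix or H x W x 3 array, values in \[0, 255\].
#' @param identity Identity label of the animal in the frame.
#' @param view `"front"`, `"side"`, or `"unknown"`.
#' @param frame_index Non-negative integer position within the sequence.
#' @param path Optional file path the image came from / will be written to.
#' @return A list of class `"frame_record"`.
#' @export
frame_record <- function(image, identity = NA_character_,
                         view = c("unknown", "front", "side"),
                         frame_index = 0L, path = NA_character_) {
  view <- match.arg(view)
  if (frame_index < 0) stop("frame_record: frame_index must be non-negative")
  structure(
    list(image = image, identity = as.character(identity), view = view,
         frame_index = as.integer(frame_index), path = path),
    class = "frame_record"
  )
}

#' Deduplicate a frame sequence by histogram similarity
#'
#' Streams through an ordered frame sequence and drops every frame whose
#' histogram similarity to the most recently *retained* frame exceeds the
#' threshold (strict inequality: S equal to the threshold keeps the frame).
#' The first frame is always retained and order is preserved.  Filtering an
#' already-filtered sequence is a no-op.
#'
#' @param frames List of [frame_record()] objects ordered by `frame_index`
#'   (plain image arrays are accepted and wrapped).
#' @param threshold Similarity above which a frame is considered a duplicate
#'   (default 0.8); must lie in (0, 1).
#' @param n_bins Bins used for the per-frame histograms (default 256).
#' @return The retained sublist, in order.
#' @export
filter_frames <- function(frames, threshold = 0.8, n_bins = 256L) {
  if (threshold <= 0 || threshold >= 1) {
    stop("filter_frames: threshold must lie in (0, 1)")
  }
  if (length(frames) == 0L) return(list())
  get_img <- function(f) if (inherits(f, "frame_record")) f$image else f
  kept <- vector("list", length(frames))
  kept[[1L]] <- frames[[1L]]
  n_kept <- 1L
  last_hist <- image_histogram(get_img(frames[[1L]]), n_bins)
  for (i in seq_along(frames)[-1L]) {
    h <- image_histogram(get_img(frames[[i]]), n_bins)
    if (histogram_similarity(h, last_hist) > threshold) next
    n_kept <- n_kept + 1L
    kept[[n_kept]] <- frames[[i]]
    last_hist <- h
  }
  kept[seq_len(n_kept)]
}

#' Write a dataset manifest
#'
#' Writes the standard CSV manifest (`path,identity,view,frame_index`,
#' UTF-8, comma-separated) describing a set of labelled frames.
#'
#' @param records List of [frame_record()] objects, or a data frame already
#'   holding the four manifest columns.
#' @param out_path File path to write.
#' @return The manifest data frame, invisibly.
#' @seealso [read_manifest()]
#' @export
write_manifest <- function(records, out_path) {
  df <- if (is.data.frame(records)) {
    records[, c("path", "identity", "view", "frame_index")]
  } else {
    data.frame(
      path = vapply(records, function(r) as.character(r$path), character(1)),
      identity = vapply(records, function(r) r$identity, character(1)),
      view = vapply(records, function(r) r$view, character(1)),
      frame_index = vapply(records, function(r) r$frame_index, integer(1)),
      stringsAsFactors = FALSE
    )
  }
  utils::write.csv(df, out_path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(df)
}

#' Read a dataset manifest
#'
#' @param path CSV manifest written by [write_manifest()].
#' @return Data frame with columns `path`, `identity`, `view`, `frame_index`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(path = "character",
                                       identity = "character",
                                       view = "character",
                                       frame_index = "integer"))
  df
}
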