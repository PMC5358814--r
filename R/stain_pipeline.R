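#' Value channel of the hue-saturation-value decomposition
#'
#' For each pixel, value = max(R, G, B) / 255, i.e. the V channel of the
#' HSV decomposition on a \[0, 1\] scale. Dark precipitate has low value;
#' pale unstained tissue has high value. The value channel is itself a
#' grayscale representation of the image, so no separate luminance
#' conversion is applied.
#'
#' @param image An `rgb_image`.
#' @return A numeric matrix (`height` x `width`) with entries in \[0, 1\].
#' @export
value_channel <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  pmax(image[, , 1L], image[, , 2L], image[, , 3L]) / 255
}

#' Invert a scalar channel
#'
#' Maps every value v to 1 - v, so dark (low-value) stained pixels become
#' bright. Involutive: `invert_channel(invert_channel(x))` equals `x`.
#'
#' @param channel Numeric matrix with values in \[0, 1\].
#' @return The inverted matrix.
#' @export
invert_channel <- function(channel) {
  stopifnot(is.numeric(channel), min(channel) >= 0, max(channel) <= 1)
  1 - channel
}

#' Fixed global threshold mask
#'
#' A pixel is classified as stained when its (inverted-value) intensity is
#' greater than or equal to the threshold. The comparison is inclusive so
#' that a uniform image exactly at the threshold is fully stained; this
#' convention is fixed so results are bit-reproducible.
#'
#' @param channel Numeric matrix with values in \[0, 1\] (normally the
#'   inverted value channel).
#' @param threshold Global threshold in \[0, 1\]; default 0.7, the
#'   published setting used for all images.
#' @return A `binary_mask`: list with elements `mask` (logical matrix,
#'   `TRUE` = stained) and `threshold`.
#' @export
threshold_mask <- function(channel, threshold = 0.7) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must be a single number in [0, 1]", call. = FALSE)
  }
  stopifnot(is.numeric(channel), min(channel) >= 0, max(channel) <= 1)
  structure(list(mask = channel >= threshold, threshold = threshold),
            class = "binary_mask")
}

#' Fraction of image area occupied by stained pixels
#'
#' The denominator is the whole image, not a tissue-only region, matching
#' the published measurement.
#'
#' @param mask A `binary_mask` or a logical matrix.
#' @return A single number in \[0, 1\]: stained pixels / total pixels.
#' @export
area_fraction <- function(mask) {
  m <- if (inherits(mask, "binary_mask")) mask$mask else mask
  stopifnot(is.logical(m))
  sum(m) / length(m)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<binary_mask> %d x %d px, threshold=%.3f, area_fraction=%.5f\n",
              d[2], d[1], x$threshold, area_fraction(x)))
  invisible(x)
}

#' Measure the stained area fraction of one micrograph
#'
#' The full published pipeline: value channel, inversion, fixed global
#' threshold, area occupied. Equivalent to
#' `area_fraction(threshold_mask(invert_channel(value_channel(image)), threshold))`
#' and deterministic for a fixed input.
#'
#' @param image An `rgb_image`.
#' @param threshold Threshold on the inverted value channel (default 0.7).
#' @return The stained area fraction in \[0, 1\].
#' @examples
#' white <- rgb_image(array(255L, dim = c(4, 4, 3)))
#' measure_image(white)  # 0: inverted value 0 is below the threshold
#' @export
measure_image <- function(image, threshold = 0.7) {
  area_fraction(threshold_mask(invert_channel(value_channel(image)),
                               threshold))
}

#' Quantify every image referenced by a manifest
#'
#' Loads each image, runs the measurement pipeline, and returns one row
#' per image.
#'
#' @param manifest A `sample_manifest` (see [load_manifest()]).
#' @param threshold Threshold on the inverted value channel (default 0.7).
#' @return A data frame with columns `sample_id`, `replicate_index`,
#'   `image_path`, `threshold`, `stained_pixels`, `total_pixels`,
#'   `area_fraction`, plus `group`, `is_control`, `section_id` and
#'   `kit_value` carried over from the manifest.
#' @export
quantify_manifest <- function(manifest, threshold = 0.7) {
  manifest <- if (inherits(manifest, "sample_manifest")) manifest else
    as_sample_manifest(manifest)
  res <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- load_image(manifest$image_path[i],
                      sample_id = manifest$sample_id[i],
                      replicate_index = manifest$replicate_index[i])
    bm <- threshold_mask(invert_channel(value_channel(img)), threshold)
    data.frame(sample_id = manifest$sample_id[i],
               replicate_index = manifest$replicate_index[i],
               image_path = manifest$image_path[i],
               threshold = threshold,
               stained_pixels = sum(bm$mask),
               total_pixels = length(bm$mask),
               area_fraction = area_fraction(bm),
               group = manifest$group[i],
               is_control = manifest$is_control[i],
               section_id = manifest$section_id[i],
               kit_value = manifest$kit_value[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
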