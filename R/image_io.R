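#' Read a brightfield micrograph as an 8-bit RGB image
#'
#' Decodes a TIFF, PNG or JPEG file into a 3-channel integer array with
#' intensities in \[0, 255\]. Grayscale sources are expanded to three
#' identical channels, an alpha channel is dropped, and higher-bit-depth
#' sources (e.g. 16-bit TIFF) are linearly rescaled to \[0, 255\] by
#' max-value division.
#'
#' @param path Path to the image file. Format is chosen by extension
#'   (`.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg`).
#' @param sample_id Optional sample identifier to attach to the image.
#' @param replicate_index Optional replicate index (integer >= 1).
#' @return An object of class `rgb_image`: an integer array of dimension
#'   `c(height, width, 3)` with attributes `sample_id` and
#'   `replicate_index`.
#' @examples
#' tmp <- tempfile(fileext = ".png")
#' png::writePNG(array(1, dim = c(2, 2, 3)), tmp)
#' img <- load_image(tmp)
#' range(img)  # 255 255
#' @export
load_image <- function(path, sample_id = NA_character_, replicate_index = 1L) {
  if (!file.exists(path)) {
    stop("cannot read image: file does not exist: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      jpg  = ,
      jpeg = read_jpeg_ebimage(path),
      stop("unsupported image format '", ext, "' for ", path, call. = FALSE)
    ),
    error = function(e) {
      stop("failed to decode image ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  # decoders return values on [0, 1] regardless of source bit depth
  if (is.matrix(arr)) {
    arr <- array(arr, dim = c(dim(arr), 1L))
  }
  nchan <- dim(arr)[3]
  if (nchan == 1L) {
    arr <- array(arr[, , 1L], dim = c(dim(arr)[1:2], 3L))
  } else if (nchan == 2L) {       # gray + alpha
    arr <- array(arr[, , 1L], dim = c(dim(arr)[1:2], 3L))
  } else if (nchan >= 4L) {       # drop alpha
    arr <- arr[, , 1:3, drop = FALSE]
  }
  pix <- array(as.integer(round(arr * 255)), dim = dim(arr))
  rgb_image(pix, sample_id = sample_id, replicate_index = replicate_index)
}

# EBImage stores data as (width, height, channel); transpose to (h, w, c)
read_jpeg_ebimage <- function(path) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("JPEG input requires the EBImage package", call. = FALSE)
  }
  dat <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(dat)) == 2L) t(dat) else aperm(dat, c(2L, 1L, 3L))
}

#' Construct and validate an RGB image object
#'
#' @param pixels Integer array `c(height, width, 3)` with values in
#'   \[0, 255\].
#' @param sample_id,replicate_index Identity metadata carried with the
#'   image.
#' @return An `rgb_image` object.
#' @export
rgb_image <- function(pixels, sample_id = NA_character_, replicate_index = 1L) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) {
    stop("an RGB image must be a height x width x 3 array", call. = FALSE)
  }
  if (d[1] < 1L || d[2] < 1L) {
    stop("image must contain at least one pixel", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L) {
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  }
  structure(array(as.integer(pixels), dim = d),
            sample_id = sample_id,
            replicate_index = as.integer(replicate_index),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d px, sample_id=%s, replicate=%d\n",
              d[2], d[1], attr(x, "sample_id"), attr(x, "replicate_index")))
  invisible(x)
}

#' Write an RGB image losslessly
#'
#' PNG or uncompressed/deflate TIFF only; JPEG output is refused because
#' lossy compression would break pixel-exact ground truth.
#'
#' @param image An `rgb_image`.
#' @param path Destination path (`.png`, `.tif` or `.tiff`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  arr <- unclass(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(arr, path),
    tif  = ,
    tiff = tiff::writeTIFF(arr, path, compression = "deflate"),
    stop("lossless output only: use .png or .tiff, not '", ext, "'",
         call. = FALSE)
  )
  invisible(path)
}

#' Load and validate a sample manifest
#'
#' The manifest CSV is the source of truth for sample, replicate, group and
#' control identity. Required columns: `image_path`, `sample_id`,
#' `replicate_index`, `group`, `is_control`. Optional columns: `kit_value`
#' (paired colorimetric-assay value, blank allowed) and `section_id`
#' (section tier for between-section precision reports).
#'
#' @param path Path to the CSV file.
#' @param base_dir Directory against which relative `image_path` entries
#'   are resolved; defaults to the manifest's own directory.
#' @param check_paths Verify that every referenced image exists (default
#'   `TRUE`).
#' @return A `sample_manifest` data frame with an absolute `image_path`
#'   column.
#' @export
load_manifest <- function(path, base_dir = dirname(path), check_paths = TRUE) {
  if (!file.exists(path)) {
    stop("manifest not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_sample_manifest(df, base_dir = base_dir, check_paths = check_paths)
}

#' Validate a data frame as a sample manifest
#'
#' @param df A data frame with the manifest columns.
#' @inheritParams load_manifest
#' @return A `sample_manifest` data frame.
#' @export
as_sample_manifest <- function(df, base_dir = ".", check_paths = TRUE) {
  required <- c("image_path", "sample_id", "replicate_index", "group",
                "is_control")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$replicate_index <- as.integer(df$replicate_index)
  df$group <- as.character(df$group)
  df$is_control <- parse_logical(df$is_control)
  if (anyNA(df$replicate_index) || any(df$replicate_index < 1L)) {
    stop("replicate_index must be an integer >= 1", call. = FALSE)
  }
  key <- paste(df$sample_id, df$replicate_index, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- which(dup)[1]
    stop(sprintf("duplicate (sample_id, replicate_index) pair: (%s, %d)",
                 df$sample_id[first], df$replicate_index[first]),
         call. = FALSE)
  }
  rel <- !is_absolute_path(df$image_path)
  df$image_path[rel] <- file.path(base_dir, df$image_path[rel])
  if (check_paths) {
    missing_img <- !file.exists(df$image_path)
    if (any(missing_img)) {
      stop("manifest references missing image file(s): ",
           paste(utils::head(df$image_path[missing_img], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  if (!"kit_value" %in% names(df)) df$kit_value <- NA_real_
  df$kit_value <- suppressWarnings(as.numeric(df$kit_value))
  if (!"section_id" %in% names(df)) df$section_id <- "1"
  df$section_id <- as.character(df$section_id)
  class(df) <- c("sample_manifest", "data.frame")
  df
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes")
}

is_absolute_path <- function(p) {
  grepl("^(/|[A-Za-z]:[/\\\\]|\\\\\\\\)", p)
}
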