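# shared fixture builders and the literal per-pixel reference pipeline

uniform_image <- function(r, g = r, b = r, w = 4L, h = 4L) {
  pix <- array(0L, dim = c(h, w, 3L))
  pix[, , 1L] <- r; pix[, , 2L] <- g; pix[, , 3L] <- b
  rgb_image(pix)
}

random_image <- function(w, h, seed) {
  set.seed(seed)
  rgb_image(array(sample(0:255, h * w * 3L, replace = TRUE),
                  dim = c(h, w, 3L)))
}

# literal re-statement of the measurement: explicit loops, no shared code
# with the pipeline under test
ref_measure <- function(image, threshold = 0.7) {
  d <- dim(image)
  stained <- 0L
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      v <- max(image[i, j, 1], image[i, j, 2], image[i, j, 3]) / 255
      if (1 - v >= threshold) stained <- stained + 1L
    }
  }
  stained / (d[1] * d[2])
}

# per-image fraction rows for scoring tests, bypassing image files
fractions_table <- function(sample_means, groups, is_control,
                            replicates = 3L, jitter = 0) {
  rows <- list()
  for (i in seq_along(sample_means)) {
    for (r in seq_len(replicates)) {
      f <- sample_means[i] * (1 + jitter * (r - (replicates + 1) / 2))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("S%02d", i), replicate_index = r,
        area_fraction = f, group = groups[i], is_control = is_control[i],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
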