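#' Parameters for the synthetic stained-section generator
#'
#' The generator emulates the structure the pipeline actually measures: a
#' pale tissue field (high value-channel values) carrying dark orange-brown
#' precipitate blobs (low value). Only the value separation is load-bearing
#' for ground truth; hue is cosmetic. Stain and background value ranges
#' must sit strictly on opposite sides of `1 - threshold` (0.3 at the
#' default 0.7 threshold) with a safety margin, so that every pixel's
#' stained/unstained status is unambiguous even after noise and 8-bit
#' quantization.
#'
#' @param width,height Canvas size in pixels.
#' @param target_fraction Ground-truth stained area fraction in \[0, 1\].
#' @param blob_count Number of precipitate blobs to place, or `NULL`
#'   (default) to keep adding blobs until the target fraction is reached.
#' @param blob_radius_range Blob radius range in pixels.
#' @param background_value_range Value-channel range of unstained tissue;
#'   must lie within (0.3, 1\].
#' @param stain_value_range Value-channel range of precipitate; must lie
#'   within \[0, 0.3).
#' @param noise_sd Gaussian pixel-noise SD on the value channel; noise is
#'   truncated so no pixel crosses the threshold margin.
#' @param noise_margin Half-width of the exclusion band around 0.3 that no
#'   pixel may enter (default 0.02; must be at least 1/255 so 8-bit
#'   rounding cannot flip a pixel).
#' @param seed Integer seed; generation is deterministic given the params.
#' @return A validated `synth_params` list.
#' @export
synth_params <- function(width = 256L, height = 256L, target_fraction = 0.1,
                         blob_count = NULL, blob_radius_range = c(3, 12),
                         background_value_range = c(0.7, 0.95),
                         stain_value_range = c(0.05, 0.25),
                         noise_sd = 0.02, noise_margin = 0.02, seed = 1L) {
  stopifnot(width >= 1L, height >= 1L,
            target_fraction >= 0, target_fraction <= 1,
            length(blob_radius_range) == 2L,
            blob_radius_range[1] >= 1, diff(blob_radius_range) >= 0,
            noise_sd >= 0)
  if (noise_margin < 1 / 255) {
    stop("noise_margin must be at least 1/255 to survive 8-bit quantization",
         call. = FALSE)
  }
  s <- stain_value_range; b <- background_value_range
  if (s[1] < 0 || s[2] >= 0.3 - noise_margin + 1e-12 || s[1] > s[2]) {
    stop("stain_value_range must lie within [0, ", 0.3 - noise_margin,
         ") given the noise margin", call. = FALSE)
  }
  if (b[1] <= 0.3 + noise_margin - 1e-12 || b[2] > 1 || b[1] > b[2]) {
    stop("background_value_range must lie within (", 0.3 + noise_margin,
         ", 1] given the noise margin", call. = FALSE)
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 target_fraction = target_fraction,
                 blob_count = if (is.null(blob_count)) NULL else
                   as.integer(blob_count),
                 blob_radius_range = blob_radius_range,
                 background_value_range = b, stain_value_range = s,
                 noise_sd = noise_sd, noise_margin = noise_margin,
                 seed = as.integer(seed)),
            class = "synth_params")
}

# run expr with a private RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate one synthetic stained section with pixel-exact ground truth
#'
#' Places overlapping disk-shaped precipitate blobs until the stained
#' union reaches the target pixel count (trimming the last blob so the
#' achieved fraction equals `round(target_fraction * width * height)`
#' pixels exactly), renders precipitate in warm orange-brown hues and
#' tissue in pale pink, adds margin-truncated Gaussian value noise, and
#' quantizes to 8 bits. Because no pixel may cross the threshold margin,
#' [measure_image()] at the default 0.7 threshold recovers the true
#' fraction exactly.
#'
#' @param params A `synth_params` object.
#' @return A `synth_section`: list with `image` (an `rgb_image`),
#'   `true_mask` (a `binary_mask`), `true_fraction` and `params`.
#' @examples
#' gt <- generate_section(synth_params(width = 64, height = 64,
#'                                     target_fraction = 0.2, seed = 7))
#' measure_image(gt$image) == gt$true_fraction  # TRUE
#' @export
generate_section <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  with_seed(params$seed, {
    w <- params$width; h <- params$height
    total <- w * h
    target_px <- round(params$target_fraction * total)
    mask <- matrix(FALSE, h, w)
    if (target_px >= total) {
      mask[] <- TRUE
    } else if (target_px > 0L) {
      mask <- place_blobs(mask, target_px, params)
    }
    val <- matrix(stats::runif(total, params$background_value_range[1],
                               params$background_value_range[2]), h, w)
    ns <- sum(mask)
    if (ns > 0L) {
      val[mask] <- stats::runif(ns, params$stain_value_range[1],
                                params$stain_value_range[2])
    }
    if (params$noise_sd > 0) {
      val <- val + stats::rnorm(total, 0, params$noise_sd)
      # truncate: stained pixels stay below the margin band, background above
      lo_stain <- 0; hi_stain <- 0.3 - params$noise_margin
      lo_bg <- 0.3 + params$noise_margin; hi_bg <- 1
      val[mask] <- pmin(pmax(val[mask], lo_stain), hi_stain)
      val[!mask] <- pmin(pmax(val[!mask], lo_bg), hi_bg)
    }
    r_byte <- matrix(as.integer(round(val * 255)), h, w)
    # warm orange-brown precipitate vs pale pink tissue; R is the channel
    # maximum everywhere so the value channel equals r_byte / 255
    g_byte <- ifelse(mask, round(r_byte * 0.55), round(r_byte * 0.84))
    b_byte <- ifelse(mask, round(r_byte * 0.15), round(r_byte * 0.90))
    pix <- array(0L, dim = c(h, w, 3L))
    pix[, , 1L] <- r_byte; pix[, , 2L] <- g_byte; pix[, , 3L] <- b_byte
    structure(list(image = rgb_image(pix),
                   true_mask = structure(list(mask = mask, threshold = 0.7),
                                         class = "binary_mask"),
                   true_fraction = sum(mask) / total,
                   params = params),
              class = "synth_section")
  })
}

# add disk blobs until the union holds >= target_px pixels, then trim the
# most recent blob's contribution so the count is exact
place_blobs <- function(mask, target_px, params) {
  h <- nrow(mask); w <- ncol(mask)
  rr <- params$blob_radius_range
  n_blobs <- 0L
  max_blobs <- if (is.null(params$blob_count)) 100000L else params$blob_count
  while (sum(mask) < target_px && n_blobs < max_blobs) {
    cx <- stats::runif(1, 1, w); cy <- stats::runif(1, 1, h)
    rad <- stats::runif(1, rr[1], rr[2])
    xs <- max(1L, floor(cx - rad)):min(w, ceiling(cx + rad))
    ys <- max(1L, floor(cy - rad)):min(h, ceiling(cy + rad))
    disk <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= rad^2
    new_px <- which(disk & !mask[ys, xs, drop = FALSE])
    over <- sum(mask) + length(new_px) - target_px
    if (over > 0L) {
      # trim: drop a random subset of this blob's new pixels
      new_px <- sample(new_px, length(new_px) - over)
    }
    sub <- mask[ys, xs, drop = FALSE]
    sub[new_px] <- TRUE
    mask[ys, xs] <- sub
    n_blobs <- n_blobs + 1L
  }
  short <- target_px - sum(mask)
  if (short > 0L) {
    # fixed blob budget left us short: rebalance with random single pixels
    pool <- which(!mask)
    mask[sample(pool, short)] <- TRUE
  }
  mask
}

#' @export
print.synth_section <- function(x, ...) {
  cat(sprintf("<synth_section> %d x %d px, true stained fraction %.5f (seed %d)\n",
              x$params$width, x$params$height, x$true_fraction,
              x$params$seed))
  invisible(x)
}

#' Generate a synthetic cohort of stained sections on disk
#'
#' Builds a control group plus treatment groups whose mean stained
#' fractions are `control_fraction * target_ratio`, writes one PNG per
#' replicate, and emits a valid sample manifest plus a ground-truth table.
#' Per-replicate fractions are jittered multiplicatively with the
#' requested CV. A synthetic paired `kit_value` (proportional to the true
#' sample fraction with 2% noise) is included so method-comparison runs
#' work end to end.
#'
#' @param group_specs Data frame with columns `group`, `n_samples`,
#'   `target_ratio` and `is_control`. Exactly one control group with
#'   `n_samples >= 3` is required; its `target_ratio` must be 1.
#' @param control_fraction Mean stained area fraction of control samples.
#' @param replicates Replicate images per sample (default 5, the published
#'   practice).
#' @param dir Output directory (created if missing).
#' @param seed Master seed; all image seeds and jitter derive from it.
#' @param width,height Image size in pixels.
#' @param replicate_cv Multiplicative jitter CV across replicates
#'   (fractional, default 0.03).
#' @param max_fraction Feasibility ceiling for stained fractions; targets
#'   above it are capped with a warning.
#' @return Invisibly, a list with `manifest` (a `sample_manifest`),
#'   `truth` (per-replicate true fractions) and the file paths written
#'   (`manifest_path`, `truth_path`).
#' @export
generate_cohort <- function(group_specs, control_fraction = 0.015,
                            replicates = 5L, dir = tempfile("cohort"),
                            seed = 1L, width = 128L, height = 128L,
                            replicate_cv = 0.03, max_fraction = 0.9) {
  stopifnot(is.data.frame(group_specs),
            all(c("group", "n_samples", "target_ratio", "is_control") %in%
                  names(group_specs)))
  ctrl <- group_specs[group_specs$is_control, , drop = FALSE]
  if (nrow(ctrl) != 1L || ctrl$n_samples < 3L) {
    stop("exactly one control group with at least 3 samples is required",
         call. = FALSE)
  }
  if (ctrl$target_ratio != 1) {
    stop("the control group must have target_ratio 1", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); truth <- list()
  with_seed(seed, {
    for (gi in seq_len(nrow(group_specs))) {
      g <- group_specs[gi, ]
      target <- control_fraction * g$target_ratio
      if (target > max_fraction) {
        warning(sprintf("group %s: target fraction %.3f capped at %.3f",
                        g$group, target, max_fraction), call. = FALSE)
        target <- max_fraction
      }
      for (si in seq_len(g$n_samples)) {
        sid <- sprintf("%s_%02d", g$group, si)
        kit <- target * 100 * (1 + stats::rnorm(1, 0, 0.02))
        for (ri in seq_len(replicates)) {
          f <- target * (1 + stats::rnorm(1, 0, replicate_cv))
          f <- min(max(f, 0), max_fraction)
          img_seed <- sample.int(.Machine$integer.max - 1L, 1L)
          gt <- generate_section(synth_params(
            width = width, height = height, target_fraction = f,
            seed = img_seed))
          fname <- sprintf("%s_r%d.png", sid, ri)
          write_image(gt$image, file.path(dir, fname))
          rows[[length(rows) + 1L]] <- data.frame(
            image_path = fname, sample_id = sid, replicate_index = ri,
            group = g$group, is_control = g$is_control, kit_value = kit,
            stringsAsFactors = FALSE)
          truth[[length(truth) + 1L]] <- data.frame(
            sample_id = sid, replicate_index = ri,
            true_fraction = gt$true_fraction, stringsAsFactors = FALSE)
        }
      }
    }
  })
  manifest_df <- do.call(rbind, rows)
  truth_df <- do.call(rbind, truth)
  manifest_path <- file.path(dir, "manifest.csv")
  truth_path <- file.path(dir, "truth.csv")
  utils::write.csv(manifest_df, manifest_path, row.names = FALSE)
  utils::write.csv(truth_df, truth_path, row.names = FALSE)
  invisible(list(manifest = as_sample_manifest(manifest_df, base_dir = dir),
                 truth = truth_df,
                 manifest_path = manifest_path, truth_path = truth_path,
                 dir = dir))
}
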