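#' Coefficient of variation, in percent
#'
#' Sample standard deviation (n - 1 denominator) over the mean, times 100.
#' Defined as 0 when all replicates are zero or when only one replicate is
#' available.
#'
#' @param x Numeric vector of replicate measurements (>= 1 value).
#' @return CV in percent (>= 0).
#' @export
cv_percent <- function(x) {
  if (length(x) == 0L) stop("CV of an empty vector is undefined", call. = FALSE)
  if (length(x) == 1L) return(0)
  m <- mean(x)
  if (m == 0) {
    if (all(x == 0)) return(0)
    stop("CV undefined: replicate mean is zero with nonzero spread",
         call. = FALSE)
  }
  100 * stats::sd(x) / m
}

#' Summarise replicate area fractions for one sample
#'
#' @param fractions Numeric vector of replicate area fractions (length
#'   >= 1, each in \[0, 1\]).
#' @param sample_id,group Sample identity.
#' @param is_control Whether this sample is a healthy control used for
#'   normalization.
#' @return A `stain_measurement`: list with `sample_id`, `group`,
#'   `is_control`, `replicate_fractions`, `n_replicates`, `mean_fraction`,
#'   `cv_percent` and `single_replicate` flag.
#' @export
summarize_sample <- function(fractions, sample_id, group = NA_character_,
                             is_control = FALSE) {
  if (length(fractions) < 1L) {
    stop("at least one replicate fraction is required for sample ",
         sample_id, call. = FALSE)
  }
  if (anyNA(fractions) || min(fractions) < 0 || max(fractions) > 1) {
    stop("area fractions must lie in [0, 1] (sample ", sample_id, ")",
         call. = FALSE)
  }
  structure(list(sample_id = as.character(sample_id),
                 group = as.character(group),
                 is_control = isTRUE(is_control),
                 replicate_fractions = as.numeric(fractions),
                 n_replicates = length(fractions),
                 mean_fraction = mean(fractions),
                 cv_percent = cv_percent(fractions),
                 single_replicate = length(fractions) == 1L),
            class = "stain_measurement")
}

#' Summarise a table of per-image fractions into per-sample measurements
#'
#' @param fractions Data frame with columns `sample_id`, `area_fraction`
#'   and (optionally) `group`, `is_control` — e.g. the output of
#'   [quantify_manifest()].
#' @param min_replicates Warn for samples with fewer replicates than this
#'   (default 3; the published practice is 5 measurements per sample).
#' @return A data frame with one row per sample: `sample_id`, `group`,
#'   `is_control`, `n_replicates`, `mean_fraction`, `cv_percent`.
#' @export
summarize_cohort <- function(fractions, min_replicates = 3L) {
  stopifnot(is.data.frame(fractions),
            all(c("sample_id", "area_fraction") %in% names(fractions)))
  if (!"group" %in% names(fractions)) fractions$group <- NA_character_
  if (!"is_control" %in% names(fractions)) fractions$is_control <- FALSE
  ids <- unique(fractions$sample_id)
  rows <- lapply(ids, function(id) {
    sub <- fractions[fractions$sample_id == id, , drop = FALSE]
    m <- summarize_sample(sub$area_fraction, id,
                          group = sub$group[1],
                          is_control = sub$is_control[1])
    data.frame(sample_id = m$sample_id, group = m$group,
               is_control = m$is_control, n_replicates = m$n_replicates,
               mean_fraction = m$mean_fraction, cv_percent = m$cv_percent,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  few <- out$n_replicates < min_replicates
  if (any(few)) {
    warning(sum(few), " sample(s) have fewer than ", min_replicates,
            " replicates: ", paste(out$sample_id[few], collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Normalize sample measurements to the healthy-control average
#'
#' Each sample's mean area fraction is divided by the mean over control
#' samples of their mean fractions, yielding the area ratio. At least 3
#' control samples are required; controls receive ratios too, and their
#' ratios average to 1 by construction.
#'
#' @param measurements Per-sample data frame from [summarize_cohort()]
#'   (columns `sample_id`, `is_control`, `mean_fraction` required).
#' @return The input with an `area_ratio` column appended.
#' @export
normalize_to_controls <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            all(c("sample_id", "is_control", "mean_fraction") %in%
                  names(measurements)))
  n_ctrl <- sum(measurements$is_control)
  if (n_ctrl < 3L) {
    stop("normalization requires at least 3 control samples from healthy ",
         "tissue; found ", n_ctrl, call. = FALSE)
  }
  ctrl_mean <- mean(measurements$mean_fraction[measurements$is_control])
  if (ctrl_mean <= 0) {
    stop("degenerate cohort: control samples have zero mean stained area, ",
         "area ratios are undefined", call. = FALSE)
  }
  measurements$area_ratio <- measurements$mean_fraction / ctrl_mean
  measurements
}

#' Assign the integer Ammonia Score from a control-normalized area ratio
#'
#' Scoring rubric (bins left-closed, right-open):
#' \tabular{ll}{
#'   area ratio \[0, 2)   \tab score 1 \cr
#'   area ratio \[2, 10)  \tab score 2 \cr
#'   area ratio \[10, 20) \tab score 3 \cr
#'   area ratio \[20, 30) \tab score 4 \cr
#'   area ratio \[30, 40) \tab score 5 \cr
#'   area ratio \[40, Inf) \tab score 6
#' }
#' The published ranges share their endpoints; the half-open reading used
#' here is the unique total, non-overlapping cover of \[0, Inf), and every
#' boundary value maps to the higher bin.
#'
#' @param area_ratio Numeric vector of non-negative, finite area ratios.
#' @return Integer vector of scores in 1..6.
#' @examples
#' assign_score(c(1, 5, 15, 25, 35, 50))  # 1 2 3 4 5 6
#' @export
assign_score <- function(area_ratio) {
  if (!is.numeric(area_ratio) || anyNA(area_ratio) ||
      any(!is.finite(area_ratio)) || any(area_ratio < 0)) {
    stop("area ratios must be finite and non-negative", call. = FALSE)
  }
  as.integer(findInterval(area_ratio, c(0, 2, 10, 20, 30, 40)))
}

# rubric identifier embedded in reports for provenance
SCORE_BIN_TABLE_VERSION <- "AS-6bin-v1"

#' Score a whole cohort from per-image fractions
#'
#' Composition of [summarize_cohort()], [normalize_to_controls()] and
#' [assign_score()]: per-sample means and CVs, control normalization, and
#' the integer Ammonia Score, plus a per-group summary.
#'
#' @param fractions Per-image data frame from [quantify_manifest()] (or
#'   any data frame with `sample_id`, `area_fraction`, `group`,
#'   `is_control` columns).
#' @param min_replicates Passed to [summarize_cohort()].
#' @return An `ammonia_scores` object: list with `samples` (per-sample
#'   data frame including `area_ratio` and `ammonia_score`), `groups`
#'   (per-group mean ratio, mean score, n), `control_ids`,
#'   `control_mean_fraction` and `bin_table_version`.
#' @export
score_cohort <- function(fractions, min_replicates = 3L) {
  meas <- summarize_cohort(fractions, min_replicates = min_replicates)
  meas <- normalize_to_controls(meas)
  meas$ammonia_score <- assign_score(meas$area_ratio)
  grp_names <- unique(meas$group)
  groups <- do.call(rbind, lapply(grp_names, function(g) {
    sub <- meas[meas$group == g, , drop = FALSE]
    data.frame(group = g, n = nrow(sub),
               mean_area_ratio = mean(sub$area_ratio),
               mean_score = mean(sub$ammonia_score),
               stringsAsFactors = FALSE)
  }))
  structure(list(samples = meas,
                 groups = groups,
                 control_ids = meas$sample_id[meas$is_control],
                 control_mean_fraction =
                   mean(meas$mean_fraction[meas$is_control]),
                 bin_table_version = SCORE_BIN_TABLE_VERSION),
            class = "ammonia_scores")
}

#' @export
print.ammonia_scores <- function(x, ...) {
  cat("Ammonia Score results (", nrow(x$samples), " samples, ",
      length(x$control_ids), " controls)\n", sep = "")
  cat(sprintf("control mean area fraction: %.5f\n", x$control_mean_fraction))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ammonia_scores <- function(object, ...) {
  cat("Per-sample Ammonia Scores\n")
  df <- object$samples
  df$mean_fraction <- signif(df$mean_fraction, 5)
  df$cv_percent <- signif(df$cv_percent, 4)
  df$area_ratio <- signif(df$area_ratio, 5)
  print(df, row.names = FALSE)
  invisible(object)
}
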