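#' Pearson method comparison against a paired reference assay
#'
#' Product-moment correlation between the morphological measurement and a
#' paired reference (e.g. colorimetric-kit) value across specimens, with a
#' two-sided p-value from the t transform on n - 2 degrees of freedom. An
#' exact permutation p-value is available for small n.
#'
#' @param morphological Numeric vector of morphological values (area
#'   fractions, ratios, or scores).
#' @param kit Numeric vector of paired reference values, same length.
#' @param p_method `"t"` (default) or `"permutation"` (full enumeration,
#'   n <= 8).
#' @return A `comparison_result`: list with `n_pairs`, `pearson_r`,
#'   `p_value` and `p_method`.
#' @export
pearson_compare <- function(morphological, kit, p_method = c("t", "permutation")) {
  p_method <- match.arg(p_method)
  keep <- stats::complete.cases(morphological, kit)
  x <- morphological[keep]; y <- kit[keep]
  n <- length(x)
  if (n < 3L) {
    stop("Pearson comparison requires at least 3 complete pairs; found ", n,
         call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("Pearson comparison undefined: a coordinate has zero variance",
         call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  p <- if (p_method == "t") ct$p.value else permutation_cor_p(x, y)
  structure(list(n_pairs = n, pearson_r = r, p_value = p,
                 p_method = p_method),
            class = "comparison_result")
}

# exact two-sided permutation p for |r|; feasible for n <= 8 (<= 40320 perms)
permutation_cor_p <- function(x, y) {
  n <- length(x)
  if (n > 8L) {
    stop("exact permutation p-value supported for n <= 8 only", call. = FALSE)
  }
  perms <- all_permutations(n)
  r_obs <- abs(stats::cor(x, y))
  r_all <- abs(apply(perms, 1L, function(idx) stats::cor(x, y[idx])))
  mean(r_all >= r_obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Pearson method comparison: r = %.4f, p = %.4g (n = %d, %s)\n",
              x$pearson_r, x$p_value, x$n_pairs,
              if (x$p_method == "t") "t transform" else "exact permutation"))
  invisible(x)
}

#' Between-group comparison of area ratios or scores
#'
#' Two-sided Mann-Whitney U by default: the Ammonia Score is ordinal and
#' cohorts are small, so a rank test is the defensible default. The exact
#' null distribution is used when min(n_a, n_b) <= 8, both n <= 25 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction. A Welch t-test is available via `method`.
#' The method actually used is recorded in the result.
#'
#' @param a,b Numeric vectors of per-sample values (ratios or scores) for
#'   the two groups.
#' @param method `"mann_whitney"` (default) or `"welch"`.
#' @param group_a,group_b Group labels carried into the result.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05, the published criterion).
#' @return A `group_test`: list with `group_a`, `group_b`, `n_a`, `n_b`,
#'   `statistic`, `p_value`, `significant_at_0_05`, `method_used`.
#' @export
group_compare <- function(a, b, method = c("mann_whitney", "welch"),
                          group_a = "A", group_b = "B", alpha = 0.05) {
  method <- match.arg(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (method == "mann_whitney") {
    # only ties ACROSS groups make the classical exact U distribution
    # inapplicable; within-group duplicates leave U and its null unchanged
    cross_ties <- any(a %in% b)
    use_exact <- !cross_ties && min(length(a), length(b)) <= 8L &&
      length(a) <= 25L && length(b) <= 25L
    if (use_exact) {
      U <- sum(outer(a, b, ">"))
      m <- length(a); n <- length(b)
      p_lo <- stats::pwilcox(U, m, n)
      p_hi <- 1 - stats::pwilcox(U - 1, m, n)
      ht <- list(statistic = U, p.value = min(1, 2 * min(p_lo, p_hi)))
      used <- "mann_whitney_exact"
    } else {
      ht <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
      )
      used <- "mann_whitney_normal_tie_corrected"
    }
  } else {
    if (length(a) < 2L || length(b) < 2L) {
      stop("Welch t-test requires at least 2 values per group", call. = FALSE)
    }
    ht <- stats::t.test(a, b, var.equal = FALSE)
    used <- "welch_t"
  }
  structure(list(group_a = group_a, group_b = group_b,
                 n_a = length(a), n_b = length(b),
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 significant_at_0_05 = ht$p.value < alpha,
                 method_used = used),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s vs %s (n = %d, %d): %s, statistic = %.4g, p = %.4g%s\n",
              x$group_a, x$group_b, x$n_a, x$n_b, x$method_used,
              x$statistic, x$p_value,
              if (x$significant_at_0_05) " *" else ""))
  invisible(x)
}

#' Replicate and between-section precision report
#'
#' Within-section precision is the CV across the repeated field
#' measurements of one section; between-section precision is the CV across
#' section means of the same specimen, available when the manifest carries
#' a `section_id` column with more than one tier.
#'
#' @param fractions Per-image data frame with columns `sample_id`,
#'   `area_fraction` and optionally `section_id` (defaults to a single
#'   tier).
#' @return A list of class `cv_report` with `within` (per sample x
#'   section: `n_replicates`, `mean_fraction`, `cv_percent`,
#'   `single_replicate`) and `across` (per sample: `n_sections`,
#'   `mean_fraction`, `cv_percent`; `NA` CV when only one section exists).
#' @export
replicate_cv_report <- function(fractions) {
  stopifnot(is.data.frame(fractions), nrow(fractions) > 0L,
            all(c("sample_id", "area_fraction") %in% names(fractions)))
  if (!"section_id" %in% names(fractions)) fractions$section_id <- "1"
  keyed <- unique(fractions[, c("sample_id", "section_id")])
  within <- do.call(rbind, lapply(seq_len(nrow(keyed)), function(i) {
    sub <- fractions[fractions$sample_id == keyed$sample_id[i] &
                       fractions$section_id == keyed$section_id[i], ]
    data.frame(sample_id = keyed$sample_id[i],
               section_id = keyed$section_id[i],
               n_replicates = nrow(sub),
               mean_fraction = mean(sub$area_fraction),
               cv_percent = cv_percent(sub$area_fraction),
               single_replicate = nrow(sub) == 1L,
               stringsAsFactors = FALSE)
  }))
  across <- do.call(rbind, lapply(unique(within$sample_id), function(id) {
    sub <- within[within$sample_id == id, ]
    data.frame(sample_id = id,
               n_sections = nrow(sub),
               mean_fraction = mean(sub$mean_fraction),
               cv_percent = if (nrow(sub) > 1L)
                 cv_percent(sub$mean_fraction) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(within = within, across = across), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Within-section (replicate) precision:\n")
  print(x$within, row.names = FALSE)
  if (any(x$across$n_sections > 1L)) {
    cat("Between-section precision:\n")
    print(x$across, row.names = FALSE)
  }
  invisible(x)
}
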