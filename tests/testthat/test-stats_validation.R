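test_that("Pearson comparison recovers exact linear relations", {
  x <- 1:5
  up <- pearson_compare(x, 2 * x + 1)
  expect_equal(up$pearson_r, 1)
  expect_lt(up$p_value, 1e-6)
  down <- pearson_compare(x, -3 * x + 10)
  expect_equal(down$pearson_r, -1)
})

test_that("Pearson r matches the direct product-moment formula", {
  # fixed synthetic morphology/kit table; oracle is the formula itself
  morph <- c(0.012, 0.034, 0.051, 0.080, 0.110, 0.145)
  kit <- c(1.1, 3.9, 4.6, 8.8, 10.2, 15.0)
  r_formula <- sum((morph - mean(morph)) * (kit - mean(kit))) /
    sqrt(sum((morph - mean(morph))^2) * sum((kit - mean(kit))^2))
  res <- pearson_compare(morph, kit)
  expect_equal(res$pearson_r, r_formula, tolerance = 1e-12)
  expect_equal(res$n_pairs, 6L)
  # p from the t transform on n - 2 df
  tstat <- r_formula * sqrt(4 / (1 - r_formula^2))
  expect_equal(res$p_value, 2 * stats::pt(-abs(tstat), df = 4),
               tolerance = 1e-12)
})

test_that("Pearson comparison validates input and is affine invariant", {
  expect_error(pearson_compare(1:2, 2:3), "at least 3")
  expect_error(pearson_compare(c(1, 1, 1), 1:3), "zero variance")
  set.seed(21)
  x <- runif(8); y <- runif(8)
  base <- pearson_compare(x, y)
  shifted <- pearson_compare(3 * x + 2, 0.5 * y - 1)
  expect_equal(shifted$pearson_r, base$pearson_r, tolerance = 1e-12)
  flipped <- pearson_compare(-x, y)
  expect_equal(flipped$pearson_r, -base$pearson_r, tolerance = 1e-12)
})

test_that("exact permutation p agrees with the observed extreme on a line", {
  x <- c(1, 2, 3, 4, 5)
  res <- pearson_compare(x, x^2, p_method = "permutation")
  # only orderings reproducing |r| >= observed are counted
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 0.05)
})

test_that("group comparison uses the exact U null for small untied groups", {
  a <- c(1, 1, 1, 1); b <- c(100, 100, 100, 100)
  res <- group_compare(a, b, group_a = "low", group_b = "high")
  expect_identical(res$method_used, "mann_whitney_exact")

  # oracle: enumerate all C(8,4) group labelings of the pooled values
  pool <- c(a, b)
  labelings <- utils::combn(8, 4)
  U_all <- apply(labelings, 2, function(idx) {
    sum(outer(pool[idx], pool[-idx], `>`)) +
      0.5 * sum(outer(pool[idx], pool[-idx], `==`))
  })
  U_obs <- sum(outer(a, b, `>`))
  p_exact <- min(1, 2 * min(mean(U_all <= U_obs), mean(U_all >= U_obs)))
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
  expect_equal(res$p_value, 2 / choose(8, 4), tolerance = 1e-12)
  expect_true(res$significant_at_0_05)
})

test_that("group comparison is symmetric and null on exchangeable data", {
  same <- group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.99)
  expect_false(same$significant_at_0_05)

  set.seed(4)
  a <- rnorm(6); b <- rnorm(7) + 1
  ab <- group_compare(a, b)
  ba <- group_compare(b, a)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_equal(ab$statistic, length(a) * length(b) - ba$statistic)

  wt <- group_compare(a, b, method = "welch")
  tw <- group_compare(b, a, method = "welch")
  expect_identical(wt$method_used, "welch_t")
  expect_equal(wt$statistic, -tw$statistic, tolerance = 1e-12)
  expect_error(group_compare(numeric(0), 1:3), "non-empty")
})

test_that("ties across groups fall back to the corrected normal approximation", {
  res <- group_compare(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_identical(res$method_used, "mann_whitney_normal_tie_corrected")
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("CV report separates within- and between-section precision", {
  fr <- data.frame(
    sample_id = rep("S1", 6),
    section_id = rep(c("sec1", "sec2"), each = 3),
    area_fraction = c(0.10, 0.10, 0.10, 0.20, 0.20, 0.20))
  rep <- replicate_cv_report(fr)
  expect_equal(rep$within$cv_percent, c(0, 0))
  expect_gt(rep$across$cv_percent, 0)
  expect_equal(rep$across$n_sections, 2L)

  flat <- data.frame(sample_id = "S2", area_fraction = rep(0.3, 5))
  rep2 <- replicate_cv_report(flat)
  expect_equal(rep2$within$cv_percent, 0)
  expect_true(is.na(rep2$across$cv_percent))   # one section: undefined
})

test_that("CV is scale invariant and matches the stated noise level", {
  x <- c(0.08, 0.1, 0.12)
  expect_equal(cv_percent(x), cv_percent(10 * x), tolerance = 1e-12)
  expect_equal(cv_percent(rep(0.4, 4)), 0)
  expect_equal(cv_percent(c(0, 0, 0)), 0)

  # replicates with 3% multiplicative noise should report CVs near 3%
  set.seed(17)
  cvs <- replicate(200, {
    mu <- runif(1, 0.01, 0.3)
    cv_percent(mu * (1 + rnorm(5, 0, 0.03)))
  })
  expect_gte(stats::median(cvs), 2)
  expect_lte(stats::median(cvs), 4)
})
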