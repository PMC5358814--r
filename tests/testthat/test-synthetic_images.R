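test_that("generated sections are recovered exactly by the pipeline", {
  for (f in c(0.01, 0.05, 0.1, 0.2, 0.4)) {
    # noise disabled: zero error
    gt <- generate_section(synth_params(width = 96, height = 96,
                                        target_fraction = f,
                                        noise_sd = 0, seed = 31))
    expect_identical(measure_image(gt$image), gt$true_fraction)
    expect_equal(gt$true_fraction, f, tolerance = 0.01)
    # margin-truncated noise: error stays within the stated bound
    gn <- generate_section(synth_params(width = 96, height = 96,
                                        target_fraction = f,
                                        noise_sd = 0.03, seed = 32))
    expect_lte(abs(measure_image(gn$image) - gn$true_fraction), 0.002)
  }
})

test_that("degenerate target fractions produce empty and full masks", {
  none <- generate_section(synth_params(width = 32, height = 32,
                                        target_fraction = 0, seed = 1))
  expect_equal(none$true_fraction, 0)
  expect_equal(measure_image(none$image), 0)
  all_st <- generate_section(synth_params(width = 32, height = 32,
                                          target_fraction = 1, seed = 1))
  expect_equal(all_st$true_fraction, 1)
  expect_equal(measure_image(all_st$image), 1)
})

test_that("the ground-truth mask, not blob bookkeeping, defines the fraction", {
  gt <- generate_section(synth_params(width = 64, height = 64,
                                      target_fraction = 0.2, seed = 7))
  expect_equal(gt$true_fraction, area_fraction(gt$true_mask))
  expect_identical(gt$true_mask$mask,
                   threshold_mask(invert_channel(value_channel(gt$image)),
                                  0.7)$mask)
})

test_that("generation is deterministic for a fixed seed", {
  p <- synth_params(width = 48, height = 48, target_fraction = 0.15, seed = 9)
  a <- generate_section(p); b <- generate_section(p)
  expect_identical(as.integer(a$image), as.integer(b$image))
  expect_identical(a$true_mask$mask, b$true_mask$mask)
  other <- generate_section(synth_params(width = 48, height = 48,
                                         target_fraction = 0.15, seed = 10))
  expect_false(identical(as.integer(a$image), as.integer(other$image)))
  # generation must not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_section(p)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("infeasible value ranges are rejected", {
  expect_error(synth_params(stain_value_range = c(0.1, 0.35)), "stain_value_range")
  expect_error(synth_params(background_value_range = c(0.25, 0.9)),
               "background_value_range")
  expect_error(synth_params(noise_margin = 0.001), "1/255")
})

test_that("generated cohorts flow through scoring with the intended ratios", {
  specs <- data.frame(group = c("Ctrl", "Injury"),
                      n_samples = c(4L, 4L),
                      target_ratio = c(1, 15),
                      is_control = c(TRUE, FALSE))
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(specs, control_fraction = 0.015, replicates = 3L,
                            dir = dir, seed = 5, width = 64L, height = 64L)
  expect_s3_class(cohort$manifest, "sample_manifest")
  expect_identical(nrow(cohort$manifest), 24L)
  expect_true(file.exists(cohort$manifest_path))

  fr <- quantify_manifest(cohort$manifest)
  # the generator's own truth table is the oracle for every image
  merged <- merge(fr, cohort$truth, by = c("sample_id", "replicate_index"))
  expect_equal(merged$area_fraction, merged$true_fraction)

  res <- score_cohort(fr)
  inj <- res$samples[res$samples$group == "Injury", ]
  expect_true(all(inj$ammonia_score == 3L))
  expect_true(all(res$samples$ammonia_score[res$samples$is_control] == 1L))
})

test_that("cohort regeneration with one seed is byte-identical on disk", {
  specs <- data.frame(group = "Ctrl", n_samples = 3L, target_ratio = 1,
                      is_control = TRUE)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(specs, replicates = 2L, dir = d1, seed = 42,
                  width = 32L, height = 32L)
  generate_cohort(specs, replicates = 2L, dir = d2, seed = 42,
                  width = 32L, height = 32L)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("cohort validation enforces controls and feasibility", {
  bad <- data.frame(group = "Ctrl", n_samples = 2L, target_ratio = 1,
                    is_control = TRUE)
  expect_error(generate_cohort(bad), "at least 3")
  no_ctrl <- data.frame(group = "G", n_samples = 4L, target_ratio = 2,
                        is_control = FALSE)
  expect_error(generate_cohort(no_ctrl), "control group")
  hot <- data.frame(group = c("Ctrl", "X"), n_samples = c(3L, 1L),
                    target_ratio = c(1, 80), is_control = c(TRUE, FALSE))
  expect_warning(
    generate_cohort(hot, control_fraction = 0.05, replicates = 1L,
                    dir = withr::local_tempdir(), width = 32L, height = 32L),
    "capped")
})
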