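test_that("whole-pixel allocation hits planted fractions and target score", {
  # exact when fractions divide the pixel count evenly
  cnt <- allocate_class_counts(1000, 0.2, 0.3, 0.1)
  expect_identical(unlist(cnt),
                   c(n_weak = 200L, n_medium = 300L, n_strong = 100L,
                     n_negative = 400L, n_total = 1000L))

  # otherwise the realized weighted score is the closest grid point to the
  # target, so the realized H-score is within 0.5/n of the planted one
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(50:5000, 1)
    fr <- runif(3); fr <- fr / sum(fr) * runif(1)
    cnt <- allocate_class_counts(n, fr[1], fr[2], fr[3])
    expect_equal(cnt$n_total,
                 cnt$n_weak + cnt$n_medium + cnt$n_strong + cnt$n_negative)
    target_h <- fr[1] + 2 * fr[2] + 3 * fr[3]
    realized_h <- (cnt$n_weak + 2 * cnt$n_medium + 3 * cnt$n_strong) / n
    expect_lte(abs(realized_h - target_h), 0.5 / n + 1e-12)
    # largest remainder keeps each class within one pixel of its quota and
    # the score correction moves at most a few more single pixels
    expect_lte(abs(cnt$n_weak - n * fr[1]), 4)
    expect_lte(abs(cnt$n_medium - n * fr[2]), 4)
    expect_lte(abs(cnt$n_strong - n * fr[3]), 4)
  }
})

test_that("H-score inversion reproduces the target under the fixed shape", {
  for (h in seq(0, 3, by = 0.05)) {
    fr <- hscore_to_fractions(h)
    expect_equal(fr$frac_weak + 2 * fr$frac_medium + 3 * fr$frac_strong, h,
                 tolerance = 1e-12)
    expect_lte(fr$frac_weak + fr$frac_medium + fr$frac_strong, 1 + 1e-12)
  }
  # above the mixture-shape maximum the generator goes strong-only
  fr <- hscore_to_fractions(2.4)
  expect_equal(fr$frac_weak, 0)
  expect_equal(fr$frac_medium, 0)
  expect_equal(fr$frac_strong, 0.8)
  expect_error(hscore_to_fractions(3.2), "\\[0, 3\\]")
})

test_that("identical specs generate byte-identical images", {
  spec <- synthetic_image_spec(40, 40, 0.15, 0.25, 0.05, roi_shape = "disc",
                               noise_sd = 3, seed = 99)
  g1 <- generate_image(spec)
  g2 <- generate_image(spec)
  expect_identical(g1$image, g2$image)
  expect_identical(g1$labels, g2$labels)
  g3 <- generate_image(synthetic_image_spec(40, 40, 0.15, 0.25, 0.05,
                                            roi_shape = "disc", noise_sd = 3,
                                            seed = 100))
  expect_false(identical(g1$image, g3$image))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(555)
  before <- runif(1)
  set.seed(555)
  invisible(generate_image(synthetic_image_spec(16, 16, 0.1, seed = 4)))
  expect_identical(runif(1), before)
})

test_that("zero-noise images are classified exactly as planted", {
  specs <- list(
    synthetic_image_spec(64, 64, 0.20, 0.30, 0.10, seed = 42),
    synthetic_image_spec(33, 57, 0.05, 0, 0.85, seed = 8),
    synthetic_image_spec(50, 50, 0, 0, 0, seed = 2),
    synthetic_image_spec(48, 48, 0.3, 0.3, 0.2, roi_shape = "disc", seed = 6))
  for (spec in specs) {
    gen <- generate_image(spec)
    cl <- classify_pixels(gen$image, gen$mask)
    expect_identical(cl$counts, gen$counts)
    expect_identical(cl$labels, gen$labels)
  }
})

test_that("ground-truth label maps agree with planted counts", {
  gen <- generate_image(synthetic_image_spec(32, 32, 0.2, 0.3, 0.1,
                                             roi_shape = "disc", seed = 12))
  tab <- tabulate(gen$labels + 1L, nbins = 5)
  expect_equal(tab[3], gen$counts$n_weak)
  expect_equal(tab[4], gen$counts$n_medium)
  expect_equal(tab[5], gen$counts$n_strong)
  expect_equal(tab[2], gen$counts$n_negative)
  expect_equal(sum(gen$mask), gen$counts$n_total)
})

test_that("invalid image specs are rejected", {
  expect_error(synthetic_image_spec(frac_weak = 0.6, frac_medium = 0.6),
               "sum to more than 1")
  expect_error(synthetic_image_spec(noise_sd = -1), "noise_sd")
  expect_error(generate_image(synthetic_image_spec(16, 16, 0.1, seed = 1,
                                                   noise_sd = 40)),
               "noise_sd too large")
})

test_that("cohorts are reproducible and honor their targets", {
  spec <- synthetic_cohort_spec(
    n_per_group = 3, mean_hscore_a = 1.0, mean_hscore_b = 0.4,
    between_sample_sd = 0.2,
    image_spec = synthetic_image_spec(32, 32), seed = 77)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$samples[[2]]$image, c2$samples[[2]]$image)
  expect_equal(c1$manifest$group, rep(c("N0", "N1"), each = 3))
  expect_true(all(c1$truth$target_hscore >= 0 & c1$truth$target_hscore <= 3))
  # realized ground truth tracks per-sample targets up to pixel quantization
  expect_lte(max(abs(c1$truth$hscore - c1$truth$target_hscore)), 3 / 1024)

  # zero between-sample spread pins every sample at the group mean
  c0 <- generate_cohort(synthetic_cohort_spec(
    n_per_group = 2, mean_hscore_a = 1.05, mean_hscore_b = 0.11,
    between_sample_sd = 0,
    image_spec = synthetic_image_spec(64, 64), seed = 5))
  expect_equal(c0$truth$target_hscore, rep(c(1.05, 0.11), each = 2))
  expect_lte(max(abs(c0$truth$hscore - c0$truth$target_hscore)), 0.5 / 4096)
})

test_that("cohort spec validation", {
  expect_error(synthetic_cohort_spec(n_per_group = 1), "n_per_group")
  expect_error(synthetic_cohort_spec(mean_hscore_a = 3.5), "\\[0, 3\\]")
})
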