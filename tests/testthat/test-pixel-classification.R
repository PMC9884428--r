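codes <- ihc_label_codes()

test_that("hematoxylin-blue image is entirely negative", {
  img <- array(0, c(10, 12, 3))
  img[, , 3] <- 200  # saturated blue, hue far from the DAB window
  cl <- classify_pixels(img)
  expect_equal(cl$counts$n_weak, 0L)
  expect_equal(cl$counts$n_medium, 0L)
  expect_equal(cl$counts$n_strong, 0L)
  expect_equal(cl$counts$n_negative, 120L)
  expect_equal(cl$counts$n_total, 120L)
  expect_true(all(cl$labels == codes[["negative"]]))
})

test_that("intensity bins are half-open and closed at the darker edge", {
  # DAB-hued triples constructed so channel means hit the default bin edges
  edge_pixel <- function(r, g, b) {
    classify_pixels(array(c(r, g, b), c(1, 1, 3)))$labels[1, 1]
  }
  expect_equal(edge_pixel(225, 175, 125), codes[["weak"]])     # I = 175
  expect_equal(edge_pixel(224, 174, 124), codes[["medium"]])   # I = 174
  expect_equal(edge_pixel(150, 100, 50), codes[["medium"]])    # I = 100
  expect_equal(edge_pixel(149, 99, 49), codes[["strong"]])     # I = 99
  expect_equal(edge_pixel(255, 225, 180), codes[["negative"]]) # I = 220, faint
  expect_equal(edge_pixel(254, 224, 179), codes[["weak"]])     # I = 219
})

test_that("counts are conserved and independent of excluded pixels", {
  set.seed(23)
  for (rep in 1:10) {
    img <- random_rgb_image(20, 20)
    mask <- matrix(runif(400) < 0.6, 20, 20)
    cl <- classify_pixels(img, mask)
    with(cl$counts, {
      expect_identical(n_total, n_weak + n_medium + n_strong + n_negative)
      expect_identical(n_total, as.integer(sum(mask)))
    })
    expect_true(all((cl$labels == 0L) == !mask))

    # editing excluded pixels never changes the counts
    img2 <- img
    img2[, , 1][!mask] <- 0
    img2[, , 2][!mask] <- 255
    expect_identical(classify_pixels(img2, mask)$counts, cl$counts)
  }
})

test_that("all-excluded mask yields zero counts, mismatch errors", {
  img <- random_rgb_image(8, 8)
  cl <- classify_pixels(img, matrix(FALSE, 8, 8))
  expect_equal(cl$counts$n_total, 0L)
  expect_true(all(cl$labels == codes[["excluded"]]))
  expect_error(classify_pixels(img, matrix(TRUE, 8, 9)),
               "do not match")
})

test_that("darkening stained pixels moves them toward stronger bins", {
  gen <- generate_image(synthetic_image_spec(48, 48, frac_weak = 0.3,
                                             frac_medium = 0.2,
                                             frac_strong = 0.1, seed = 5))
  before <- classify_pixels(gen$image, gen$mask)$counts
  darker <- array(round(gen$image * 0.7), dim(gen$image))
  after <- classify_pixels(darker, gen$mask)$counts
  expect_gte(after$n_strong, before$n_strong)
  expect_gte(after$n_strong + after$n_medium,
             before$n_strong + before$n_medium)
  expect_gte(after$n_strong + after$n_medium + after$n_weak,
             before$n_strong + before$n_medium + before$n_weak)
})

test_that("vectorized classifier agrees with the per-pixel oracle", {
  set.seed(31)
  params_list <- list(
    pixel_class_params(),
    pixel_class_params(hue_center = 0.08, hue_width = 0.3,
                       saturation_threshold = 0.1,
                       iwp_high = 230, iwp_low = 160, ip_low = 90,
                       isp_low = 10))
  for (rep in 1:10) {
    img <- random_rgb_image(16, 16)
    mask <- matrix(runif(256) < 0.8, 16, 16)
    for (p in params_list) {
      expect_identical(classify_pixels(img, mask, p)$labels,
                       brute_force_labels(img, mask, p))
    }
  }
})

test_that("markup rendering uses the exact palette and inverts", {
  labels <- matrix(c(0L, 1L, 2L, 3L, 4L, 4L), 2, 3)
  markup <- render_markup(labels)
  pal <- rbind(c(255, 255, 255), c(0, 0, 255), c(255, 255, 0),
               c(255, 165, 0), c(255, 0, 0))
  for (k in 0:4) {
    sel <- labels == k
    for (ch in 1:3)
      expect_true(all(markup[, , ch][sel] == pal[k + 1, ch]))
  }
  # palette is bijective: recover the label map from the colors
  key <- pal[, 1] * 65536 + pal[, 2] * 256 + pal[, 3]
  enc <- markup[, , 1] * 65536 + markup[, , 2] * 256 + markup[, , 3]
  expect_identical(matrix(match(enc, key) - 1L, 2, 3), labels)

  all_strong <- render_markup(matrix(4L, 3, 3))
  expect_true(all(all_strong[, , 1] == 255) && all(all_strong[, , 2] == 0) &&
                all(all_strong[, , 3] == 0))
  all_neg <- render_markup(matrix(1L, 3, 3))
  expect_true(all(all_neg[, , 3] == 255) && all(all_neg[, , 1] == 0))
})

test_that("threshold parameters are validated", {
  expect_error(pixel_class_params(iwp_low = 90, ip_low = 100),
               "isp_low < ip_low < iwp_low < iwp_high")
  expect_error(pixel_class_params(hue_center = 1.2), "hue_center")
  expect_error(pixel_class_params(saturation_threshold = 2),
               "saturation_threshold")
})
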