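#' Specification of one synthetic IHC image
#'
#' Describes a synthetic DAB/hematoxylin image with planted per-class pixel
#' fractions. Within the region of interest, the requested fractions of
#' pixels are rendered as DAB-brown at intensities drawn strictly inside the
#' weak/medium/strong bins of `params` (margin at least `3 * noise_sd` plus
#' rounding slack from each bin edge), the remainder as hematoxylin-blue
#' negatives whose hue lies far outside the DAB window. Pixels outside the
#' ROI are white background. Gaussian channel noise with standard deviation
#' `noise_sd` is added to ROI pixels, then channels are clamped to
#' `[0, 255]` and rounded.
#'
#' @param width,height Image dimensions in pixels.
#' @param frac_weak,frac_medium,frac_strong Planted class fractions of ROI
#'   pixels, each in `[0, 1]`, summing to at most 1.
#' @param roi_shape `"full"` (all pixels in the ROI) or `"disc"` (a centered
#'   disc of radius `0.45 * min(width, height)` emulating a tissue-microarray
#'   core on white background).
#' @param noise_sd Standard deviation of additive Gaussian channel noise,
#'   on the 0-255 intensity scale.
#' @param seed Integer RNG seed; identical specs give identical images.
#' @return An object of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(width = 64, height = 64,
                                 frac_weak = 0, frac_medium = 0,
                                 frac_strong = 0,
                                 roi_shape = c("full", "disc"),
                                 noise_sd = 0, seed = 1L) {
  roi_shape <- match.arg(roi_shape)
  fr <- c(frac_weak, frac_medium, frac_strong)
  if (any(fr < 0) || any(fr > 1))
    stop("planted fractions must lie in [0, 1]", call. = FALSE)
  if (sum(fr) > 1 + 1e-12)
    stop("planted fractions sum to more than 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (width < 1 || height < 1) stop("empty image", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 frac_weak = frac_weak, frac_medium = frac_medium,
                 frac_strong = frac_strong, roi_shape = roi_shape,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

#' Generate a synthetic IHC image with ground truth
#'
#' @param spec A [synthetic_image_spec()].
#' @param params The classification thresholds the image is planted against
#'   (defaults to [pixel_class_params()]). `hue_center` must lie in the
#'   red-to-yellow sextant `[0, 1/6]`, which covers chromogen browns.
#' @return A list with `image` (RGB array), `mask` (logical ROI matrix),
#'   `labels` (ground-truth label map coded as in [ihc_label_codes()]),
#'   `counts` (planted class counts, same shape as [classify_pixels()]
#'   counts) and `spec`.
#' @export
generate_image <- function(spec, params = pixel_class_params()) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  with_seed(spec$seed, {
    h <- spec$height
    w <- spec$width
    mask <- roi_mask_for(spec$roi_shape, w, h)
    idx <- which(mask)
    n <- length(idx)
    if (n == 0) stop("ROI contains no pixels", call. = FALSE)

    counts <- allocate_class_counts(n, spec$frac_weak, spec$frac_medium,
                                    spec$frac_strong)
    # class codes 1 negative, 2 weak, 3 medium, 4 strong, shuffled over ROI
    lab <- sample(rep.int(
      1:4, c(counts$n_negative, counts$n_weak, counts$n_medium,
             counts$n_strong)))

    labels <- matrix(0L, h, w)
    labels[idx] <- lab

    bins <- list(`2` = c(params$iwp_low, params$iwp_high),
                 `3` = c(params$ip_low, params$iwp_low),
                 `4` = c(params$isp_low, params$ip_low))
    margin <- max(2, 3 * spec$noise_sd)

    red <- matrix(255, h, w); green <- matrix(255, h, w)
    blue <- matrix(255, h, w)

    neg <- idx[lab == 1L]
    if (length(neg)) {
      iv <- stats::runif(length(neg), 80, 115)
      px <- hematoxylin_rgb(iv)
      red[neg] <- px$r; green[neg] <- px$g; blue[neg] <- px$b
    }
    for (code in 2:4) {
      sel <- idx[lab == code]
      if (!length(sel)) next
      rng <- bins[[as.character(code)]]
      lo <- rng[1] + margin
      hi <- rng[2] - margin
      if (lo >= hi)
        stop("noise_sd too large for the ", IHC_LABELS[code + 1],
             " intensity bin", call. = FALSE)
      iv <- stats::runif(length(sel), lo, hi)
      px <- dab_rgb(iv, params$hue_center)
      red[sel] <- px$r; green[sel] <- px$g; blue[sel] <- px$b
    }

    if (spec$noise_sd > 0) {
      red[idx] <- red[idx] + stats::rnorm(n, sd = spec$noise_sd)
      green[idx] <- green[idx] + stats::rnorm(n, sd = spec$noise_sd)
      blue[idx] <- blue[idx] + stats::rnorm(n, sd = spec$noise_sd)
    }

    image <- array(0, c(h, w, 3))
    image[, , 1] <- round(pmin(pmax(red, 0), 255))
    image[, , 2] <- round(pmin(pmax(green, 0), 255))
    image[, , 3] <- round(pmin(pmax(blue, 0), 255))

    list(image = image, mask = mask, labels = labels, counts = counts,
         spec = spec)
  })
}

#' Specification of a synthetic two-group cohort
#'
#' @param n_per_group Samples per group (at least 2).
#' @param mean_hscore_a,mean_hscore_b Target mean H-scores in `[0, 3]` for
#'   groups `"N0"` and `"N1"`.
#' @param between_sample_sd Standard deviation of per-sample target H-scores
#'   around the group mean (draws are truncated to `[0, 3]`).
#' @param image_spec Template [synthetic_image_spec()]; its fractions are
#'   overridden per sample, its seed is replaced by `seed + sample index`.
#' @param seed Integer RNG seed for the cohort.
#' @return An object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_per_group = 8,
                                  mean_hscore_a = 1.05,
                                  mean_hscore_b = 0.11,
                                  between_sample_sd = 0,
                                  image_spec = synthetic_image_spec(
                                    width = 96, height = 96,
                                    roi_shape = "disc"),
                                  seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  for (m in c(mean_hscore_a, mean_hscore_b))
    if (m < 0 || m > 3)
      stop("target mean H-scores must lie in [0, 3]", call. = FALSE)
  if (between_sample_sd < 0)
    stop("between_sample_sd must be >= 0", call. = FALSE)
  stopifnot(inherits(image_spec, "synthetic_image_spec"))
  structure(list(n_per_group = as.integer(n_per_group),
                 mean_hscore_a = mean_hscore_a, mean_hscore_b = mean_hscore_b,
                 between_sample_sd = between_sample_sd,
                 image_spec = image_spec, seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

#' Generate a synthetic cohort of IHC images with group structure
#'
#' Draws one target H-score per sample from
#' `Normal(group mean, between_sample_sd)` truncated to `[0, 3]`, converts it
#' to planted class fractions with [hscore_to_fractions()], and generates one
#' image per sample. Group labels are `"N0"` (group a) and `"N1"` (group b).
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param params Classification thresholds passed to [generate_image()].
#' @return A list with `samples` (list of [generate_image()] results, one per
#'   sample), `manifest` (data frame `sample_id`, `group`) and `truth`
#'   (data frame `sample_id`, `group`, `target_hscore`, `hscore`, where
#'   `hscore` is the realized ground-truth score after pixel quantization).
#' @export
generate_cohort <- function(spec, params = pixel_class_params()) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  n <- spec$n_per_group
  groups <- rep(c("N0", "N1"), each = n)
  means <- rep(c(spec$mean_hscore_a, spec$mean_hscore_b), each = n)
  ids <- sprintf("%s_s%02d", groups, c(seq_len(n), seq_len(n)))

  targets <- with_seed(spec$seed, {
    pmin(pmax(stats::rnorm(2 * n, mean = means,
                           sd = spec$between_sample_sd), 0), 3)
  })

  samples <- vector("list", 2 * n)
  realized <- numeric(2 * n)
  for (i in seq_len(2 * n)) {
    fr <- hscore_to_fractions(targets[i])
    ispec <- spec$image_spec
    ispec$frac_weak <- fr$frac_weak
    ispec$frac_medium <- fr$frac_medium
    ispec$frac_strong <- fr$frac_strong
    ispec$seed <- spec$seed + i
    gen <- generate_image(ispec, params)
    gen$sample_id <- ids[i]
    samples[[i]] <- gen
    realized[i] <- hscore_from_counts(gen$counts, ids[i])$h_score
  }

  list(samples = samples,
       manifest = data.frame(sample_id = ids, group = groups,
                             stringsAsFactors = FALSE),
       truth = data.frame(sample_id = ids, group = groups,
                          target_hscore = targets, hscore = realized,
                          stringsAsFactors = FALSE))
}

#' Convert a target H-score to planted class fractions
#'
#' The inversion from one H-score to three fractions is underdetermined; the
#' generator fixes the mixture shape: fractions proportional to
#' (weak, medium, strong) = (0.5, 0.3, 0.2), scaled so the weighted sum hits
#' the target. That shape reaches H = 1.7 when the ROI is fully positive;
#' for larger targets the generator falls back to strong-only staining
#' (`frac_strong = H / 3`).
#'
#' @param h Target H-score in `[0, 3]`.
#' @return List with `frac_weak`, `frac_medium`, `frac_strong`.
#' @export
hscore_to_fractions <- function(h) {
  if (!is.finite(h) || h < 0 || h > 3)
    stop("target H-score must lie in [0, 3]", call. = FALSE)
  shape <- c(0.5, 0.3, 0.2)
  hmax <- sum(shape * 1:3)  # 1.7
  if (h <= hmax) {
    fr <- shape * h / hmax
  } else {
    fr <- c(0, 0, h / 3)
  }
  list(frac_weak = fr[1], frac_medium = fr[2], frac_strong = fr[3])
}

#' Allocate whole-pixel class counts for planted fractions
#'
#' Largest-remainder rounding of the four class fractions (negative, weak,
#' medium, strong) to whole pixels, followed by a deterministic one-pixel
#' correction: single pixels are moved between adjacent classes until the
#' realized weighted score `(n_weak + 2 n_medium + 3 n_strong)` equals the
#' nearest integer to `n * H_target`. Realized scores live on a grid of
#' spacing `1/n`, so the realized H-score is always within `0.5/n` of the
#' planted target.
#'
#' @param n Number of ROI pixels.
#' @param frac_weak,frac_medium,frac_strong Planted fractions, sum at most 1.
#' @return Counts list as in [classify_pixels()].
#' @export
allocate_class_counts <- function(n, frac_weak, frac_medium, frac_strong) {
  fr <- c(1 - frac_weak - frac_medium - frac_strong,
          frac_weak, frac_medium, frac_strong)
  if (any(fr < -1e-12)) stop("fractions must sum to at most 1", call. = FALSE)
  fr <- pmax(fr, 0)
  ideal <- n * fr
  counts <- floor(ideal)
  short <- n - sum(counts)
  if (short > 0) {
    up <- order(ideal - counts, decreasing = TRUE)[seq_len(short)]
    counts[up] <- counts[up] + 1
  }

  # move single pixels between adjacent classes (score step +/- 1) until the
  # integer score matches round(n * target H)
  target <- round(n * (frac_weak + 2 * frac_medium + 3 * frac_strong))
  score <- counts[2] + 2 * counts[3] + 3 * counts[4]
  while (score != target) {
    s <- sign(target - score)
    moved <- FALSE
    # donor -> recipient pairs with score change s
    pairs <- if (s > 0) list(c(1, 2), c(2, 3), c(3, 4)) else
      list(c(2, 1), c(3, 2), c(4, 3))
    for (p in pairs) {
      if (counts[p[1]] > 0) {
        counts[p[1]] <- counts[p[1]] - 1
        counts[p[2]] <- counts[p[2]] + 1
        moved <- TRUE
        break
      }
    }
    if (!moved) break  # degenerate (all mass at an extreme); keep allocation
    score <- score + s
  }

  counts <- as.integer(counts)
  list(n_weak = counts[2], n_medium = counts[3], n_strong = counts[4],
       n_negative = counts[1], n_total = as.integer(n))
}

# ---- internal rendering helpers ------------------------------------------

# DAB-brown RGB at given mean intensities; hexagonal hue = hue_center, which
# must lie in the red..yellow sextant [0, 1/6] so red is the maximal channel.
# Saturation shrinks near white so the red channel never clips.
dab_rgb <- function(intensity, hue_center) {
  hp <- 6 * hue_center
  if (hp < 0 || hp > 1)
    stop("generator supports hue_center in [0, 1/6] (chromogen browns)",
         call. = FALSE)
  wsum <- (1 + hp) / 3                       # (C + hp*C)/(3C)
  s <- pmin(0.35, 0.85 * (255 / intensity - 1) * wsum / (1 - wsum))
  b <- intensity * (1 - s)
  chroma <- intensity * s / wsum
  list(r = b + chroma, g = b + hp * chroma, b = b)
}

# hematoxylin-like blue (hue 2/3, saturation 0.5) at given mean intensities
hematoxylin_rgb <- function(intensity) {
  mn <- intensity * 0.5
  list(r = mn, g = mn, b = 3 * intensity - 2 * mn)
}

roi_mask_for <- function(shape, width, height) {
  if (shape == "full") return(matrix(TRUE, height, width))
  r <- 0.45 * min(width, height)
  cx <- (width + 1) / 2
  cy <- (height + 1) / 2
  x <- matrix(rep(seq_len(width), each = height), height, width)
  y <- matrix(rep(seq_len(height), times = width), height, width)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
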