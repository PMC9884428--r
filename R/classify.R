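#' Thresholds for positive-pixel classification
#'
#' Bundles the hue window, saturation floor and intensity-bin boundaries used
#' to classify DAB-stained pixels. A pixel is positive when its hue falls
#' within `hue_center +/- hue_width/2` (circular distance), its saturation is
#' at least `saturation_threshold`, and its intensity lies in
#' `[isp_low, iwp_high)`. Positive pixels are binned by intensity with
#' half-open bins closed at the darker (lower) edge:
#' strong `[isp_low, ip_low)`, medium `[ip_low, iwp_low)`,
#' weak `[iwp_low, iwp_high)`. Pixels at or above `iwp_high` are too faint to
#' count as stained and are negative regardless of hue.
#'
#' The defaults are the publicly documented defaults of the Aperio-style
#' positive pixel counting algorithm for DAB chromogen: a brown hue window
#' centered at 0.1 (width 0.5), saturation floor 0.04, and intensity cuts
#' 220 / 175 / 100 / 0.
#'
#' @param hue_center Hue of the chromogen, in `[0, 1)`; 0.1 is DAB brown.
#' @param hue_width Full width of the accepted hue window, in `(0, 1]`.
#' @param saturation_threshold Minimum saturation for a stained pixel.
#' @param iwp_high Upper intensity bound of the weak bin (exclusive).
#' @param iwp_low Lower intensity bound of the weak bin.
#' @param ip_low Lower intensity bound of the medium bin.
#' @param isp_low Lower intensity bound of the strong bin.
#' @return An object of class `pixel_class_params`.
#' @export
pixel_class_params <- function(hue_center = 0.1,
                               hue_width = 0.5,
                               saturation_threshold = 0.04,
                               iwp_high = 220,
                               iwp_low = 175,
                               ip_low = 100,
                               isp_low = 0) {
  p <- list(hue_center = hue_center, hue_width = hue_width,
            saturation_threshold = saturation_threshold,
            iwp_high = iwp_high, iwp_low = iwp_low,
            ip_low = ip_low, isp_low = isp_low)
  if (hue_center < 0 || hue_center >= 1)
    stop("hue_center must be in [0, 1)", call. = FALSE)
  if (hue_width <= 0 || hue_width > 1)
    stop("hue_width must be in (0, 1]", call. = FALSE)
  if (saturation_threshold < 0 || saturation_threshold > 1)
    stop("saturation_threshold must be in [0, 1]", call. = FALSE)
  if (!(isp_low < ip_low && ip_low < iwp_low && iwp_low < iwp_high))
    stop("intensity bounds must satisfy isp_low < ip_low < iwp_low < iwp_high",
         call. = FALSE)
  if (isp_low < 0 || iwp_high > 256)
    stop("intensity bounds must lie in [0, 256]", call. = FALSE)
  structure(p, class = "pixel_class_params")
}

# integer codes of the label map; position i holds the name of code i - 1
IHC_LABELS <- c("excluded", "negative", "weak", "medium", "strong")

#' Label codes used in pixel label maps
#'
#' @return Named integer vector mapping class name to the integer code used
#'   in label maps: excluded 0, negative 1, weak 2, medium 3, strong 4.
#' @export
ihc_label_codes <- function() {
  stats::setNames(0:4, IHC_LABELS)
}

#' Classify ROI pixels as negative or weak/medium/strong positive
#'
#' Applies the hue/saturation/intensity rules of [pixel_class_params()] to
#' every pixel inside the region of interest, producing a per-pixel label map
#' and the class counts used for scoring: the number of weak (Nwp), medium
#' (Np), strong (Nsp) and negative pixels, and NTotal, the number of pixels
#' counted (included pixels only).
#'
#' @param image `height x width x 3` array, channels in `[0, 255]`.
#' @param mask Logical `height x width` matrix; `TRUE` marks pixels inside
#'   the region of interest. `NULL` (default) includes every pixel. An
#'   all-`FALSE` mask is allowed and yields all-zero counts.
#' @param params A [pixel_class_params()] object.
#' @return A list with `labels`, an integer matrix coded per
#'   [ihc_label_codes()], and `counts`, a list with elements `n_weak`,
#'   `n_medium`, `n_strong`, `n_negative`, `n_total`.
#' @examples
#' gen <- generate_image(synthetic_image_spec(
#'   width = 32, height = 32, frac_weak = 0.2, frac_medium = 0.3,
#'   frac_strong = 0.1, seed = 1))
#' classify_pixels(gen$image, gen$mask)$counts
#' @export
classify_pixels <- function(image, mask = NULL, params = pixel_class_params()) {
  validate_rgb_image(image)
  if (!inherits(params, "pixel_class_params"))
    stop("params must be created by pixel_class_params()", call. = FALSE)
  h <- dim(image)[1]
  w <- dim(image)[2]
  if (is.null(mask)) {
    mask <- matrix(TRUE, h, w)
  } else {
    if (!is.matrix(mask) || !is.logical(mask))
      stop("mask must be a logical matrix", call. = FALSE)
    if (nrow(mask) != h || ncol(mask) != w)
      stop(sprintf("mask dimensions (%d x %d) do not match image (%d x %d)",
                   nrow(mask), ncol(mask), h, w), call. = FALSE)
  }

  hsi <- rgb_to_hsi(image)
  positive <- hue_distance(hsi$hue, params$hue_center) <= params$hue_width / 2 &
    hsi$saturation >= params$saturation_threshold &
    hsi$intensity >= params$isp_low &
    hsi$intensity < params$iwp_high

  labels <- matrix(1L, h, w)
  labels[positive & hsi$intensity >= params$iwp_low] <- 2L
  labels[positive & hsi$intensity >= params$ip_low &
           hsi$intensity < params$iwp_low] <- 3L
  labels[positive & hsi$intensity < params$ip_low] <- 4L
  labels[!mask] <- 0L

  tab <- tabulate(labels + 1L, nbins = 5L)
  counts <- list(n_weak = tab[3], n_medium = tab[4], n_strong = tab[5],
                 n_negative = tab[2],
                 n_total = tab[2] + tab[3] + tab[4] + tab[5])
  list(labels = labels, counts = counts)
}

# bit-exact markup palette, rows indexed by label code + 1
MARKUP_PALETTE <- matrix(c(
  255, 255, 255,   # excluded -> white
  0,     0, 255,   # negative -> blue
  255, 255,   0,   # weak     -> yellow
  255, 165,   0,   # medium   -> orange
  255,   0,   0),  # strong   -> red
  ncol = 3, byrow = TRUE)

#' Render a classification markup image
#'
#' Recolors a label map with the conventional markup palette: strong red,
#' medium orange, weak yellow, negative blue, excluded white.
#'
#' @param labels Integer label matrix as returned by [classify_pixels()].
#' @return A `height x width x 3` RGB array with values in `[0, 255]`.
#' @export
render_markup <- function(labels) {
  if (!is.matrix(labels) || !all(labels %in% 0:4))
    stop("labels must be an integer matrix with codes 0..4", call. = FALSE)
  out <- array(0, c(nrow(labels), ncol(labels), 3))
  idx <- as.integer(labels) + 1L
  for (ch in 1:3)
    out[, , ch] <- matrix(MARKUP_PALETTE[idx, ch], nrow(labels), ncol(labels))
  out
}
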