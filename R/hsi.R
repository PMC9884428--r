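#' Convert an RGB image to hue/saturation/intensity planes
#'
#' Converts an 8-bit RGB image to the HSI parameterization in which the
#' positive-pixel thresholds are expressed. Intensity is the plain channel
#' mean on the 0-255 scale, saturation is `1 - min(R,G,B)/intensity`
#' (0 for black pixels), and hue is the standard hexagonal hue normalized
#' to `[0, 1)` with 0 at pure red, wrapping circularly. Achromatic pixels
#' (R = G = B) are assigned hue 0.
#'
#' @param image Numeric array of dimension `height x width x 3` with channel
#'   values in `[0, 255]` (see [read_ihc_image()]).
#' @return A list with matrices `hue` (in `[0, 1)`), `saturation`
#'   (in `[0, 1]`) and `intensity` (in `[0, 255]`), each `height x width`.
#' @examples
#' img <- array(0, c(1, 1, 3))
#' img[1, 1, ] <- c(200, 150, 100)
#' rgb_to_hsi(img)
#' @export
rgb_to_hsi <- function(image) {
  validate_rgb_image(image)
  r <- image[, , 1, drop = TRUE]
  g <- image[, , 2, drop = TRUE]
  b <- image[, , 3, drop = TRUE]
  if (is.null(dim(r))) {
    dm <- dim(image)[1:2]
    dim(r) <- dm; dim(g) <- dm; dim(b) <- dm
  }

  intensity <- (r + g + b) / 3
  mn <- pmin(r, g, b)
  mx <- pmax(r, g, b)
  chroma <- mx - mn

  saturation <- matrix(0, nrow(r), ncol(r))
  nz <- intensity > 0
  saturation[nz] <- 1 - mn[nz] / intensity[nz]

  # hexagonal hue; branch order R, G, B resolves ties at equal maxima
  hue6 <- matrix(0, nrow(r), ncol(r))
  chromatic <- chroma > 0
  is_r <- chromatic & (mx == r)
  is_g <- chromatic & !is_r & (mx == g)
  is_b <- chromatic & !is_r & !is_g
  hue6[is_r] <- ((g[is_r] - b[is_r]) / chroma[is_r]) %% 6
  hue6[is_g] <- (b[is_g] - r[is_g]) / chroma[is_g] + 2
  hue6[is_b] <- (r[is_b] - g[is_b]) / chroma[is_b] + 4

  list(hue = hue6 / 6, saturation = saturation, intensity = intensity)
}

#' Circular distance between two hues on the unit circle
#'
#' @param h Numeric vector/matrix of hues in `[0, 1)`.
#' @param center Single hue in `[0, 1)`.
#' @return Distances in `[0, 0.5]`, same shape as `h`.
#' @keywords internal
hue_distance <- function(h, center) {
  d <- abs(h - center)
  pmin(d, 1 - d)
}

validate_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("image must be a height x width x 3 array", call. = FALSE)
  if (dim(image)[1] < 1 || dim(image)[2] < 1)
    stop("image must have at least one pixel", call. = FALSE)
  rng <- range(image)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("channel values must lie in [0, 255] with no missing values",
         call. = FALSE)
  invisible(image)
}
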