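#' Read an IHC image from PNG or TIFF
#'
#' Reads an RGB image into the `height x width x 3` array (values 0-255)
#' used throughout the package. Alpha channels are dropped; grayscale images
#' are replicated across the three channels; 16-bit input is rescaled to
#' 8-bit with a warning.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return RGB array with values in `[0, 255]`.
#' @export
read_ihc_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: '", ext,
                     "' (use PNG or TIFF)", call. = FALSE))
  to_rgb255(raw, path)
}

#' Read a region-of-interest mask
#'
#' Reads a single-channel PNG mask; any nonzero pixel is included in the
#' region of interest. Multi-channel masks use the first channel.
#'
#' @param path Path to the mask PNG.
#' @return Logical matrix, `TRUE` = include.
#' @export
read_roi_mask <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  raw > 0
}

#' Write an RGB array as PNG
#'
#' @param image RGB array with values in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  validate_rgb_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

# normalize readPNG/readTIFF output to a 0-255 RGB array
to_rgb255 <- function(raw, path) {
  if (length(dim(raw)) == 2) {
    raw <- array(rep(raw, 3), c(dim(raw), 3))
  } else if (dim(raw)[3] > 3) {
    raw <- raw[, , 1:3, drop = FALSE]  # drop alpha
  } else if (dim(raw)[3] == 2) {       # gray + alpha
    raw <- array(rep(raw[, , 1], 3), c(dim(raw)[1:2], 3))
  }
  # png/tiff return [0,1] doubles for both 8- and 16-bit input; detect
  # 16-bit by values that do not sit on the 255-step grid
  v255 <- raw * 255
  if (max(abs(v255 - round(v255))) > 1e-6) {
    warning("image '", path,
            "' looks deeper than 8-bit; rescaling to 8-bit", call. = FALSE)
  }
  array(round(v255), dim(raw))
}

#' Write per-sample pixel counts to CSV
#'
#' Columns: `sample_id`, `n_weak`, `n_medium`, `n_strong`, `n_negative`,
#' `n_total`.
#'
#' @param counts_df Data frame with those columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(counts_df, path) {
  utils::write.csv(counts_df, path, row.names = FALSE)
  invisible(path)
}

#' Write per-sample scores to CSV
#'
#' Columns: `sample_id`, `frac_weak`, `frac_medium`, `frac_strong`,
#' `frac_positive`, `h_score`; numeric columns rounded to 4 decimals.
#'
#' @param scores_df Data frame with those columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores_df, path) {
  num <- vapply(scores_df, is.numeric, logical(1))
  scores_df[num] <- lapply(scores_df[num], round, digits = 4)
  utils::write.csv(scores_df, path, row.names = FALSE)
  invisible(path)
}
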