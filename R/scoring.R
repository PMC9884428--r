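#' Per-bin positivity fractions from pixel counts
#'
#' Divides the weak, medium and strong positive-pixel counts by the total
#' number of counted pixels (NTotal). The total positivity is their sum
#' (NPositive / NTotal). All fractions are on the 0-1 scale.
#'
#' @param counts Pixel counts as returned by [classify_pixels()]: a list with
#'   `n_weak`, `n_medium`, `n_strong`, `n_negative`, `n_total`.
#' @param sample_id Optional identifier used in error messages.
#' @return List with `frac_weak`, `frac_medium`, `frac_strong`,
#'   `frac_positive`.
#' @export
compute_fractions <- function(counts, sample_id = NULL) {
  validate_counts(counts)
  if (counts$n_total == 0) {
    id <- if (is.null(sample_id)) "" else paste0(" for sample '", sample_id, "'")
    stop("empty region of interest (n_total = 0)", id,
         ": no score is defined", call. = FALSE)
  }
  fw <- counts$n_weak / counts$n_total
  fm <- counts$n_medium / counts$n_total
  fs <- counts$n_strong / counts$n_total
  list(frac_weak = fw, frac_medium = fm, frac_strong = fs,
       frac_positive = fw + fm + fs)
}

#' Weighted H-score from positivity fractions
#'
#' The H-score weights the positivity fractions by staining intensity:
#' `H = 1 * frac_weak + 2 * frac_medium + 3 * frac_strong`, giving a value
#' on the 0-3 scale (the conventional pathology 0-300 scale is this value
#' times 100).
#'
#' @param fractions Fractions as returned by [compute_fractions()].
#' @param sample_id Optional identifier carried into the result.
#' @return List with `sample_id`, the input fractions, and `h_score`.
#' @examples
#' compute_hscore(list(frac_weak = 0.10, frac_medium = 0.05,
#'                     frac_strong = 0.02))
#' @export
compute_hscore <- function(fractions, sample_id = NULL) {
  for (f in c("frac_weak", "frac_medium", "frac_strong")) {
    v <- fractions[[f]]
    if (is.null(v) || !is.finite(v) || v < 0 || v > 1)
      stop(f, " must be a fraction in [0, 1]", call. = FALSE)
  }
  if (fractions$frac_weak + fractions$frac_medium + fractions$frac_strong >
      1 + 1e-12)
    stop("positivity fractions sum to more than 1", call. = FALSE)
  h <- fractions$frac_weak + 2 * fractions$frac_medium +
    3 * fractions$frac_strong
  list(sample_id = sample_id,
       frac_weak = fractions$frac_weak,
       frac_medium = fractions$frac_medium,
       frac_strong = fractions$frac_strong,
       frac_positive = fractions$frac_weak + fractions$frac_medium +
         fractions$frac_strong,
       h_score = h)
}

#' H-score directly from pixel counts
#'
#' Convenience wrapper: [compute_fractions()] followed by [compute_hscore()].
#'
#' @inheritParams compute_fractions
#' @return As [compute_hscore()].
#' @export
hscore_from_counts <- function(counts, sample_id = NULL) {
  compute_hscore(compute_fractions(counts, sample_id), sample_id)
}

validate_counts <- function(counts) {
  need <- c("n_weak", "n_medium", "n_strong", "n_negative", "n_total")
  if (!all(need %in% names(counts)))
    stop("counts must contain ", paste(need, collapse = ", "), call. = FALSE)
  v <- unlist(counts[need])
  if (any(!is.finite(v)) || any(v < 0))
    stop("counts must be non-negative and finite", call. = FALSE)
  if (counts$n_total !=
      counts$n_weak + counts$n_medium + counts$n_strong + counts$n_negative)
    stop("n_total must equal the sum of the four class counts", call. = FALSE)
  invisible(counts)
}
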