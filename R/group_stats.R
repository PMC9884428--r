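#' Summarize one group's H-scores
#'
#' @param samples Data frame with columns `sample_id`, `group`, `h_score`.
#' @param group Group label to summarize.
#' @return List with `group`, `n`, `mean`, `sem`. The SEM uses the sample
#'   (n - 1) standard deviation divided by `sqrt(n)`; it is `NA` for n = 1.
#' @export
summarize_group <- function(samples, group) {
  x <- group_scores(samples, group)
  if (length(x) < 1)
    stop("group '", group, "' has no samples", call. = FALSE)
  sem <- if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  list(group = group, n = length(x), mean = mean(x), sem = sem)
}

#' Compare H-scores between two groups
#'
#' Computes per-group mean and SEM, a two-sided unpaired two-sample t-test,
#' and the fold-change `mean_a / mean_b`. The classical pooled-variance
#' Student test is the default; set `welch = TRUE` for the Welch
#' unequal-variance form.
#'
#' If both groups have zero within-group variance the t statistic is taken
#' at its limit: 0 (p = 1) when the means coincide, signed infinity (p = 0)
#' when they differ.
#'
#' @param samples Data frame with columns `sample_id`, `group`, `h_score`.
#' @param group_a,group_b The two group labels; `group_a` is the reference
#'   group (numerator of the fold-change).
#' @param welch Use the Welch unequal-variance test instead of the pooled
#'   Student test.
#' @return An object of class `group_comparison`: a list with `group_a`,
#'   `group_b`, `n_a`, `n_b`, `mean_a`, `mean_b`, `sem_a`, `sem_b`,
#'   `t_statistic`, `df`, `p_value`, `fold_change` (NA when `mean_b` is 0)
#'   and `method`.
#' @examples
#' d <- data.frame(sample_id = paste0("s", 1:6),
#'                 group = rep(c("N0", "N1"), each = 3),
#'                 h_score = c(1.1, 1.0, 1.05, 0.12, 0.10, 0.11))
#' compare_groups(d, "N0", "N1")
#' @export
compare_groups <- function(samples, group_a, group_b, welch = FALSE) {
  xa <- group_scores(samples, group_a)
  xb <- group_scores(samples, group_b)
  if (length(xa) < 2 || length(xb) < 2)
    stop("each group needs at least 2 samples (got ",
         length(xa), " and ", length(xb), ")", call. = FALSE)
  if (any(!is.finite(c(xa, xb))))
    stop("H-scores must be finite", call. = FALSE)

  sa <- summarize_group(samples, group_a)
  sb <- summarize_group(samples, group_b)

  if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
    delta <- sa$mean - sb$mean
    tt <- list(statistic = if (delta == 0) 0 else sign(delta) * Inf,
               parameter = length(xa) + length(xb) - 2,
               p.value = if (delta == 0) 1 else 0)
  } else {
    fit <- stats::t.test(xa, xb, var.equal = !welch, alternative = "two.sided")
    tt <- list(statistic = unname(fit$statistic),
               parameter = unname(fit$parameter),
               p.value = fit$p.value)
  }

  fold <- if (sb$mean == 0) NA_real_ else sa$mean / sb$mean
  structure(list(
    group_a = group_a, group_b = group_b,
    n_a = sa$n, n_b = sb$n,
    mean_a = sa$mean, mean_b = sb$mean,
    sem_a = sa$sem, sem_b = sb$sem,
    t_statistic = tt$statistic, df = tt$parameter, p_value = tt$p.value,
    fold_change = fold,
    method = if (welch) "Welch two-sample t-test" else
      "pooled two-sample t-test"
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(format_comparison(x), sep = "\n")
  invisible(x)
}

# human-readable report; means/SEM to 2 decimals, fold-change to 1 decimal,
# p to 4 significant figures
format_comparison <- function(x) {
  fold_txt <- if (is.na(x$fold_change))
    sprintf("undefined (mean of %s is 0)", x$group_b)
  else
    sprintf("%.1f (%s / %s)", x$fold_change, x$group_a, x$group_b)
  c(sprintf("Two-group H-score comparison (%s)", x$method),
    sprintf("  %s: n = %d, mean = %.2f, SEM = %.2f",
            x$group_a, x$n_a, x$mean_a, x$sem_a),
    sprintf("  %s: n = %d, mean = %.2f, SEM = %.2f",
            x$group_b, x$n_b, x$mean_b, x$sem_b),
    sprintf("  t = %.4g, df = %.4g, p = %.4g",
            x$t_statistic, x$df, x$p_value),
    paste0("  fold-change: ", fold_txt))
}

group_scores <- function(samples, group) {
  if (!is.data.frame(samples) ||
      !all(c("group", "h_score") %in% names(samples)))
    stop("samples must be a data frame with columns group and h_score",
         call. = FALSE)
  samples$h_score[samples$group == group]
}
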