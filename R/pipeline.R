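#' Quantify a set of IHC images
#'
#' Runs classification and scoring over a set of images: each image is read,
#' classified against `params` within its ROI mask (if given), counted and
#' scored. Unreadable or empty-ROI samples are recorded as error rows and
#' the run continues.
#'
#' When `out_dir` is given, writes `counts.csv`, `scores.csv`, one markup
#' PNG per sample under `markup/`, a `run_log.txt` recording the resolved
#' parameters and per-sample NTotal, and `params.csv` echoing the
#' classification thresholds.
#'
#' @param image_paths Character vector of PNG/TIFF paths.
#' @param mask_paths Optional character vector of mask PNG paths, parallel
#'   to `image_paths` (`NA` entries mean no mask). `NULL` = no masks.
#' @param params [pixel_class_params()] to classify with.
#' @param out_dir Output directory, created if needed; `NULL` = no files.
#' @param sample_ids Identifiers; defaults to file names without extension.
#' @return List with data frames `counts`, `scores` and `errors`
#'   (`sample_id`, `error`).
#' @export
run_quantify <- function(image_paths, mask_paths = NULL,
                         params = pixel_class_params(),
                         out_dir = NULL, sample_ids = NULL) {
  if (is.null(sample_ids))
    sample_ids <- tools::file_path_sans_ext(basename(image_paths))
  if (!is.null(mask_paths) && length(mask_paths) != length(image_paths))
    stop("mask_paths must parallel image_paths", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)

  log_lines <- c(format_params(params))
  counts_rows <- list(); scores_rows <- list(); error_rows <- list()
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "markup"), recursive = TRUE,
               showWarnings = FALSE)
  }

  for (i in seq_along(image_paths)) {
    id <- sample_ids[i]
    res <- tryCatch({
      image <- read_ihc_image(image_paths[i])
      mask <- NULL
      if (!is.null(mask_paths) && !is.na(mask_paths[i]))
        mask <- read_roi_mask(mask_paths[i])
      cl <- classify_pixels(image, mask, params)
      score <- hscore_from_counts(cl$counts, id)
      list(cl = cl, score = score)
    }, error = function(e) e)

    if (inherits(res, "error")) {
      msg <- conditionMessage(res)
      error_rows[[id]] <- data.frame(sample_id = id, error = msg,
                                     stringsAsFactors = FALSE)
      log_lines <- c(log_lines, sprintf("sample %s: ERROR %s", id, msg))
      warning("sample '", id, "': ", msg, call. = FALSE)
      next
    }
    counts_rows[[id]] <- data.frame(sample_id = id,
                                    res$cl$counts[c("n_weak", "n_medium",
                                                    "n_strong", "n_negative",
                                                    "n_total")],
                                    stringsAsFactors = FALSE)
    scores_rows[[id]] <- data.frame(sample_id = id,
                                    res$score[c("frac_weak", "frac_medium",
                                                "frac_strong",
                                                "frac_positive", "h_score")],
                                    stringsAsFactors = FALSE)
    log_lines <- c(log_lines,
                   sprintf("sample %s: n_total = %d, h_score = %.6f",
                           id, res$cl$counts$n_total, res$score$h_score))
    if (!is.null(out_dir))
      write_image_png(render_markup(res$cl$labels),
                      file.path(out_dir, "markup", paste0(id, "_markup.png")))
  }

  out <- list(counts = bind_rows_df(counts_rows,
                c("sample_id", "n_weak", "n_medium", "n_strong",
                  "n_negative", "n_total")),
              scores = bind_rows_df(scores_rows,
                c("sample_id", "frac_weak", "frac_medium", "frac_strong",
                  "frac_positive", "h_score")),
              errors = bind_rows_df(error_rows, c("sample_id", "error")))

  if (!is.null(out_dir)) {
    write_counts_csv(out$counts, file.path(out_dir, "counts.csv"))
    write_scores_csv(out$scores, file.path(out_dir, "scores.csv"))
    utils::write.csv(params_as_df(params), file.path(out_dir, "params.csv"),
                     row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  out
}

#' Compare scored samples between two groups
#'
#' Joins per-sample H-scores with a group manifest and runs
#' [compare_groups()]. Every scored sample must appear in the manifest;
#' unmatched ids are a hard error.
#'
#' When `out_dir` is given, writes `comparison.csv`, a human-readable
#' `comparison.txt`, and `comparison_plot.png` (group means with SEM error
#' bars).
#'
#' @param scores Data frame with `sample_id` and `h_score`, or path to a
#'   scores CSV written by [run_quantify()].
#' @param manifest Data frame with `sample_id` and `group`, or path to a
#'   manifest CSV.
#' @param group_a,group_b Group labels; `group_a` is the fold-change
#'   reference (numerator).
#' @param welch Use the Welch test instead of the pooled Student test.
#' @param out_dir Output directory, or `NULL` for no files.
#' @return A `group_comparison` object (see [compare_groups()]).
#' @export
run_compare <- function(scores, manifest, group_a = "N0", group_b = "N1",
                        welch = FALSE, out_dir = NULL) {
  if (is.character(scores))
    scores <- utils::read.csv(scores, stringsAsFactors = FALSE)
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "h_score") %in% names(scores)))
    stop("scores must have columns sample_id and h_score", call. = FALSE)
  if (!all(c("sample_id", "group") %in% names(manifest)))
    stop("manifest must have columns sample_id and group", call. = FALSE)

  missing_ids <- setdiff(scores$sample_id, manifest$sample_id)
  if (length(missing_ids))
    stop("samples missing from manifest: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  merged <- merge(scores, manifest, by = "sample_id")

  present <- unique(merged$group)
  if (!all(c(group_a, group_b) %in% present))
    stop("groups not found in manifest: ",
         paste(setdiff(c(group_a, group_b), present), collapse = ", "),
         call. = FALSE)

  cmp <- compare_groups(merged, group_a, group_b, welch = welch)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(comparison_as_df(cmp),
                     file.path(out_dir, "comparison.csv"), row.names = FALSE)
    writeLines(format_comparison(cmp), file.path(out_dir, "comparison.txt"))
    save_comparison_plot(cmp, file.path(out_dir, "comparison_plot.png"))
  }
  cmp
}

#' Write a synthetic cohort to disk
#'
#' Materializes a [generate_cohort()] result as files: `images/<id>.png`,
#' `masks/<id>_mask.png`, `manifest.csv` and ground-truth `truth.csv`.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param out_dir Output directory, created if needed.
#' @param params Classification thresholds the images are planted against.
#' @return Invisibly, a list with `image_paths`, `mask_paths`, the
#'   `manifest` and the `truth` data frames.
#' @export
simulate_cohort <- function(spec, out_dir, params = pixel_class_params()) {
  cohort <- generate_cohort(spec, params)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  ids <- cohort$manifest$sample_id
  image_paths <- file.path(out_dir, "images", paste0(ids, ".png"))
  mask_paths <- file.path(out_dir, "masks", paste0(ids, "_mask.png"))
  for (i in seq_along(ids)) {
    write_image_png(cohort$samples[[i]]$image, image_paths[i])
    png::writePNG(cohort$samples[[i]]$mask * 1, mask_paths[i])
  }
  utils::write.csv(cohort$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  invisible(list(image_paths = image_paths, mask_paths = mask_paths,
                 manifest = cohort$manifest, truth = cohort$truth))
}

#' Run the built-in demonstration cohort end to end
#'
#' Generates a deterministic two-group cohort (8 samples per group, target
#' mean H-scores 1.05 for N0 and 0.11 for N1, no between-sample variation,
#' 96 x 96 disc ROIs, noise-free), quantifies every image and compares the
#' groups. The N0/N1 fold-change of the targets is 1.05 / 0.11 = 9.5 at one
#' decimal.
#'
#' @param out_dir Optional output directory for quantification and
#'   comparison artifacts.
#' @param seed Integer seed controlling image generation.
#' @return List with `comparison` (a `group_comparison`), `scores`,
#'   `truth` and `manifest`.
#' @export
run_demo <- function(out_dir = NULL, seed = 1L) {
  spec <- synthetic_cohort_spec(
    n_per_group = 8, mean_hscore_a = 1.05, mean_hscore_b = 0.11,
    between_sample_sd = 0,
    image_spec = synthetic_image_spec(width = 96, height = 96,
                                      roi_shape = "disc", noise_sd = 0),
    seed = seed)
  params <- pixel_class_params()
  cohort <- generate_cohort(spec, params)

  scores_rows <- lapply(cohort$samples, function(s) {
    cl <- classify_pixels(s$image, s$mask, params)
    sc <- hscore_from_counts(cl$counts, s$sample_id)
    data.frame(sample_id = s$sample_id,
               sc[c("frac_weak", "frac_medium", "frac_strong",
                    "frac_positive", "h_score")],
               stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, scores_rows)
  rownames(scores) <- NULL

  cmp <- run_compare(scores, cohort$manifest, "N0", "N1", out_dir = out_dir)
  if (!is.null(out_dir)) {
    write_scores_csv(scores, file.path(out_dir, "scores.csv"))
    utils::write.csv(cohort$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  list(comparison = cmp, scores = scores, truth = cohort$truth,
       manifest = cohort$manifest)
}

#' Bar plot of group mean H-scores with SEM error bars
#'
#' @param cmp A `group_comparison` object.
#' @return A ggplot object.
#' @export
plot_group_comparison <- function(cmp) {
  df <- data.frame(group = factor(c(cmp$group_a, cmp$group_b),
                                  levels = c(cmp$group_a, cmp$group_b)),
                   mean = c(cmp$mean_a, cmp$mean_b),
                   sem = c(cmp$sem_a, cmp$sem_b))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey35", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.15) +
    ggplot2::labs(x = NULL, y = "Mean H-score (0-3)") +
    ggplot2::theme_classic()
}

save_comparison_plot <- function(cmp, path) {
  p <- plot_group_comparison(cmp)
  grDevices::png(path, width = 800, height = 600, res = 150)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}

# ---- small helpers --------------------------------------------------------

bind_rows_df <- function(rows, col_names) {
  if (length(rows) == 0) {
    df <- as.data.frame(stats::setNames(
      replicate(length(col_names), character(0), simplify = FALSE),
      col_names), stringsAsFactors = FALSE)
    return(df)
  }
  df <- do.call(rbind, unname(rows))
  rownames(df) <- NULL
  df
}

params_as_df <- function(params) {
  data.frame(parameter = names(unclass(params)),
             value = unlist(unclass(params), use.names = FALSE),
             stringsAsFactors = FALSE)
}

format_params <- function(params) {
  c("classification parameters:",
    sprintf("  %s = %g", names(unclass(params)),
            unlist(unclass(params), use.names = FALSE)))
}

comparison_as_df <- function(cmp) {
  data.frame(group_a = cmp$group_a, group_b = cmp$group_b,
             n_a = cmp$n_a, n_b = cmp$n_b,
             mean_a = cmp$mean_a, mean_b = cmp$mean_b,
             sem_a = cmp$sem_a, sem_b = cmp$sem_b,
             t_statistic = cmp$t_statistic, df = cmp$df,
             p_value = cmp$p_value, fold_change = cmp$fold_change,
             method = cmp$method, stringsAsFactors = FALSE)
}
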