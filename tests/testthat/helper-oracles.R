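# Independent oracles used across tests: scalar per-pixel classification and
# the textbook pooled two-sample t formulas. Deliberately written without the
# package's vectorized code paths.

brute_force_labels <- function(image, mask, params) {
  h <- dim(image)[1]
  w <- dim(image)[2]
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (!mask[i, j]) next
      r <- image[i, j, 1]; g <- image[i, j, 2]; b <- image[i, j, 3]
      I <- (r + g + b) / 3
      mn <- min(r, g, b); mx <- max(r, g, b); C <- mx - mn
      s <- if (I > 0) 1 - mn / I else 0
      hue <- if (C == 0) 0
      else if (mx == r) (((g - b) / C) %% 6) / 6
      else if (mx == g) ((b - r) / C + 2) / 6
      else ((r - g) / C + 4) / 6
      d <- abs(hue - params$hue_center)
      d <- min(d, 1 - d)
      pos <- d <= params$hue_width / 2 &&
        s >= params$saturation_threshold &&
        I >= params$isp_low && I < params$iwp_high
      out[i, j] <- if (!pos) 1L
      else if (I >= params$iwp_low) 2L
      else if (I >= params$ip_low) 3L
      else 4L
    }
  }
  out
}

pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

random_rgb_image <- function(h, w) {
  array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
}

samples_df <- function(a, b, group_a = "A", group_b = "B") {
  data.frame(
    sample_id = paste0("s", seq_len(length(a) + length(b))),
    group = rep(c(group_a, group_b), c(length(a), length(b))),
    h_score = c(a, b), stringsAsFactors = FALSE)
}
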