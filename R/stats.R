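# Model-comparison statistics: normality screen, paired t-test from the
# closed form, and the all-pairs comparison over per-image scores. The paired
# t statistic itself is computed from first principles (mean difference over
# its standard error); only the t distribution function comes from stats.

#' Shapiro-Wilk normality screen
#'
#' @param samples Numeric vector, `3 <= n <= 5000`.
#' @return The Shapiro-Wilk p-value.
#' @export
test_normality <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 3) stop("normality test requires at least 3 samples")
  if (stats::sd(samples) == 0) {
    stop("degenerate sample: zero variance, normality test undefined")
  }
  stats::shapiro.test(samples)$p.value
}

#' Paired t-test
#'
#' Two-sided paired t-test on the differences `d = a - b`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with the sample standard deviation,
#' `df = n - 1`, and the p-value from the t distribution.
#'
#' @param a,b Paired numeric vectors of equal length `n >= 2`.
#' @return List with `t_statistic`, `p_value` and `df`.
#' @export
paired_t_test <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stop("paired samples must have equal length")
  n <- length(a)
  if (n < 2) stop("paired t-test requires n >= 2")
  d <- a - b
  sdd <- stats::sd(d)
  if (sdd == 0) {
    stop("degenerate case: paired differences have zero variance")
  }
  t <- mean(d) / (sdd / sqrt(n))
  list(t_statistic = t, p_value = 2 * stats::pt(-abs(t), df = n - 1), df = n - 1L)
}

#' Pairwise model comparison over per-image scores
#'
#' For every pair of model variants and each metric (Dice, IoU), screens the
#' paired differences for normality (Shapiro-Wilk) and applies the paired
#' t-test at significance level `alpha` (default 0.01, i.e. 99%). All
#' variants must be scored on the identical image set. No multiple-comparison
#' correction is applied across the pairwise grid.
#'
#' @param per_image_scores Data frame with columns `image_id`, `variant`,
#'   `dice`, `iou`.
#' @param alpha Significance level (default 0.01).
#' @return Data frame of class `model_comparison`: one row per (pair, metric)
#'   with `n`, `normality_p`, `t_statistic`, `p_value`, `significant`.
#' @export
compare_models <- function(per_image_scores, alpha = 0.01) {
  need <- c("image_id", "variant", "dice", "iou")
  if (!all(need %in% names(per_image_scores))) {
    stop("scores must have columns image_id, variant, dice, iou")
  }
  variants <- unique(per_image_scores$variant)
  if (length(variants) < 2) stop("need at least two variants to compare")
  ids <- sort(unique(per_image_scores$image_id))
  for (v in variants) {
    have <- per_image_scores$image_id[per_image_scores$variant == v]
    miss <- setdiff(ids, have)
    if (length(miss) > 0) {
      stop(sprintf("variant '%s' is missing scores for: %s", v,
                   paste(utils::head(miss, 5), collapse = ", ")))
    }
  }
  pairs <- utils::combn(variants, 2, simplify = FALSE)
  rows <- list()
  for (pr in pairs) {
    sa <- per_image_scores[per_image_scores$variant == pr[1], ]
    sb <- per_image_scores[per_image_scores$variant == pr[2], ]
    sa <- sa[match(ids, sa$image_id), ]
    sb <- sb[match(ids, sb$image_id), ]
    for (metric in c("dice", "iou")) {
      a <- sa[[metric]]
      b <- sb[[metric]]
      tt <- paired_t_test(a, b)
      d <- a - b
      np <- if (length(d) >= 3 && length(d) <= 5000) test_normality(d) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, model_a = pr[1], model_b = pr[2], n = length(a),
        normality_p = np, t_statistic = tt$t_statistic, p_value = tt$p_value,
        significant = tt$p_value < alpha, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "summary") <- .score_summary(per_image_scores)
  class(out) <- c("model_comparison", "data.frame")
  out
}

.score_summary <- function(scores) {
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  do.call(rbind, lapply(split(scores, scores$variant), function(s) {
    data.frame(variant = s$variant[1],
               mean_dice = mean(s$dice), sd_dice = pop_sd(s$dice),
               mean_iou = mean(s$iou), sd_iou = pop_sd(s$iou))
  }))
}

#' @export
print.model_comparison <- function(x, ...) {
  alpha <- attr(x, "alpha")
  s <- attr(x, "summary")
  cat("Per-variant scores (mean +/- sd over images):\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-22s Dice %6.2f%% +/- %5.2f   IoU %6.2f%% +/- %5.2f\n",
                s$variant[i], 100 * s$mean_dice[i], 100 * s$sd_dice[i],
                100 * s$mean_iou[i], 100 * s$sd_iou[i]))
  }
  cat(sprintf("\nPaired t-tests (alpha = %g, ** = significant):\n", alpha))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-4s %-20s vs %-20s t=%8.3f  p=%.3g %s\n",
                x$metric[i], x$model_a[i], x$model_b[i], x$t_statistic[i],
                x$p_value[i], if (x$significant[i]) "**" else ""))
  }
  cat("\nNo multiple-comparison correction applied across the pairwise grid.\n")
  invisible(x)
}
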