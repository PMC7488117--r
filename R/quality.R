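# Comparing genotyping-quality metric distributions between groups and
# scoring BeadChip calls by proximity to genotype-cluster borders.

#' Welch comparison of a quality metric between two groups
#'
#' Welch's unequal-variance t-test (Welch-Satterthwaite degrees of freedom,
#' two-sided p) on the finite values of two groups, e.g. the GC scores of
#' concordant vs discordant calls. A group with fewer than two finite values
#' (or two groups both without variance) yields an undefined comparison, not
#' an error.
#'
#' @param values_a,values_b Numeric vectors.
#' @param metric_name,group_by Optional labels carried into the output row.
#' @param alpha Significance threshold (default 0.05).
#' @return A one-row tibble: `metric_name, group_by, n_a, n_b, mean_a,
#'   mean_b, t_stat, df, p_value, significant`. Undefined comparisons have
#'   `NA` statistics.
#' @export
compare_metric_distributions <- function(values_a, values_b,
                                         metric_name = NA_character_,
                                         group_by = NA_character_,
                                         alpha = 0.05) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  row <- tibble::tibble(
    metric_name = metric_name, group_by = group_by,
    n_a = length(a), n_b = length(b),
    mean_a = if (length(a)) mean(a) else NA_real_,
    mean_b = if (length(b)) mean(b) else NA_real_,
    t_stat = NA_real_, df = NA_real_, p_value = NA_real_,
    significant = NA
  )
  if (length(a) < 2 || length(b) < 2) {
    return(row)
  }
  tt <- tryCatch(t.test(a, b, var.equal = FALSE),
                 error = function(e) NULL)  # both groups constant
  if (is.null(tt)) {
    return(row)
  }
  row$t_stat <- unname(tt$statistic)
  row$df <- unname(tt$parameter)
  row$p_value <- tt$p.value
  row$significant <- tt$p.value < alpha
  row
}

#' Welch comparisons of several metrics under one grouping
#'
#' Convenience wrapper running [compare_metric_distributions()] for each
#' metric column of a data frame, split by a two-level grouping column
#' (e.g. concordance status, variant class or zygosity). Multiple testing is
#' not corrected by default, matching a per-metric exploratory reading; set
#' `bonferroni = TRUE` to adjust the p-values (and the significance flags)
#' across the table.
#'
#' @param data A data frame (e.g. paired calls joined with platform metrics).
#' @param metric_cols Character vector of numeric column names to compare.
#' @param group_col Name of the grouping column; its first two distinct
#'   values define groups A and B.
#' @param alpha Significance threshold.
#' @param bonferroni Apply Bonferroni correction across the table?
#' @return A tibble with one row per metric.
#' @export
quality_comparison_table <- function(data, metric_cols, group_col,
                                     alpha = 0.05, bonferroni = FALSE) {
  g <- data[[group_col]]
  lev <- unique(g[!is.na(g)])
  if (length(lev) < 2) {
    stop("grouping column '", group_col, "' has fewer than two levels",
         call. = FALSE)
  }
  lev <- lev[1:2]
  rows <- lapply(metric_cols, function(mc) {
    compare_metric_distributions(
      data[[mc]][g == lev[1]], data[[mc]][g == lev[2]],
      metric_name = mc,
      group_by = paste(group_col, ":", lev[1], "vs", lev[2]),
      alpha = alpha
    )
  })
  out <- dplyr::bind_rows(rows)
  if (bonferroni) {
    out$p_value <- p.adjust(out$p_value, method = "bonferroni")
    out$significant <- ifelse(is.na(out$p_value), NA, out$p_value < alpha)
  }
  out
}

# Canonical Theta cluster center of a genotype class: 0 at hom-ref, 0.5 at
# a het carrying the reference allele, 1 at genotypes without the reference
# allele (in the two-channel array space all non-ref alleles load the B
# channel).
theta_center <- function(class) {
  centers <- c(AA = 0, AB = 0.5, BB = 1, AC = 0.5, BC = 1, CC = 1)
  unname(centers[class])
}

#' Score BeadChip calls by distance from their genotype-cluster center
#'
#' Distance of each call's Theta from the canonical center of its called
#' class (0 / 0.5 / 1 for hom-ref / ref-het / non-ref genotypes). Calls whose
#' distance exceeds a quantile of the *concordant* group's distances are
#' flagged as near a cluster border -- the regime where genotype assignment by
#' clustering becomes unreliable. True GenomeStudio cluster centers are
#' per-marker and unavailable downstream; the canonical centers are an
#' idealization.
#'
#' @param data A data frame with columns `theta`, `class` (genotype class of
#'   the BeadChip call) and logical `concordant`.
#' @param border_quantile Quantile of the concordant group's distances used
#'   as the near-border threshold (default 0.9).
#' @return `data` with added columns `theta_distance` and `near_border`;
#'   the threshold is attached as attribute `"border_threshold"`.
#' @export
score_cluster_border <- function(data, border_quantile = 0.9) {
  dist <- abs(data$theta - theta_center(data$class))
  thr <- if (any(data$concordant)) {
    unname(quantile(dist[data$concordant], border_quantile, na.rm = TRUE))
  } else {
    NA_real_
  }
  out <- data
  out$theta_distance <- dist
  out$near_border <- dist > thr
  attr(out, "border_threshold") <- thr
  out
}
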