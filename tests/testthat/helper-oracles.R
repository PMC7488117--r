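# Independent oracles, deliberately written as literal transcriptions of the
# defining procedures (explicit loops, no shared code with the package).

# Metric computation oracle: per-class reduction with explicit double loops,
# weighted precision/sensitivity, unweighted mean accuracy/specificity over
# classes with a nonzero row or column sum.
oracle_metrics <- function(m) {
  classes <- rownames(m)
  n <- sum(m)
  prec_sum <- 0
  sens_sum <- 0
  accs <- c()
  specs <- c()
  trace <- 0
  for (k in classes) {
    tp <- 0; fn <- 0; fp <- 0; tn <- 0
    for (i in classes) {
      for (j in classes) {
        if (i == k && j == k) tp <- tp + m[i, j]
        else if (i == k) fn <- fn + m[i, j]
        else if (j == k) fp <- fp + m[i, j]
        else tn <- tn + m[i, j]
      }
    }
    trace <- trace + tp
    if (tp + fp > 0) prec_sum <- prec_sum + (tp / (tp + fp)) * (tp + fp) / n
    if (tp + fn > 0) sens_sum <- sens_sum + (tp / (tp + fn)) * (tp + fn) / n
    present <- sum(m[k, ]) > 0 || sum(m[, k]) > 0
    if (present) {
      accs <- c(accs, (tp + tn) / n)
      if (tn + fp > 0) specs <- c(specs, tn / (tn + fp))
    }
  }
  aa <- m["AA", "AA"]
  list(
    genotype_concordance = trace / n,
    nonref_genotype_concordance =
      if (n - aa > 0) (trace - aa) / (n - aa) else NA_real_,
    nonref_sensitivity =
      if (n - sum(m["AA", ]) > 0) (trace - aa) / (n - sum(m["AA", ])) else NA_real_,
    sensitivity = sens_sum,
    precision = prec_sum,
    specificity = if (length(specs)) mean(specs) else NA_real_,
    accuracy = if (length(accs)) mean(accs) else NA_real_
  )
}

# Random 6x6 matrix with cell values in {0,1,2} on a random 3-class block.
random_confusion_matrix <- function() {
  m <- matrix(0L, 6, 6, dimnames = list(truth = GENOTYPE_CLASSES,
                                        test = GENOTYPE_CLASSES))
  active <- sample(GENOTYPE_CLASSES, 3)
  m[active, active] <- sample(0:2, 9, replace = TRUE)
  class(m) <- c("confusion_matrix", class(m))
  m
}

# Exhaustive best bounded window: the maximum number of positions coverable
# by any single window of the given span (windows anchored at each position).
brute_force_best_window <- function(positions, max_span) {
  best <- 0L
  for (p in positions) {
    cnt <- sum(positions >= p & positions <= p + max_span)
    if (cnt > best) best <- cnt
  }
  best
}

# Welch t statistic and two-sided p, coded directly from the textbook
# formulas (statistic, Welch-Satterthwaite df).
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}
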