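# The 6x6 genotype-class confusion matrix, its per-class dimensionality
# reduction, and the seven concordance quality metrics.

#' Build a genotype-class confusion matrix
#'
#' Counts (truth class, test class) co-occurrences over the six diploid
#' genotype classes. `MISSING` labels are rejected: harmonization removes
#' sites not genotyped on both platforms before any matrix is built.
#'
#' @param class_truth,class_test Character vectors over [GENOTYPE_CLASSES].
#' @return A `confusion_matrix`: a 6x6 integer matrix with `dimnames`
#'   `(truth, test)`; `sum()` of its cells is the number of paired calls.
#' @examples
#' confusion_matrix(c("AA", "AA", "AB"), c("AA", "AB", "AB"))
#' @export
confusion_matrix <- function(class_truth, class_test) {
  if (length(class_truth) != length(class_test)) {
    stop("class vectors differ in length", call. = FALSE)
  }
  bad <- setdiff(unique(c(class_truth, class_test)), GENOTYPE_CLASSES)
  if (length(bad)) {
    stop("class label(s) outside the six-class universe: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- table(factor(class_truth, levels = GENOTYPE_CLASSES),
             factor(class_test, levels = GENOTYPE_CLASSES))
  m <- matrix(as.integer(m), 6, 6,
              dimnames = list(truth = GENOTYPE_CLASSES,
                              test = GENOTYPE_CLASSES))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' @rdname confusion_matrix
#' @param paired A paired-call tibble from [harmonize_pair()] (columns
#'   `class_truth`, `class_test`).
#' @export
build_confusion_matrix <- function(paired) {
  confusion_matrix(paired$class_truth, paired$class_test)
}

#' @method print confusion_matrix
#' @export
print.confusion_matrix <- function(x, ...) {
  cat("6x6 genotype-class confusion matrix (truth rows, test columns),",
      "n =", sum(x), "\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Transpose of a confusion matrix (swap truth and test roles)
#' @param x A `confusion_matrix`.
#' @export
t.confusion_matrix <- function(x) {
  m <- t(unclass(x))
  dimnames(m) <- list(truth = colnames(x), test = rownames(x))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Reduce a confusion matrix to one focal class
#'
#' The per-class dimensionality reduction: the focal class is kept intact in
#' both call sets and all other classes are pooled, yielding the 2x2 counts
#' `tp` (truth focal, test focal), `fn` (truth focal, test other), `fp`
#' (truth other, test focal) and `tn` (both other).
#'
#' @param cm A `confusion_matrix`.
#' @param focal One of the six class labels.
#' @return A list with `focal_class, tp, fn, fp, tn`; the four counts always
#'   sum to the parent total.
#' @export
reduce_by_class <- function(cm, focal) {
  focal <- match.arg(focal, GENOTYPE_CLASSES)
  tp <- cm[focal, focal]
  fn <- sum(cm[focal, ]) - tp
  fp <- sum(cm[, focal]) - tp
  tn <- sum(cm) - tp - fn - fp
  list(focal_class = focal, tp = as.integer(tp), fn = as.integer(fn),
       fp = as.integer(fp), tn = as.integer(tn))
}

#' Concordance quality metrics of a confusion matrix
#'
#' Computes the seven quality metrics of a truth/test genotype comparison.
#' Per focal class \eqn{k} (after [reduce_by_class()]):
#' \eqn{precision_k = tp/(tp+fp)}, \eqn{sensitivity_k = tp/(tp+fn)},
#' \eqn{specificity_k = tn/(tn+fp)}, \eqn{accuracy_k = (tp+tn)/n}.
#' Overall precision and sensitivity are the per-class values weighted by the
#' focal column/row share of the full matrix (a class with a zero denominator
#' contributes zero with zero weight), which makes both algebraically equal to
#' the genotype concordance \eqn{trace/n}. Overall accuracy and specificity
#' are means of the defined per-class values; by default only classes present
#' in the matrix (nonzero row or column sum) enter the mean.
#'
#' Non-reference variants: `nonref_genotype_concordance` is the concordant
#' share after removing the hom-ref diagonal cell from numerator and
#' denominator; `nonref_sensitivity` divides the same numerator by the total
#' of all non-hom-ref truth rows.
#'
#' @param cm A `confusion_matrix`.
#' @param classes Class universe for the accuracy/specificity mean:
#'   `"present"` (default; classes with a nonzero row or column sum) or
#'   `"all"` (all six).
#' @param class_weights Averaging rule for accuracy/specificity: `"equal"`
#'   (default, the unweighted mean) or `"truth"` (weight each class by its
#'   truth-row share of the matrix).
#' @return A `metrics_report`: a one-row tibble with columns
#'   `genotype_concordance, nonref_genotype_concordance, nonref_sensitivity,
#'   sensitivity, precision, specificity, accuracy` plus `n`. Undefined
#'   metrics (division by zero, or an empty matrix) are `NA`.
#' @examples
#' cm <- confusion_matrix(rep(c("AA", "AB"), c(5, 3)),
#'                        rep(c("AA", "AB", "AB"), c(4, 1, 3)))
#' compute_metrics(cm)
#' @export
compute_metrics <- function(cm, classes = c("present", "all"),
                            class_weights = c("equal", "truth")) {
  classes <- match.arg(classes)
  class_weights <- match.arg(class_weights)
  n <- sum(cm)
  empty <- tibble::tibble(
    genotype_concordance = NA_real_, nonref_genotype_concordance = NA_real_,
    nonref_sensitivity = NA_real_, sensitivity = NA_real_,
    precision = NA_real_, specificity = NA_real_, accuracy = NA_real_,
    n = as.integer(n)
  )
  class(empty) <- c("metrics_report", class(empty))
  if (n == 0) {
    return(empty)
  }

  tp <- diag(unclass(cm))
  row_sum <- rowSums(cm)
  col_sum <- colSums(cm)
  fn <- row_sum - tp
  fp <- col_sum - tp
  tn <- n - tp - fn - fp
  trace <- sum(tp)

  prec_k <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  sens_k <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  spec_k <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  acc_k <- (tp + tn) / n

  # weighted sums: undefined per-class values carry zero weight by definition
  precision <- sum(ifelse(is.na(prec_k), 0, prec_k * (tp + fp) / n))
  sensitivity <- sum(ifelse(is.na(sens_k), 0, sens_k * (tp + fn) / n))

  in_universe <- if (classes == "present") row_sum > 0 | col_sum > 0 else
    rep(TRUE, 6)
  avg <- function(v) {
    use <- in_universe & !is.na(v)
    if (!any(use)) return(NA_real_)
    if (class_weights == "equal") {
      mean(v[use])
    } else {
      w <- row_sum[use]
      if (sum(w) == 0) NA_real_ else sum(v[use] * w) / sum(w)
    }
  }

  aa <- cm["AA", "AA"]
  nr_den <- n - aa
  nr_sens_den <- n - unname(row_sum["AA"])

  out <- tibble::tibble(
    genotype_concordance = trace / n,
    nonref_genotype_concordance =
      if (nr_den > 0) (trace - aa) / nr_den else NA_real_,
    nonref_sensitivity =
      if (nr_sens_den > 0) (trace - aa) / nr_sens_den else NA_real_,
    sensitivity = sensitivity,
    precision = precision,
    specificity = avg(spec_k),
    accuracy = avg(acc_k),
    n = as.integer(n)
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' Role-symmetrized concordance metrics
#'
#' With no baseline truth available, neither platform is a comparator: each
#' call set is treated alternately as truth and as test, and the two metric
#' sets are averaged element-wise. A metric undefined on either side stays
#' undefined.
#'
#' @inheritParams compute_metrics
#' @return A one-row `metrics_report` (see [compute_metrics()]).
#' @export
symmetrize_metrics <- function(cm, classes = c("present", "all"),
                               class_weights = c("equal", "truth")) {
  m1 <- compute_metrics(cm, classes, class_weights)
  m2 <- compute_metrics(t(cm), classes, class_weights)
  out <- m1
  metric_cols <- setdiff(names(m1), "n")
  for (col in metric_cols) {
    out[[col]] <- (m1[[col]] + m2[[col]]) / 2
  }
  out
}

#' Write a metrics report as a flat table
#'
#' Serializes one or more metric reports (one row per sample/comparison) as
#' TSV or JSON.
#'
#' @param reports A `metrics_report` or a tibble of row-bound reports.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(reports, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(reports)
  if (format == "tsv") {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}
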