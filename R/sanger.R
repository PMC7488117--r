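# Three-way BeadChip / WGS / Sanger adjudication: parsing Sanger genotype
# strings, classifying concordance patterns, and Sanger-as-truth metrics.

SANGER_DASHES <- c("-", "\u2013", "\u2014")  # hyphen, en dash, em dash
ALLELE_CHARS <- c("A", "C", "G", "T", "I", "D")

#' Parse a Sanger genotype string
#'
#' A two-symbol string (e.g. `"TC"`, `"II"`) is a resolved diploid genotype:
#' both the forward and the reverse chromatogram covered the position. A
#' single symbol followed by a dash (hyphen, en or em dash; e.g. `"G-"`), or
#' a bare single symbol, is a haploid call from one read only. `"NA"` (or a
#' missing value) marks a failed reaction. Indel alleles use the same `I`/`D`
#' symbols as the array platform.
#'
#' @param text Genotype string.
#' @return A list `genotype` (the raw string), `alleles` (character vector,
#'   length 2, 1 or 0) and `status` (`"RESOLVED_DIPLOID"`,
#'   `"HAPLOID_SINGLE_READ"` or `"FAILED"`).
#' @examples
#' parse_sanger_genotype("TC")$status
#' parse_sanger_genotype("G-")$status
#' @export
parse_sanger_genotype <- function(text) {
  if (length(text) != 1) {
    stop("parse_sanger_genotype() is scalar; got length ", length(text),
         call. = FALSE)
  }
  raw <- text
  if (is.na(text) || toupper(trimws(text)) == "NA") {
    return(list(genotype = raw, alleles = character(), status = "FAILED"))
  }
  chars <- strsplit(trimws(text), NULL)[[1]]
  is_allele <- chars %in% ALLELE_CHARS
  is_dash <- chars %in% SANGER_DASHES
  if (length(chars) == 2 && all(is_allele)) {
    return(list(genotype = raw, alleles = chars, status = "RESOLVED_DIPLOID"))
  }
  if (length(chars) == 2 && is_allele[1] && is_dash[2]) {
    return(list(genotype = raw, alleles = chars[1],
                status = "HAPLOID_SINGLE_READ"))
  }
  if (length(chars) == 1 && is_allele[1]) {
    return(list(genotype = raw, alleles = chars,
                status = "HAPLOID_SINGLE_READ"))
  }
  stop("unrecognized Sanger genotype string: '", raw, "'", call. = FALSE)
}

# Split a two-letter platform genotype string ("TG", "II", ...) into alleles.
split_gt_string <- function(text) {
  chars <- strsplit(trimws(text), NULL)[[1]]
  if (length(chars) != 2 || !all(chars %in% ALLELE_CHARS)) {
    stop("unrecognized platform genotype string: '", text, "'", call. = FALSE)
  }
  chars
}

#' Classify the three-way concordance pattern of one validated variant
#'
#' Resolved rows are classified by exact unordered-pair genotype equality:
#' Sanger matches both platforms (`ALL_THREE`), WGS only (`WGS_ONLY`),
#' BeadChip only (`BEADCHIP_ONLY`) or neither (`NONE`). Rows whose Sanger
#' call is not a resolved diploid genotype are `UNRESOLVED`.
#'
#' @param bead,wgs Length-2 character vectors of platform alleles.
#' @param sanger A parsed Sanger call from [parse_sanger_genotype()].
#' @return One of `"WGS_ONLY","ALL_THREE","BEADCHIP_ONLY","NONE",
#'   "UNRESOLVED"`.
#' @export
classify_concordance_pattern <- function(bead, wgs, sanger) {
  if (sanger$status != "RESOLVED_DIPLOID") {
    return("UNRESOLVED")
  }
  same <- function(x, y) identical(sort(x), sort(y))
  s_wgs <- same(sanger$alleles, wgs)
  s_bead <- same(sanger$alleles, bead)
  if (s_wgs && s_bead) "ALL_THREE"
  else if (s_wgs) "WGS_ONLY"
  else if (s_bead) "BEADCHIP_ONLY"
  else "NONE"
}

#' Read a three-way validation table
#'
#' Tab-delimited table with columns `rsID`, `Chromosome`,
#' `Position (GRCh38)` (or `Position`), `BeadChip genotype`, `WGS genotype`
#' and `Sanger genotype`; the bundled example
#' (`gtconcord_example("sanger_validation.tsv")`) follows this layout. Every
#' row is parsed and its concordance pattern classified.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the raw columns plus `sanger_status` and `pattern`.
#' @export
read_validation_table <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = NULL)
  pos_col <- intersect(c("Position (GRCh38)", "Position"), names(tab))[1]
  need <- c("rsID", "Chromosome", pos_col, "BeadChip genotype",
            "WGS genotype", "Sanger genotype")
  absent <- setdiff(need, names(tab))
  if (length(absent) || is.na(pos_col)) {
    stop("validation table is missing column(s): ",
         paste(c(absent, if (is.na(pos_col)) "Position"), collapse = ", "),
         call. = FALSE)
  }
  parsed <- lapply(tab[["Sanger genotype"]], parse_sanger_genotype)
  pattern <- vapply(seq_len(nrow(tab)), function(i) {
    classify_concordance_pattern(
      split_gt_string(tab[["BeadChip genotype"]][i]),
      split_gt_string(tab[["WGS genotype"]][i]),
      parsed[[i]]
    )
  }, character(1))
  tibble::tibble(
    rsid = tab[["rsID"]],
    chrom = tab[["Chromosome"]],
    pos = as.integer(tab[[pos_col]]),
    bead_gt = tab[["BeadChip genotype"]],
    wgs_gt = tab[["WGS genotype"]],
    sanger_gt = tab[["Sanger genotype"]],
    sanger_status = vapply(parsed, `[[`, character(1), "status"),
    pattern = pattern
  )
}

# Site-local genotype-class labels for a validation row without VCF context:
# A is the Sanger-majority allele (ties broken by total count over all three
# genotypes, then alphabetically), remaining alleles become B and C by total
# count then alphabetically.
site_local_classes <- function(bead, wgs, sanger_alleles) {
  all_alleles <- c(bead, wgs, sanger_alleles)
  counts <- sort(table(all_alleles), decreasing = TRUE)
  rank_of <- function(al) {
    # order by count desc, then alphabetically
    ord <- names(counts)[order(-as.integer(counts), names(counts))]
    match(al, ord)
  }
  s_tab <- table(sanger_alleles)
  cand <- names(s_tab)[s_tab == max(s_tab)]
  a_allele <- cand[order(rank_of(cand))][1]
  rest <- setdiff(unique(all_alleles), a_allele)
  rest <- rest[order(rank_of(rest))]
  if (length(rest) > 2) {
    stop("more than three distinct alleles in one validation row",
         call. = FALSE)
  }
  ordered <- c(a_allele, rest)
  cls <- function(pair) {
    sym <- c("A", "B", "C")[sort(match(pair, ordered))]
    paste(sym, collapse = "")
  }
  list(bead = cls(bead), wgs = cls(wgs), sanger = cls(sanger_alleles))
}

#' Sanger-as-truth concordance metrics for both platforms
#'
#' Restricts a validation table to rows with a resolved diploid Sanger
#' genotype, builds one six-class confusion matrix per platform with the
#' Sanger call as truth, and computes the concordance metrics for each.
#' Haploid single-read Sanger calls are excluded even when their one allele
#' is compatible with both platforms. Without VCF context the class labels
#' are site-local (A = the Sanger-majority allele); the weighted precision
#' and sensitivity are provably independent of that labeling choice.
#'
#' @param rows A validation tibble from [read_validation_table()].
#' @param classes,class_weights Passed to [compute_metrics()].
#' @return A list: `wgs` and `beadchip` (one-row `metrics_report` each),
#'   `cm_wgs`, `cm_beadchip` (the confusion matrices), `n_resolved`, and
#'   `pattern_counts` (named counts over the five patterns).
#' @export
validation_metrics <- function(rows, classes = "present",
                               class_weights = "equal") {
  pattern_counts <- table(factor(
    rows$pattern,
    levels = c("WGS_ONLY", "ALL_THREE", "BEADCHIP_ONLY", "NONE", "UNRESOLVED")
  ))
  resolved <- rows[rows$sanger_status == "RESOLVED_DIPLOID", ]
  n_resolved <- nrow(resolved)
  if (n_resolved == 0) {
    empty <- compute_metrics(confusion_matrix(character(), character()))
    return(list(wgs = empty, beadchip = empty,
                cm_wgs = NULL, cm_beadchip = NULL,
                n_resolved = 0L, pattern_counts = pattern_counts))
  }
  labs <- lapply(seq_len(n_resolved), function(i) {
    site_local_classes(
      split_gt_string(resolved$bead_gt[i]),
      split_gt_string(resolved$wgs_gt[i]),
      parse_sanger_genotype(resolved$sanger_gt[i])$alleles
    )
  })
  truth <- vapply(labs, `[[`, character(1), "sanger")
  cm_wgs <- confusion_matrix(truth, vapply(labs, `[[`, character(1), "wgs"))
  cm_bead <- confusion_matrix(truth, vapply(labs, `[[`, character(1), "bead"))
  list(
    wgs = compute_metrics(cm_wgs, classes, class_weights),
    beadchip = compute_metrics(cm_bead, classes, class_weights),
    cm_wgs = cm_wgs, cm_beadchip = cm_bead,
    n_resolved = n_resolved, pattern_counts = pattern_counts
  )
}
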