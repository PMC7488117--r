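# Diploid genotype-class universe shared by the whole package. A is the
# reference allele, B the first and C the second alternative allele of a site;
# an unordered diploid genotype therefore falls into one of six classes.

#' The six diploid genotype classes
#'
#' Class labels in canonical order: `AA, AB, BB, AC, BC, CC`, where A is the
#' site's reference allele and B/C its first/second alternative allele.
#' `MISSING` (a no-call on either platform) is deliberately not part of this
#' vector: missing calls never enter a confusion matrix.
#'
#' @export
GENOTYPE_CLASSES <- c("AA", "AB", "BB", "AC", "BC", "CC")

#' Assign the genotype class of a call at a site
#'
#' Maps an unordered pair of allele sequences onto one of the six diploid
#' genotype classes given the site's reference and alternative alleles
#' (A = reference, B = first alternative, C = second alternative).
#'
#' @param ref Reference allele sequence.
#' @param alts Character vector of alternative allele sequences (length 0-2).
#' @param a1,a2 The two called allele sequences, or `NA` for a no-call.
#' @return One of `"AA","AB","BB","AC","BC","CC"`, or `"MISSING"` for a
#'   no-call. An allele outside `c(ref, alts)` is an error: the call was not
#'   reconciled to the site's allele set (a harmonization bug, not bad input).
#' @examples
#' assign_genotype_class("G", "A", "A", "A") # hom-alt -> "BB"
#' assign_genotype_class("G", c("A", "T"), "A", "T") # -> "BC"
#' @export
assign_genotype_class <- function(ref, alts, a1, a2) {
  if (is.na(a1) || is.na(a2)) {
    return("MISSING")
  }
  site <- c(ref, alts)
  i <- match(c(a1, a2), site)
  if (anyNA(i)) {
    stop("allele(s) ", paste(c(a1, a2)[is.na(i)], collapse = ","),
         " not in site allele set {", paste(site, collapse = ","), "}",
         call. = FALSE)
  }
  symbols <- c("A", "B", "C")[sort(i)]
  paste(symbols, collapse = "")
}

# Vectorized class assignment over parallel allele columns. Returns a
# character vector over GENOTYPE_CLASSES plus "MISSING"; errors if any
# non-missing allele is outside its site's allele set.
classify_genotypes <- function(ref, alt1, alt2, a1, a2) {
  n <- length(ref)
  i1 <- integer(n)
  i2 <- integer(n)
  for (k in seq_len(3)) {
    site_k <- switch(k, ref, alt1, alt2)
    i1[!is.na(site_k) & !is.na(a1) & a1 == site_k] <- k
    i2[!is.na(site_k) & !is.na(a2) & a2 == site_k] <- k
  }
  missing <- is.na(a1) | is.na(a2)
  bad <- !missing & (i1 == 0L | i2 == 0L)
  if (any(bad)) {
    stop("unreconciled allele(s) at ", sum(bad), " site(s), e.g. ",
         a1[bad][1], "/", a2[bad][1], " vs {",
         paste(stats::na.omit(c(ref[bad][1], alt1[bad][1], alt2[bad][1])),
               collapse = ","), "}", call. = FALSE)
  }
  lo <- pmin(i1, i2)
  hi <- pmax(i1, i2)
  out <- paste0(c("A", "B", "C")[lo], c("A", "B", "C")[hi])
  out[missing] <- "MISSING"
  out
}

# "chr" prefix tolerant canonical chromosome ordering: 1..22, X, Y, MT,
# anything else after, alphabetically.
chrom_order <- function(chrom) {
  canon <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  canon[canon %in% c("M", "Mt", "mt")] <- "MT"
  lev <- c(as.character(1:22), "X", "Y", "MT")
  i <- match(canon, lev)
  order(ifelse(is.na(i), length(lev) + 1L, i), canon)
}

# Reverse complement for (possibly multi-base) nucleotide allele strings.
revcomp <- function(x) {
  flipped <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(flipped, NULL), function(s) paste(rev(s), collapse = ""),
         character(1))
}
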