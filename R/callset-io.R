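# Reading and harmonizing the two platform call sets.

#' Read a single-sample WGS call set from a VCF file
#'
#' Reads variant and non-variant (hom-ref, `ALT="."`) sites for one sample and
#' returns one row per retained record with the called allele sequences and the
#' genotype-level annotations DP, GQ, RGQ plus the site-level QUAL. Records
#' whose FILTER is anything other than `PASS` or `.` are dropped (and counted
#' in the `"dropped"` attribute), as are records with more than two
#' alternative alleles. Diploid (`0/1`, `0|1`) and haploid (`0`, `1`) GT
#' strings are accepted; a haploid call is represented as homozygous for its
#' single allele. `./.` (or `.`) becomes a missing call.
#'
#' @param path Path to an (uncompressed or gzipped) VCF 4.x file.
#' @param sample_name Sample column to read. May be omitted when the file
#'   contains exactly one sample; naming an absent sample is an error.
#' @return A tibble with columns `chrom, pos, id, ref, alt1, alt2, var_class,
#'   allele1, allele2, missing, dp, qual, gq, rgq`. `var_class` is `"INDEL"`
#'   iff any allele length differs from the reference allele length, else
#'   `"SNV"`. Attribute `"dropped"` holds counts of records removed by FILTER
#'   or by having >2 ALT alleles.
#' @export
read_wgs_vcf <- function(path, sample_name = NULL) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) NULL)
  if (is.null(vcf)) {
    # vcfR rejects record-less files; accept them as an empty call set
    lines <- readLines(path, warn = FALSE)
    head_line <- grep("^#CHROM\t", lines, value = TRUE)
    body <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (length(head_line) != 1L || length(body) > 0L) {
      stop("unparseable VCF file '", path, "'", call. = FALSE)
    }
    samples <- strsplit(head_line, "\t")[[1]][-(1:9)]
    if (!is.null(sample_name) && !sample_name %in% samples) {
      stop("sample '", sample_name, "' not in VCF (available: ",
           paste(samples, collapse = ", "), ")", call. = FALSE)
    }
    return(empty_wgs_tibble())
  }
  samples <- colnames(vcf@gt)[-1]
  if (is.null(sample_name)) {
    if (length(samples) != 1L) {
      stop("VCF has ", length(samples),
           " samples; supply sample_name (one of: ",
           paste(samples, collapse = ", "), ")", call. = FALSE)
    }
    sample_name <- samples
  }
  if (!sample_name %in% samples) {
    stop("sample '", sample_name, "' not in VCF (available: ",
         paste(samples, collapse = ", "), ")", call. = FALSE)
  }

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(empty_wgs_tibble())
  }
  filt <- ifelse(is.na(fix$FILTER), ".", fix$FILTER)
  keep_filter <- filt %in% c("PASS", ".")

  alt_list <- strsplit(ifelse(is.na(fix$ALT) | fix$ALT == ".", "", fix$ALT),
                       ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  keep_nalt <- n_alt <= 2L
  keep <- keep_filter & keep_nalt
  dropped <- c(filter_fail = sum(!keep_filter),
               multiallelic_gt2 = sum(keep_filter & !keep_nalt))

  idx <- which(keep)
  if (length(idx) == 0L) {
    return(empty_wgs_tibble(dropped))
  }
  gt_raw <- unname(vcfR::extract.gt(vcf, element = "GT")[, sample_name])
  num <- function(el) {
    m <- vcfR::extract.gt(vcf, element = el, as.numeric = TRUE)
    if (is.null(m)) rep(NA_real_, nrow(fix)) else unname(m[, sample_name])
  }
  dp <- num("DP")
  gq <- num("GQ")
  rgq <- num("RGQ")

  alt1 <- vapply(alt_list, function(a) if (length(a) >= 1) a[1] else NA_character_,
                 character(1))
  alt2 <- vapply(alt_list, function(a) if (length(a) >= 2) a[2] else NA_character_,
                 character(1))

  ref <- fix$REF[idx]
  a1v <- alt1[idx]
  a2v <- alt2[idx]
  gt <- gt_raw[idx]

  # resolve GT allele indices against the site allele set
  alleles <- matrix(NA_character_, nrow = length(idx), ncol = 2)
  gt_clean <- ifelse(is.na(gt), ".", gt)
  parts <- strsplit(gt_clean, "[/|]")
  for (r in seq_along(idx)) {
    p <- parts[[r]]
    if (length(p) == 1L) p <- c(p, p)  # haploid -> homozygous representation
    if (length(p) != 2L || all(p == ".")) {
      if (!all(p %in% c(".", ""))) {
        stop("unparseable GT '", gt[r], "' at VCF data line ", idx[r],
             call. = FALSE)
      }
      next
    }
    site <- c(ref[r], a1v[r], a2v[r])
    ai <- suppressWarnings(as.integer(p)) + 1L
    if (anyNA(ai) || any(ai > sum(!is.na(site)))) {
      stop("GT '", gt[r], "' indexes a missing ALT at VCF data line ", idx[r],
           call. = FALSE)
    }
    alleles[r, ] <- site[ai]
  }

  len_ref <- nchar(ref)
  is_indel <- (!is.na(a1v) & nchar(a1v) != len_ref) |
    (!is.na(a2v) & nchar(a2v) != len_ref)

  out <- tibble::tibble(
    chrom = as.character(fix$CHROM[idx]),
    pos = as.integer(fix$POS[idx]),
    id = ifelse(is.na(fix$ID[idx]), ".", fix$ID[idx]),
    ref = ref, alt1 = a1v, alt2 = a2v,
    var_class = ifelse(is_indel, "INDEL", "SNV"),
    allele1 = alleles[, 1], allele2 = alleles[, 2],
    missing = is.na(alleles[, 1]),
    dp = dp[idx],
    qual = suppressWarnings(as.numeric(fix$QUAL[idx])),
    gq = gq[idx], rgq = rgq[idx]
  )
  attr(out, "dropped") <- dropped
  out
}

empty_wgs_tibble <- function(dropped = c(filter_fail = 0L,
                                         multiallelic_gt2 = 0L)) {
  out <- tibble::tibble(
    chrom = character(), pos = integer(), id = character(),
    ref = character(), alt1 = character(), alt2 = character(),
    var_class = character(), allele1 = character(), allele2 = character(),
    missing = logical(), dp = numeric(), qual = numeric(),
    gq = numeric(), rgq = numeric()
  )
  attr(out, "dropped") <- dropped
  out
}

# Mandatory [Data] columns of a GenomeStudio-style final report.
BEADCHIP_COLUMNS <- c("SNP Name", "Chr", "Position",
                      "Allele1 - Plus", "Allele2 - Plus",
                      "GC Score", "GT Score", "Cluster Sep",
                      "Theta", "R", "X", "Y", "B Allele Freq")

#' Read a BeadChip call set from a GenomeStudio-style final report
#'
#' Parses the tab-delimited final-report dialect: a `[Header]` block of
#' key-value lines followed by a `[Data]` block whose first line names the
#' columns. One row is returned per marker. Genotypes are reported as two
#' plus-strand allele columns; `-`/`--`/`NC` entries become missing calls, and
#' indel genotypes use the `I`/`D` symbols.
#'
#' @param path Path to the report file.
#' @return A tibble with columns `chrom, pos, id, allele1, allele2, missing,
#'   gc_score, gt_score, cluster_sep, theta, r, x, y, b_allele_freq`.
#' @export
read_beadchip_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  data_at <- match("[Data]", trimws(lines))
  if (is.na(data_at) || data_at >= length(lines)) {
    stop("no [Data] section in report '", path, "'", call. = FALSE)
  }
  tab <- read.delim(text = lines[(data_at + 1L):length(lines)],
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  absent <- setdiff(BEADCHIP_COLUMNS, names(tab))
  if (length(absent)) {
    stop("report is missing mandatory column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  no_call <- c("-", "--", "NC", "")
  a1 <- trimws(tab[["Allele1 - Plus"]])
  a2 <- trimws(tab[["Allele2 - Plus"]])
  missing <- a1 %in% no_call | a2 %in% no_call
  a1[missing] <- NA_character_
  a2[missing] <- NA_character_
  tibble::tibble(
    chrom = as.character(tab[["Chr"]]),
    pos = as.integer(tab[["Position"]]),
    id = tab[["SNP Name"]],
    allele1 = a1, allele2 = a2, missing = missing,
    gc_score = as.numeric(tab[["GC Score"]]),
    gt_score = as.numeric(tab[["GT Score"]]),
    cluster_sep = as.numeric(tab[["Cluster Sep"]]),
    theta = as.numeric(tab[["Theta"]]),
    r = as.numeric(tab[["R"]]),
    x = as.numeric(tab[["X"]]),
    y = as.numeric(tab[["Y"]]),
    b_allele_freq = as.numeric(tab[["B Allele Freq"]])
  )
}

#' Harmonize WGS and BeadChip call sets into paired per-site calls
#'
#' Intersects the two call sets on (chromosome, position), keeps only sites
#' successfully genotyped on *both* platforms, reconciles BeadChip allele
#' symbols against the VCF allele set, assigns the six-class genotype labels
#' and flags concordance. Allele reconciliation attempts a direct match first,
#' then the reverse complement (strand flip); for indel sites the BeadChip
#' `I`/`D` symbols map to the longer/shorter of the VCF ref/alt alleles. Calls
#' that cannot be reconciled are excluded and tallied, not fatal; mismatching
#' calls at complementary-pair (A/T or C/G) sites are tallied separately as
#' strand-ambiguous since a flip cannot be proven there.
#'
#' @param wgs Tibble from [read_wgs_vcf()] (carries the site ref/alt alleles).
#' @param beadchip Tibble from [read_beadchip_report()].
#' @param exclude_chroms Chromosomes dropped before pairing (e.g.
#'   `c("MT","X","Y")` for males, `"MT"` for females).
#' @param truth Which platform plays the TRUTH role for class labelling;
#'   the site membership of the result is identical either way.
#' @return A tibble of paired calls: site columns (`chrom, pos, id, ref, alt1,
#'   alt2, var_class`), per-role allele columns (`truth_a1, truth_a2, test_a1,
#'   test_a2`), compact genotype strings (`truth_gt, test_gt`; `I`/`D` symbols
#'   at indel sites), `class_truth`, `class_test` and `concordant`. Attribute
#'   `"harmonize_report"` tallies exclusions (per-platform-only sites,
#'   missing calls, excluded chromosomes, irreconcilable and strand-ambiguous
#'   sites).
#' @export
harmonize_pair <- function(wgs, beadchip, exclude_chroms = character(),
                           truth = c("wgs", "beadchip")) {
  truth <- match.arg(truth)

  excl_w <- wgs$chrom %in% exclude_chroms
  excl_b <- beadchip$chrom %in% exclude_chroms
  w <- wgs[!excl_w, ]
  b <- beadchip[!excl_b, ]

  key_w <- paste(w$chrom, w$pos)
  key_b <- paste(b$chrom, b$pos)
  iw <- match(key_b, key_w)
  shared <- !is.na(iw)
  report <- c(
    n_excluded_chrom = sum(excl_w) + sum(excl_b),
    n_wgs_only = nrow(w) - length(unique(iw[shared])),
    n_beadchip_only = sum(!shared)
  )

  b2 <- b[shared, ]
  w2 <- w[iw[shared], ]

  drop_missing <- w2$missing | b2$missing
  report["n_missing_either"] <- sum(drop_missing)
  w2 <- w2[!drop_missing, ]
  b2 <- b2[!drop_missing, ]

  rec <- reconcile_beadchip_alleles(w2$ref, w2$alt1, w2$alt2, w2$var_class,
                                    b2$allele1, b2$allele2)
  report["n_irreconcilable"] <- sum(rec$status == "irreconcilable")
  report["n_ambiguous_strand"] <- sum(rec$status == "ambiguous")
  ok <- rec$status == "ok"
  w2 <- w2[ok, ]
  b2 <- b2[ok, ]
  bead_a1 <- rec$a1[ok]
  bead_a2 <- rec$a2[ok]

  if (truth == "wgs") {
    t_a1 <- w2$allele1; t_a2 <- w2$allele2
    s_a1 <- bead_a1; s_a2 <- bead_a2
  } else {
    t_a1 <- bead_a1; t_a2 <- bead_a2
    s_a1 <- w2$allele1; s_a2 <- w2$allele2
  }
  class_truth <- classify_genotypes(w2$ref, w2$alt1, w2$alt2, t_a1, t_a2)
  class_test <- classify_genotypes(w2$ref, w2$alt1, w2$alt2, s_a1, s_a2)

  out <- tibble::tibble(
    chrom = w2$chrom, pos = w2$pos, id = w2$id,
    ref = w2$ref, alt1 = w2$alt1, alt2 = w2$alt2,
    var_class = w2$var_class,
    truth_a1 = t_a1, truth_a2 = t_a2,
    test_a1 = s_a1, test_a2 = s_a2,
    truth_gt = genotype_string(w2$ref, w2$alt1, w2$var_class, t_a1, t_a2),
    test_gt = genotype_string(w2$ref, w2$alt1, w2$var_class, s_a1, s_a2),
    class_truth = class_truth, class_test = class_test,
    concordant = class_truth == class_test
  )
  out <- out[chrom_order(out$chrom), ]
  out <- out[order(match(out$chrom, unique(out$chrom)), out$pos), ]
  attr(out, "harmonize_report") <- report
  out
}

# Reconcile BeadChip allele symbols against the VCF allele set of each site.
# Returns list(a1, a2, status) with status in {ok, irreconcilable, ambiguous};
# reconciled alleles are VCF sequences (indel I/D symbols resolved).
reconcile_beadchip_alleles <- function(ref, alt1, alt2, var_class, a1, a2) {
  n <- length(ref)
  out1 <- character(n)
  out2 <- character(n)
  status <- rep("ok", n)
  comp_pair <- function(x, y) {
    (x == "A" & y == "T") | (x == "T" & y == "A") |
      (x == "C" & y == "G") | (x == "G" & y == "C")
  }
  for (i in seq_len(n)) {
    site <- stats::na.omit(c(ref[i], alt1[i], alt2[i]))
    bi <- c(a1[i], a2[i])
    if (var_class[i] == "INDEL") {
      if (!all(bi %in% c("I", "D")) || is.na(alt1[i]) ||
          nchar(ref[i]) == nchar(alt1[i])) {
        status[i] <- "irreconcilable"
        next
      }
      longer <- if (nchar(ref[i]) >= nchar(alt1[i])) ref[i] else alt1[i]
      shorter <- if (nchar(ref[i]) >= nchar(alt1[i])) alt1[i] else ref[i]
      mapped <- ifelse(bi == "I", longer, shorter)
      out1[i] <- mapped[1]
      out2[i] <- mapped[2]
      next
    }
    if (all(bi %in% site)) {
      out1[i] <- bi[1]
      out2[i] <- bi[2]
    } else if (all(revcomp(bi) %in% site)) {
      out1[i] <- revcomp(bi[1])
      out2[i] <- revcomp(bi[2])
    } else if (length(site) == 2 && comp_pair(site[1], site[2])) {
      # palindromic site: a mismatch cannot be attributed to strand
      status[i] <- "ambiguous"
    } else {
      status[i] <- "irreconcilable"
    }
  }
  list(a1 = out1, a2 = out2, status = status)
}

# Compact two-letter genotype string; indel sites use I/D symbols
# (I = the longer of ref/alt1, D = the shorter), SNV sites the bases.
genotype_string <- function(ref, alt1, var_class, a1, a2) {
  sym <- function(a, i) {
    if (var_class[i] != "INDEL") return(a)
    longer <- if (nchar(ref[i]) >= nchar(alt1[i])) ref[i] else alt1[i]
    if (a == longer) "I" else "D"
  }
  vapply(seq_along(ref), function(i) {
    s <- sort(c(sym(a1[i], i), sym(a2[i], i)))
    paste(s, collapse = "")
  }, character(1))
}
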