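# Seeded synthetic paired call sets: Hardy-Weinberg truth genotypes,
# platform-specific miscall processes, BeadChip intensity clusters, and
# writers for the two platform file formats so the full pipeline can run
# end-to-end without any subject-level data.

# GRCh38 autosome lengths (bp), used to weight site placement.
GRCH38_AUTOSOME_LENGTHS <- c(
  `1` = 248956422, `2` = 242193529, `3` = 198295559, `4` = 190214555,
  `5` = 181538259, `6` = 170805979, `7` = 159345973, `8` = 145138636,
  `9` = 138394717, `10` = 133797422, `11` = 135086622, `12` = 133275309,
  `13` = 114364328, `14` = 107043718, `15` = 101991189, `16` = 90338345,
  `17` = 83257441, `18` = 80373285, `19` = 58617616, `20` = 64444167,
  `21` = 46709983, `22` = 50818468
)

#' Configuration of a synthetic paired-call-set study
#'
#' Defaults emulate the regime of a single-subject BeadChip vs WGS
#' comparison: per-platform miscall rates of 0.2% and 0.4% give a pairwise
#' discordance near 0.6%, inside the observed 0.3-0.9% per-sample range;
#' Theta clusters have sd 0.04 around the canonical centers so genotype
#' clusters are well separated but brush at the borders.
#'
#' @param n_sites Number of polymorphic sites.
#' @param chrom_lengths Named vector of chromosome lengths (bp); defaults to
#'   the 22 GRCh38 autosomes.
#' @param maf_range Uniform range for the minor (alternative) allele
#'   frequency.
#' @param frac_indel Fraction of sites that are indels.
#' @param frac_triallelic Fraction of SNV sites carrying a second
#'   alternative allele.
#' @param error_rate_wgs,error_rate_beadchip Per-platform genotype miscall
#'   probabilities, each in \[0, 0.5\].
#' @param border_enrichment Shift the Theta mean of discordant BeadChip
#'   calls halfway toward the nearest cluster border?
#' @param theta_sd Standard deviation of the Theta cluster around its
#'   center.
#' @param mean_depth Mean simulated WGS read depth (Poisson).
#' @param seed Top-level integer seed; every stochastic step derives its
#'   stream from it (fixed small offsets), so one seed fixes every
#'   downstream number.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_sites = 1e5,
                              chrom_lengths = GRCH38_AUTOSOME_LENGTHS,
                              maf_range = c(0.05, 0.5),
                              frac_indel = 0.1,
                              frac_triallelic = 0.01,
                              error_rate_wgs = 0.002,
                              error_rate_beadchip = 0.004,
                              border_enrichment = TRUE,
                              theta_sd = 0.04,
                              mean_depth = 30,
                              seed = 1L) {
  stopifnot(n_sites >= 1,
            frac_indel >= 0, frac_indel <= 1,
            frac_triallelic >= 0, frac_triallelic <= 1,
            error_rate_wgs >= 0, error_rate_wgs <= 0.5,
            error_rate_beadchip >= 0, error_rate_beadchip <= 0.5,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            theta_sd > 0, is.logical(border_enrichment))
  if (n_sites > sum(chrom_lengths)) {
    stop("n_sites exceeds the total genome length", call. = FALSE)
  }
  structure(list(
    n_sites = as.integer(n_sites), chrom_lengths = chrom_lengths,
    maf_range = maf_range, frac_indel = frac_indel,
    frac_triallelic = frac_triallelic,
    error_rate_wgs = error_rate_wgs,
    error_rate_beadchip = error_rate_beadchip,
    border_enrichment = border_enrichment, theta_sd = theta_sd,
    mean_depth = mean_depth, seed = as.integer(seed)
  ), class = "simulation_config")
}

# sub-stream seeds: small fixed offsets from the top-level seed
sub_seed <- function(cfg, offset) (cfg$seed + offset) %% .Machine$integer.max

#' Simulate true genotypes at random polymorphic sites
#'
#' Sites are placed uniformly without replacement within each chromosome
#' (chromosomes weighted by length); each site gets a reference allele, one
#' or two alternative alleles (SNV or simple 1-3 bp insertion/deletion) and
#' an alternative-allele frequency drawn from `maf_range`. The two true
#' alleles are drawn independently from the site's allele frequencies, i.e.
#' genotypes follow Hardy-Weinberg proportions. Triallelic sites split the
#' alternative frequency 2:1 between B and C.
#'
#' @param cfg A [simulation_config()].
#' @return A tibble of truth records: `chrom, pos, id, ref, alt1, alt2,
#'   var_class, maf, a1, a2` (alleles as sequences, unordered).
#' @export
simulate_truth <- function(cfg) {
  set.seed(sub_seed(cfg, 0L))
  lens <- cfg$chrom_lengths
  n_per <- as.vector(stats::rmultinom(1, cfg$n_sites, lens / sum(lens)))
  n_per <- pmin(n_per, lens)  # cannot exceed a chromosome's length
  short <- cfg$n_sites - sum(n_per)
  if (short > 0) n_per[which.max(lens - n_per)] <- n_per[which.max(lens - n_per)] + short

  chrom <- rep(names(lens), n_per)
  pos <- unlist(lapply(seq_along(lens), function(i) {
    sort(sample.int(lens[i], n_per[i]))
  }), use.names = FALSE)
  n <- length(pos)

  bases <- c("A", "C", "G", "T")
  ref_base <- sample(bases, n, replace = TRUE)
  alt_base <- vapply(ref_base, function(b) sample(setdiff(bases, b), 1),
                     character(1))

  is_indel <- runif(n) < cfg$frac_indel
  is_tri <- !is_indel & runif(n) < cfg$frac_triallelic
  ins <- is_indel & runif(n) < 0.5
  extra <- vapply(seq_len(n), function(i) {
    paste(sample(bases, sample(1:3, 1), replace = TRUE), collapse = "")
  }, character(1))

  ref <- ref_base
  alt1 <- alt_base
  # insertion: ALT longer than REF; deletion: REF longer than ALT
  ref[is_indel & !ins] <- paste0(ref_base[is_indel & !ins],
                                 extra[is_indel & !ins])
  alt1[is_indel & !ins] <- ref_base[is_indel & !ins]
  alt1[is_indel & ins] <- paste0(ref_base[is_indel & ins],
                                 extra[is_indel & ins])
  ref[is_indel & ins] <- ref_base[is_indel & ins]

  alt2 <- rep(NA_character_, n)
  alt2[is_tri] <- vapply(which(is_tri), function(i) {
    sample(setdiff(bases, c(ref[i], alt1[i])), 1)
  }, character(1))

  maf <- runif(n, cfg$maf_range[1], cfg$maf_range[2])
  p_b <- ifelse(is_tri, maf * 2 / 3, maf)
  p_c <- ifelse(is_tri, maf / 3, 0)
  draw <- function() {
    u <- runif(n)
    ifelse(u < p_c, 3L, ifelse(u < p_c + p_b, 2L, 1L))
  }
  i1 <- draw()
  i2 <- draw()
  allele_at <- function(i) {
    ifelse(i == 1L, ref, ifelse(i == 2L, alt1, alt2))
  }

  tibble::tibble(
    chrom = chrom, pos = as.integer(pos),
    id = sprintf("sim%07d", seq_len(n)),
    ref = ref, alt1 = alt1, alt2 = alt2,
    var_class = ifelse(is_indel, "INDEL", "SNV"),
    maf = maf,
    a1 = allele_at(i1), a2 = allele_at(i2)
  )
}

# genotype index within the site's unordered-genotype universe:
# biallelic {1:AA,2:AB,3:BB}, triallelic {1:AA,2:AB,3:BB,4:AC,5:BC,6:CC}
genotype_index <- function(truth) {
  i1 <- ifelse(truth$a1 == truth$ref, 1L,
               ifelse(truth$a1 == truth$alt1, 2L, 3L))
  i2 <- ifelse(truth$a2 == truth$ref, 1L,
               ifelse(truth$a2 == truth$alt1, 2L, 3L))
  lo <- pmin(i1, i2)
  hi <- pmax(i1, i2)
  match(paste(lo, hi), c("1 1", "1 2", "2 2", "1 3", "2 3", "3 3"))
}

index_alleles <- function(truth, gi) {
  pair <- list(c(1L, 1L), c(1L, 2L), c(2L, 2L), c(1L, 3L), c(2L, 3L),
               c(3L, 3L))
  site <- cbind(truth$ref, truth$alt1, truth$alt2)
  a1 <- site[cbind(seq_along(gi), vapply(pair[gi], `[`, integer(1), 1))]
  a2 <- site[cbind(seq_along(gi), vapply(pair[gi], `[`, integer(1), 2))]
  list(a1 = a1, a2 = a2)
}

#' Simulate one platform's genotype calls from the truth
#'
#' Each call equals the true genotype with probability `1 - error_rate`;
#' otherwise a genotype is drawn uniformly from the site's *other* possible
#' genotype classes (2 alternatives at a biallelic site, 5 at a triallelic
#' one). Errors are independent across platforms given the truth, so the
#' expected pairwise discordance of two platforms with small error rates
#' e1 and e2 is close to e1 + e2.
#'
#' @param truth Output of [simulate_truth()].
#' @param error_rate Miscall probability in \[0, 0.5\].
#' @param seed Integer seed for this platform's error stream.
#' @return A tibble `chrom, pos, id, ref, alt1, alt2, var_class, allele1,
#'   allele2, missing` (site columns carried through for the writers).
#' @export
simulate_platform_calls <- function(truth, error_rate, seed) {
  stopifnot(error_rate >= 0, error_rate <= 0.5)
  set.seed(seed)
  n <- nrow(truth)
  gi <- genotype_index(truth)
  n_classes <- ifelse(is.na(truth$alt2), 3L, 6L)
  err <- runif(n) < error_rate
  # uniformly pick one of the other classes by offset in 1..n_classes-1
  offset <- 1L + floor(runif(n) * (n_classes - 1))
  gi_call <- gi
  gi_call[err] <- ((gi[err] - 1L + offset[err]) %% n_classes[err]) + 1L
  al <- index_alleles(truth, gi_call)
  tibble::tibble(
    chrom = truth$chrom, pos = truth$pos, id = truth$id,
    ref = truth$ref, alt1 = truth$alt1, alt2 = truth$alt2,
    var_class = truth$var_class,
    allele1 = al$a1, allele2 = al$a2, missing = FALSE
  )
}

#' Simulate BeadChip intensity metrics for a set of calls
#'
#' Theta is drawn from a Gaussian around the canonical center of the called
#' class (0 / 0.5 / 1), truncated to \[0, 1\]; when `border_enrichment` is on
#' and a call is flagged discordant, the mean is shifted halfway toward the
#' nearest cluster border (0.25 or 0.75), reproducing the near-border excess
#' of discordant calls. R is log-normal; the GC score decreases linearly in
#' the call's distance from its cluster center (clipped to \[0, 1\]); X/Y are
#' recovered from Theta and R via the polar transform
#' \eqn{\theta = (2/\pi)\,atan(y/x)}, \eqn{R = x + y}; the B allele frequency
#' interpolates Theta between the canonical cluster centers.
#'
#' @param calls Output of [simulate_platform_calls()].
#' @param discordant_flags Logical vector aligned with `calls`.
#' @param cfg A [simulation_config()].
#' @return A tibble of per-marker records: `chrom, pos, id, gc_score,
#'   gt_score, cluster_sep, theta, r, x, y, b_allele_freq`.
#' @export
simulate_beadchip_intensities <- function(calls, discordant_flags, cfg) {
  stopifnot(length(discordant_flags) == nrow(calls))
  set.seed(sub_seed(cfg, 3L))
  n <- nrow(calls)
  n_alt <- (calls$allele1 != calls$ref) + (calls$allele2 != calls$ref)
  center <- c(0, 0.5, 1)[n_alt + 1L]
  mean_theta <- center
  if (isTRUE(cfg$border_enrichment)) {
    border <- ifelse(center < 0.5, 0.25,
                     ifelse(center > 0.5, 0.75,
                            ifelse(runif(n) < 0.5, 0.25, 0.75)))
    shift <- discordant_flags
    mean_theta[shift] <- center[shift] + (border[shift] - center[shift]) / 2
  }
  theta <- pmin(1, pmax(0, rnorm(n, mean_theta, cfg$theta_sd)))
  r <- rlnorm(n, meanlog = 0, sdlog = 0.15)
  dist <- abs(theta - center)
  gc <- pmin(1, pmax(0, 0.92 - 1.2 * dist + rnorm(n, 0, 0.03)))
  angle <- theta * pi / 2
  x <- r * cos(angle) / (cos(angle) + sin(angle))
  y <- r - x
  baf <- pmin(1, pmax(0, theta))
  tibble::tibble(
    chrom = calls$chrom, pos = calls$pos, id = calls$id,
    gc_score = round(gc, 4),
    gt_score = round(pmin(1, pmax(0, rnorm(n, 0.8, 0.05))), 4),
    cluster_sep = round(pmin(1, pmax(0, rnorm(n, 0.9, 0.1))), 4),
    theta = round(theta, 4), r = round(r, 4),
    x = round(x, 4), y = round(y, 4),
    b_allele_freq = round(baf, 4)
  )
}

#' Simulate WGS genotype-level annotations
#'
#' Poisson read depth, integer Phred-scaled qualities: variant calls get a
#' QUAL and a conditional GQ; hom-ref calls get an RGQ instead (GQ absent),
#' mirroring an all-sites caller's output.
#'
#' @param calls Output of [simulate_platform_calls()].
#' @param cfg A [simulation_config()].
#' @return A tibble `chrom, pos, id, dp, qual, gq, rgq`.
#' @export
simulate_wgs_annotations <- function(calls, cfg) {
  set.seed(sub_seed(cfg, 4L))
  n <- nrow(calls)
  hom_ref <- calls$allele1 == calls$ref & calls$allele2 == calls$ref
  dp <- rpois(n, cfg$mean_depth)
  gq <- pmin(99L, as.integer(round(rnorm(n, 80, 12))))
  rgq <- pmin(99L, as.integer(round(rnorm(n, 45, 10))))
  tibble::tibble(
    chrom = calls$chrom, pos = calls$pos, id = calls$id,
    dp = as.integer(dp),
    qual = as.integer(pmax(1L, round(rnorm(n, 500, 120)))),
    gq = ifelse(hom_ref, NA_integer_, pmax(1L, gq)),
    rgq = ifelse(hom_ref, pmax(1L, rgq), NA_integer_)
  )
}

#' Write a call set as a VCF 4.2 file
#'
#' Emits one record per site with GT (allele indices against REF/ALT),
#' DP, GQ and RGQ genotype fields and the site QUAL; FILTER is `PASS`.
#' Missing calls are written as `./.`. Files written here are re-read
#' exactly by [read_wgs_vcf()].
#'
#' @param calls Output of [simulate_platform_calls()] (or any tibble with
#'   the same site/allele columns).
#' @param annotations Optional tibble from [simulate_wgs_annotations()],
#'   aligned with `calls`.
#' @param path Output file path.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_wgs_vcf <- function(calls, annotations = NULL, path,
                          sample_name = "SAMPLE") {
  n <- nrow(calls)
  alt_field <- ifelse(is.na(calls$alt2), calls$alt1,
                      paste0(calls$alt1, ",", calls$alt2))
  alt_field[is.na(alt_field)] <- "."
  idx <- function(a) {
    ifelse(is.na(a), NA_integer_,
           ifelse(a == calls$ref, 0L,
                  ifelse(a == calls$alt1, 1L, 2L)))
  }
  i1 <- idx(calls$allele1)
  i2 <- idx(calls$allele2)
  gt <- ifelse(is.na(i1) | is.na(i2), "./.",
               paste0(pmin(i1, i2), "/", pmax(i1, i2)))
  if (is.null(annotations)) {
    fmt <- "GT"
    sample_field <- gt
    qual <- rep(".", n)
  } else {
    fmt <- "GT:DP:GQ:RGQ"
    num_or_dot <- function(v) ifelse(is.na(v), ".", as.character(v))
    sample_field <- paste(gt, num_or_dot(annotations$dp),
                          num_or_dot(annotations$gq),
                          num_or_dot(annotations$rgq), sep = ":")
    qual <- num_or_dot(annotations$qual)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gtconcord-simulator",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Conditional genotype quality">',
    '##FORMAT=<ID=RGQ,Number=1,Type=Integer,Description="Reference genotype confidence">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- if (n == 0L) character(0) else {
    paste(calls$chrom, calls$pos, calls$id, calls$ref, alt_field,
          qual, "PASS", ".", fmt, sample_field, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a call set as a GenomeStudio-style final report
#'
#' Emits the `[Header]`/`[Data]` tab-delimited dialect read back by
#' [read_beadchip_report()]. Indel genotypes are written with the `I`/`D`
#' symbols (I = the longer of ref/alt); missing calls as `-`/`-`.
#'
#' @param calls Output of [simulate_platform_calls()].
#' @param records Tibble from [simulate_beadchip_intensities()], aligned
#'   with `calls`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_beadchip_report <- function(calls, records, path) {
  n <- nrow(calls)
  sym <- function(a) {
    out <- a
    ind <- calls$var_class == "INDEL" & !is.na(a)
    longer <- ifelse(nchar(calls$ref) >= nchar(calls$alt1),
                     calls$ref, calls$alt1)
    out[ind] <- ifelse(a[ind] == longer[ind], "I", "D")
    out[is.na(out)] <- "-"
    out
  }
  header <- c(
    "[Header]",
    "GSGT Version\t2.0.4",
    "Processing Date\t2026-01-01",
    paste0("Num SNPs\t", n),
    paste0("Total SNPs\t", n),
    "Num Samples\t1",
    "[Data]",
    paste(BEADCHIP_COLUMNS, collapse = "\t")
  )
  body <- paste(calls$id, calls$chrom, calls$pos,
                sym(calls$allele1), sym(calls$allele2),
                records$gc_score, records$gt_score, records$cluster_sep,
                records$theta, records$r, records$x, records$y,
                records$b_allele_freq, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Run the full synthetic study
#'
#' Simulates the truth, both platforms' calls, the WGS annotations and the
#' BeadChip intensities (discordance flags taken as bead-vs-WGS genotype
#' inequality), and optionally writes the paired VCF + final report + truth
#' TSV to a directory.
#'
#' @param cfg A [simulation_config()].
#' @param dir Optional output directory (created if needed).
#' @param sample_name Sample name used in the VCF.
#' @return A list `truth, wgs_calls, bead_calls, wgs_annotations,
#'   bead_records` and, when `dir` is given, `paths` (named file paths).
#' @export
simulate_paired_study <- function(cfg = simulation_config(), dir = NULL,
                                  sample_name = "SYNTH001") {
  truth <- simulate_truth(cfg)
  wgs_calls <- simulate_platform_calls(truth, cfg$error_rate_wgs,
                                       sub_seed(cfg, 1L))
  bead_calls <- simulate_platform_calls(truth, cfg$error_rate_beadchip,
                                        sub_seed(cfg, 2L))
  discordant <- !(pmin(wgs_calls$allele1, wgs_calls$allele2) ==
                    pmin(bead_calls$allele1, bead_calls$allele2) &
                    pmax(wgs_calls$allele1, wgs_calls$allele2) ==
                    pmax(bead_calls$allele1, bead_calls$allele2))
  bead_records <- simulate_beadchip_intensities(bead_calls, discordant, cfg)
  wgs_annotations <- simulate_wgs_annotations(wgs_calls, cfg)
  out <- list(truth = truth, wgs_calls = wgs_calls, bead_calls = bead_calls,
              wgs_annotations = wgs_annotations, bead_records = bead_records)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      vcf = file.path(dir, paste0(sample_name, ".vcf")),
      report = file.path(dir, paste0(sample_name, "_finalreport.txt")),
      truth = file.path(dir, paste0(sample_name, "_truth.tsv"))
    )
    write_wgs_vcf(wgs_calls, wgs_annotations, paths["vcf"], sample_name)
    write_beadchip_report(bead_calls, bead_records, paths["report"])
    write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$paths <- paths
  }
  out
}
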