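test_that("truth simulation is seeded, Hardy-Weinberg and respects fractions", {
  cfg <- simulation_config(n_sites = 1e4, maf_range = c(0.5, 0.5),
                           frac_indel = 0, frac_triallelic = 0, seed = 101)
  truth <- simulate_truth(cfg)
  expect_equal(nrow(truth), 1e4)
  expect_true(all(truth$var_class == "SNV"))
  het <- mean(truth$a1 != truth$a2)
  expect_lt(abs(het - 0.5), 0.02) # 2pq at p = 0.5

  truth2 <- simulate_truth(cfg)
  expect_identical(truth, truth2) # same seed, same output

  cfg3 <- simulation_config(n_sites = 2000, frac_indel = 0.3, seed = 5)
  truth3 <- simulate_truth(cfg3)
  frac <- mean(truth3$var_class == "INDEL")
  expect_lt(abs(frac - 0.3), 0.05)
  # positions strictly increasing within every chromosome
  by_chrom <- split(truth3$pos, truth3$chrom)
  expect_true(all(vapply(by_chrom, function(p) !is.unsorted(p, strictly = TRUE),
                         logical(1))))
})

test_that("site count beyond the genome length is rejected", {
  expect_error(simulation_config(n_sites = 100,
                                 chrom_lengths = c(`1` = 10, `2` = 20)),
               "exceeds")
})

test_that("platform calls reproduce the truth at error rate zero", {
  cfg <- simulation_config(n_sites = 2000, seed = 17)
  truth <- simulate_truth(cfg)
  calls <- simulate_platform_calls(truth, 0, seed = 99)
  expect_equal(pmin(calls$allele1, calls$allele2),
               pmin(truth$a1, truth$a2))
  expect_equal(pmax(calls$allele1, calls$allele2),
               pmax(truth$a1, truth$a2))
})

test_that("pairwise discordance approximates the summed error rates", {
  cfg <- simulation_config(n_sites = 1e5, seed = 23)
  truth <- simulate_truth(cfg)
  a <- simulate_platform_calls(truth, 0.002, seed = 301)
  b <- simulate_platform_calls(truth, 0.004, seed = 302)
  disc <- mean(!(pmin(a$allele1, a$allele2) == pmin(b$allele1, b$allele2) &
                   pmax(a$allele1, a$allele2) == pmax(b$allele1, b$allele2)))
  p <- 0.002 + 0.004
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(disc - p), 3 * se) # the observed ~0.6% regime
})

test_that("border enrichment pushes discordant thetas off their centers", {
  cfg <- simulation_config(n_sites = 5000, border_enrichment = TRUE,
                           seed = 41)
  truth <- simulate_truth(cfg)
  calls <- simulate_platform_calls(truth, 0.05, seed = 401)
  flags <- runif(nrow(calls)) < 0.1
  recs <- simulate_beadchip_intensities(calls, flags, cfg)
  n_alt <- (calls$allele1 != calls$ref) + (calls$allele2 != calls$ref)
  center <- c(0, 0.5, 1)[n_alt + 1]
  dist <- abs(recs$theta - center)
  expect_gt(mean(dist[flags]), mean(dist[!flags]))

  # hom-ref cluster stays within [0, 0.2] without enrichment
  cfg0 <- simulation_config(n_sites = 5000, border_enrichment = FALSE,
                            seed = 41)
  recs0 <- simulate_beadchip_intensities(calls, flags, cfg0)
  aa <- n_alt == 0
  expect_gt(mean(recs0$theta[aa] <= 0.2), 0.99)

  # GC score decreases with distance from the cluster center
  fit <- coef(lm(recs$gc_score ~ dist))
  expect_lt(fit["dist"], 0)
})

test_that("written platform files round-trip through the readers exactly", {
  cfg <- simulation_config(n_sites = 1000, frac_triallelic = 0.02, seed = 53)
  sim <- simulate_paired_study(cfg, dir = tempfile("simdir"))
  wgs <- read_wgs_vcf(sim$paths["vcf"], "SYNTH001")
  bead <- read_beadchip_report(sim$paths["report"])

  expect_equal(nrow(wgs), 1000)
  expect_equal(wgs$pos, sim$wgs_calls$pos)
  expect_equal(pmin(wgs$allele1, wgs$allele2),
               pmin(sim$wgs_calls$allele1, sim$wgs_calls$allele2))
  expect_equal(pmax(wgs$allele1, wgs$allele2),
               pmax(sim$wgs_calls$allele1, sim$wgs_calls$allele2))
  expect_equal(wgs$dp, as.numeric(sim$wgs_annotations$dp))
  expect_equal(wgs$gq, as.numeric(sim$wgs_annotations$gq))
  expect_equal(wgs$rgq, as.numeric(sim$wgs_annotations$rgq))
  expect_equal(wgs$qual, as.numeric(sim$wgs_annotations$qual))

  expect_equal(nrow(bead), 1000)
  expect_equal(bead$theta, sim$bead_records$theta)
  expect_equal(bead$gc_score, sim$bead_records$gc_score)
  expect_equal(bead$b_allele_freq, sim$bead_records$b_allele_freq)
})

test_that("an empty call set still writes valid header-only files", {
  cfg <- simulation_config(n_sites = 10, seed = 3)
  truth <- simulate_truth(cfg)[0, ]
  calls <- simulate_platform_calls(truth, 0, seed = 1)
  vcf <- tempfile(fileext = ".vcf")
  write_wgs_vcf(calls, NULL, vcf, "S0")
  expect_equal(nrow(read_wgs_vcf(vcf, "S0")), 0)
})

test_that("a triallelic site travels end-to-end and reaches class C", {
  site <- tibble::tibble(
    chrom = "1", pos = 1000L, id = "tri1", ref = "G", alt1 = "A",
    alt2 = "T", var_class = "SNV", maf = 0.3, a1 = "A", a2 = "T"
  )
  calls <- simulate_platform_calls(site, 0, seed = 1)
  ann <- tibble::tibble(chrom = "1", pos = 1000L, id = "tri1", dp = 30L,
                        qual = 500L, gq = 90L, rgq = NA_integer_)
  vcf <- tempfile(fileext = ".vcf")
  write_wgs_vcf(calls, ann, vcf, "S1")
  line <- grep("^1\t1000", readLines(vcf), value = TRUE)
  expect_match(line, "\tA,T\t") # two ALT alleles in one record

  wgs <- read_wgs_vcf(vcf, "S1")
  report <- write_beadchip_fixture(list(bead_row("tri1", "1", "1000",
                                                 "A", "T")))
  paired <- harmonize_pair(wgs, read_beadchip_report(report))
  expect_equal(paired$class_truth, "BC")
  expect_equal(paired$class_test, "BC")
})

test_that("zero platform error propagates to perfect pipeline concordance", {
  cfg <- simulation_config(n_sites = 3000, error_rate_wgs = 0,
                           error_rate_beadchip = 0, seed = 71)
  sim <- simulate_paired_study(cfg, dir = tempfile("simdir0"))
  paired <- harmonize_pair(read_wgs_vcf(sim$paths["vcf"], "SYNTH001"),
                           read_beadchip_report(sim$paths["report"]))
  m <- compute_metrics(build_confusion_matrix(paired))
  expect_equal(m$genotype_concordance, 1)
  expect_equal(m$n, 3000L)
})
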