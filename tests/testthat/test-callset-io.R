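test_that("VCF reading captures genotypes, annotations and filter policy", {
  path <- write_vcf_fixture(list(
    c("1", "109711919", "rs1633365", "T", "C", "612", "PASS", ".",
      "0/1:31:88:."),
    c("1", "200", "nocall", "G", "A", "50", "PASS", ".", "./.:.:.:."),
    c("1", "300", "homref", "A", ".", "30", ".", ".", "0/0:28:.:45"),
    c("1", "400", "failed", "C", "T", "99", "LowQual", ".", "1/1:30:90:."),
    c("1", "500", "ins", "A", "AG", "700", "PASS", ".", "1/1:25:77:."),
    c("X", "600", "haploid", "G", "T", "88", "PASS", ".", "1:20:60:.")
  ))
  calls <- read_wgs_vcf(path, "S1")

  expect_equal(nrow(calls), 5) # LowQual row dropped
  expect_equal(unname(attr(calls, "dropped")["filter_fail"]), 1)

  het <- calls[calls$id == "rs1633365", ]
  expect_setequal(c(het$allele1, het$allele2), c("T", "C"))
  expect_equal(het$dp, 31)
  expect_equal(het$gq, 88)
  expect_equal(het$qual, 612)

  expect_true(calls$missing[calls$id == "nocall"])

  homref <- calls[calls$id == "homref", ]
  expect_false(homref$missing)
  expect_equal(c(homref$allele1, homref$allele2), c("A", "A"))
  expect_equal(homref$rgq, 45)
  expect_true(is.na(homref$gq))
  expect_equal(homref$var_class, "SNV")

  ins <- calls[calls$id == "ins", ]
  expect_equal(ins$var_class, "INDEL")
  expect_equal(c(ins$allele1, ins$allele2), c("AG", "AG"))

  hap <- calls[calls$id == "haploid", ]
  expect_equal(c(hap$allele1, hap$allele2), c("T", "T"))
})

test_that("VCF reading validates the sample name", {
  path <- write_vcf_fixture(list(
    c("1", "100", ".", "A", "G", "10", "PASS", ".", "0/1:10:50:.")
  ))
  expect_error(read_wgs_vcf(path, "ghost"), "ghost")
  expect_no_error(read_wgs_vcf(path)) # single sample may be left implicit
})

test_that("final-report reading splits genotypes and flags no-calls", {
  path <- write_beadchip_fixture(list(
    bead_row("rs3832043", "2", "233671807", "I", "I", theta = 0.02,
             gc = 0.78),
    bead_row("rs0001", "1", "100", "-", "-"),
    bead_row("rs0002", "1", "200", "T", "C", theta = 0.48)
  ))
  recs <- read_beadchip_report(path)
  expect_equal(nrow(recs), 3) # row count preserved

  indel <- recs[recs$id == "rs3832043", ]
  expect_equal(c(indel$allele1, indel$allele2), c("I", "I"))
  expect_equal(indel$theta, 0.02)
  expect_equal(indel$gc_score, 0.78)

  expect_true(recs$missing[recs$id == "rs0001"])
  expect_false(recs$missing[recs$id == "rs0002"])
})

test_that("final-report reading reports absent mandatory columns by name", {
  cols <- setdiff(gtconcord:::BEADCHIP_COLUMNS, c("Theta", "GC Score"))
  path <- write_beadchip_fixture(
    list(c("rs1", "1", "100", "A", "A", "0.8", "0.9", "1.0", "0.9", "0.1",
           "0.02")),
    columns = cols
  )
  expect_error(read_beadchip_report(path), "GC Score.*Theta|Theta.*GC Score")
})

test_that("genotype class assignment follows A=ref, B/C=alts in order", {
  expect_equal(assign_genotype_class("G", "A", "A", "A"), "BB")
  expect_equal(assign_genotype_class("G", "A", "G", "G"), "AA")
  expect_equal(assign_genotype_class("G", c("A", "T"), "A", "T"), "BC")
  expect_equal(assign_genotype_class("G", c("A", "T"), "G", "T"), "AC")
  expect_equal(assign_genotype_class("G", "A", NA, NA), "MISSING")
  expect_error(assign_genotype_class("G", "A", "T", "T"), "allele")
})

test_that("harmonization pairs shared sites, assigns classes, drops no-calls", {
  vcf <- write_vcf_fixture(list(
    c("1", "109711919", "rs1633365", "T", "C", "612", "PASS", ".",
      "0/0:31:.:70"),
    c("1", "200", "same", "C", "T", "99", "PASS", ".", "0/0:30:.:50"),
    c("1", "300", "beadmissing", "A", "G", "99", "PASS", ".", "0/1:30:80:."),
    c("1", "400", "wgsonly", "A", "G", "99", "PASS", ".", "0/1:30:80:."),
    c("2", "100", "indel", "AG", "A", "700", "PASS", ".", "1/1:25:77:.")
  ))
  report <- write_beadchip_fixture(list(
    bead_row("rs1633365", "1", "109711919", "T", "C"),
    bead_row("same", "1", "200", "C", "C"),
    bead_row("beadmissing", "1", "300", "-", "-"),
    bead_row("beadonly", "1", "500", "A", "A"),
    bead_row("indel", "2", "100", "D", "D")
  ))
  paired <- harmonize_pair(read_wgs_vcf(vcf), read_beadchip_report(report))

  expect_equal(nrow(paired), 3)
  expect_true(all(paired$class_truth != "MISSING" &
                    paired$class_test != "MISSING"))
  rep <- attr(paired, "harmonize_report")
  expect_equal(unname(rep["n_missing_either"]), 1)
  expect_equal(unname(rep["n_wgs_only"]), 1)
  expect_equal(unname(rep["n_beadchip_only"]), 1)

  # BeadChip het vs WGS hom-ref: AB vs AA, discordant
  row <- paired[paired$id == "rs1633365", ]
  expect_equal(row$class_test, "AB")
  expect_equal(row$class_truth, "AA")
  expect_false(row$concordant)

  expect_true(paired$concordant[paired$id == "same"])

  # deletion site: bead DD maps to the shorter allele, hom-alt = BB
  ind <- paired[paired$id == "indel", ]
  expect_equal(ind$class_truth, "BB")
  expect_equal(ind$class_test, "BB")
  expect_equal(ind$test_gt, "DD")
  expect_true(ind$concordant)
})

test_that("strand flips reconcile via reverse complement; palindromic mismatches are excluded", {
  vcf <- write_vcf_fixture(list(
    c("1", "100", "flip1", "T", "C", "99", "PASS", ".", "0/1:30:80:."),
    c("1", "200", "flip2", "G", "T", "99", "PASS", ".", "0/0:30:.:50"),
    c("1", "300", "pal", "A", "T", "99", "PASS", ".", "0/1:30:80:."),
    c("1", "400", "bad", "C", "T", "99", "PASS", ".", "0/1:30:80:."),
    c("1", "500", "ok", "A", "C", "99", "PASS", ".", "0/1:30:80:.")
  ))
  report <- write_beadchip_fixture(list(
    bead_row("flip1", "1", "100", "A", "G"), # revcomp of T/C
    bead_row("flip2", "1", "200", "C", "C"), # revcomp of G/G
    bead_row("pal", "1", "300", "C", "G"),   # mismatch at an A/T site
    bead_row("bad", "1", "400", "C", "A"),   # no orientation matches
    bead_row("ok", "1", "500", "A", "C")
  ))
  paired <- harmonize_pair(read_wgs_vcf(vcf), read_beadchip_report(report))
  rep <- attr(paired, "harmonize_report")

  expect_setequal(paired$id, c("flip1", "flip2", "ok"))
  expect_equal(unname(rep["n_ambiguous_strand"]), 1)
  expect_equal(unname(rep["n_irreconcilable"]), 1)

  f1 <- paired[paired$id == "flip1", ]
  expect_setequal(c(f1$test_a1, f1$test_a2), c("T", "C"))
  expect_equal(f1$class_test, "AB")
  expect_equal(paired$class_test[paired$id == "flip2"], "AA")
})

test_that("reverse complement applied twice is the identity", {
  alleles <- c("A", "C", "G", "T", "AG", "GATTACA")
  expect_equal(gtconcord:::revcomp(gtconcord:::revcomp(alleles)), alleles)
})

test_that("pair membership is unchanged by the truth-role designation and by chromosome exclusion", {
  vcf <- write_vcf_fixture(list(
    c("1", "100", "a", "A", "G", "99", "PASS", ".", "0/1:30:80:."),
    c("2", "200", "b", "C", "T", "99", "PASS", ".", "1/1:30:80:."),
    c("X", "300", "x", "A", "C", "99", "PASS", ".", "0/1:30:80:.")
  ))
  report <- write_beadchip_fixture(list(
    bead_row("a", "1", "100", "A", "G"),
    bead_row("b", "2", "200", "T", "T"),
    bead_row("x", "X", "300", "A", "A")
  ))
  w <- read_wgs_vcf(vcf)
  b <- read_beadchip_report(report)
  p1 <- harmonize_pair(w, b, truth = "wgs")
  p2 <- harmonize_pair(w, b, truth = "beadchip")
  expect_equal(p1[, c("chrom", "pos")], p2[, c("chrom", "pos")])
  expect_equal(p1$class_truth, p2$class_test)
  expect_equal(p1$class_test, p2$class_truth)

  p3 <- harmonize_pair(w, b, exclude_chroms = c("X", "Y", "MT"))
  expect_false("X" %in% p3$chrom)
  expect_equal(nrow(p3), 2)
})
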