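# In-code fixtures: tiny VCFs and final reports written to tempfiles.

write_vcf_fixture <- function(rows, path = tempfile(fileext = ".vcf"),
                              sample = "S1", format = "GT:DP:GQ:RGQ") {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="GQ">',
    '##FORMAT=<ID=RGQ,Number=1,Type=Integer,Description="RGQ">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  writeLines(c(header, vapply(rows, function(r) {
    paste(c(r[1:8], format, r[9]), collapse = "\t")
  }, character(1))), path)
  path
}

write_beadchip_fixture <- function(rows, path = tempfile(fileext = ".txt"),
                                   columns = gtconcord:::BEADCHIP_COLUMNS) {
  header <- c("[Header]", "GSGT Version\t2.0.4", "Num SNPs\t0",
              "[Data]", paste(columns, collapse = "\t"))
  writeLines(c(header, vapply(rows, paste, character(1), collapse = "\t")),
             path)
  path
}

# one final-report row with sane default intensity values
bead_row <- function(id, chrom, pos, a1, a2, theta = 0.02, gc = 0.78) {
  c(id, chrom, pos, a1, a2, gc, "0.8", "0.9", theta, "1.0", "0.9", "0.1",
    "0.02")
}

# minimal paired-call tibble for discordance-mapping tests
paired_fixture <- function(chrom, pos, concordant,
                           var_class = rep("SNV", length(pos))) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos),
                 id = sprintf("m%03d", seq_along(pos)),
                 var_class = var_class, concordant = concordant)
}
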