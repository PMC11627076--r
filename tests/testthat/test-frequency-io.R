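# panel/VCF/TSV ingestion: allele counting, phased haplotype counting,
# greedy block detection, round-trips

test_that("read_panel validates and round-trips", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tpopulation", "s1\tPEL", "s2\tPEL"), tf)
  p <- read_panel(tf)
  expect_s3_class(p, "genodyn_panel")
  expect_equal(nrow(p), 2L)
  expect_equal(unique(p$population), "PEL")

  writeLines(c("sample\tpopulation", "s1\tPEL", "s1\tTSI"), tf)
  expect_error(read_panel(tf), "duplicate sample")
  writeLines(c("sample\tpopulation", "s1\t"), tf)
  expect_error(read_panel(tf), "empty population")

  # 10-population panel round-trip
  p10 <- population_panel(sprintf("s%02d", 1:30), rep(sprintf("P%02d", 1:10), 3))
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_panel(p10, tf2)
  expect_equal(as.data.frame(read_panel(tf2)), as.data.frame(p10))
})

test_that("frequencies_from_vcf counts alleles per population", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  panel <- population_panel(sprintf("s%d", 1:4), rep("PEL", 4))
  # all homozygous REF
  write_toy_vcf(tf, sprintf("s%d", 1:4), list(
    list(chrom = "3", pos = 100, id = "rs1", ref = "T", alt = "C",
         gts = rep("0|0", 4))))
  ft <- frequencies_from_vcf(tf, panel)
  expect_equal(ft[ft$allele == "T"]$freq, 1.0)
  expect_equal(ft[ft$allele == "C"]$freq, 0.0)

  # 0|1 and 1|1: 3 of 4 chromosomes carry ALT
  panel2 <- population_panel(c("a", "b"), c("PEL", "PEL"))
  write_toy_vcf(tf, c("a", "b"), list(
    list(chrom = "3", pos = 100, id = "rs1", ref = "T", alt = "C",
         gts = c("0|1", "1|1"))))
  ft2 <- frequencies_from_vcf(tf, panel2)
  expect_equal(ft2[ft2$allele == "C"]$freq, 0.75)

  # missing genotypes leave the denominator
  write_toy_vcf(tf, c("a", "b"), list(
    list(chrom = "3", pos = 100, id = "rs1", ref = "T", alt = "C",
         gts = c("0|1", "./."))))
  ft3 <- frequencies_from_vcf(tf, panel2)
  expect_equal(ft3[ft3$allele == "C"]$freq, 0.5)

  # sample not in the panel is a hard error
  expect_error(frequencies_from_vcf(tf, population_panel("a", "PEL")),
               "absent from panel")
})

test_that("multi-allelic and non-SNP records are skipped and counted", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  panel <- population_panel(c("a", "b"), c("PEL", "PEL"))
  write_toy_vcf(tf, c("a", "b"), list(
    list(chrom = "3", pos = 100, id = "rs1", ref = "T", alt = "C",
         gts = c("0|0", "0|1")),
    list(chrom = "3", pos = 200, id = "rs2", ref = "A", alt = "G,C",
         gts = c("0|1", "0|2")),
    list(chrom = "3", pos = 300, id = "rs3", ref = "AT", alt = "A",
         gts = c("0|0", "0|1"))))
  expect_message(ft <- frequencies_from_vcf(tf, panel), "skipped 2")
  expect_equal(unique(ft$snp_id), "rs1")
  expect_equal(attr(ft, "n_skipped_multiallelic"), 2L)
})

test_that("VCF round-trip recovers the generator's counted frequencies exactly", {
  fm <- matrix(c(0.5, 0.9, 0.12, 0.7, 0.44, 1.0), nrow = 3,
               dimnames = list(c("snpA", "snpB", "snpC"), c("P1", "P2")))
  ff <- multi_freqs(fm)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  pan <- withr::local_tempfile(fileext = ".tsv")
  counted <- gen_vcf_fixture(ff, n_per_pop = 20L, vcf, pan, seed = 5L)
  got <- frequencies_from_vcf(vcf, read_panel(pan))
  a <- as.data.frame(got)[, c("snp_id", "allele", "population", "freq")]
  b <- as.data.frame(counted)[, c("snp_id", "allele", "population", "freq")]
  a <- a[order(a$snp_id, a$population, a$allele), ]
  b <- b[order(b$snp_id, b$population, b$allele), ]
  expect_equal(a$freq, b$freq)  # integer arithmetic: exact
  # and within binomial sampling error of the generator parameters, 1/(2N)
  # per chromosome scale: |p_hat - p| <= ~4 sd
  m <- merge(as.data.frame(ff), b, by = c("snp_id", "allele", "population"))
  expect_true(all(abs(m$freq.x - m$freq.y) <=
                    4 * sqrt(pmax(m$freq.x * (1 - m$freq.x), 1e-4) / 40) + 1e-12))
})

test_that("haplotype_frequencies counts phased chromosome strings", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  panel <- population_panel(c("a", "b"), c("PEL", "PEL"))
  # 1-SNP block: haplotype frequencies equal allele frequencies
  write_toy_vcf(tf, c("a", "b"), list(
    list(chrom = "3", pos = 100, id = "rs1", ref = "T", alt = "C",
         gts = c("0|1", "1|1"))))
  rec <- haplotype_frequencies(tf, panel, "rs1", "PEL")
  expect_equal(rec$hap_freq, c(C = 0.75, T = 0.25))

  # 2 SNPs in perfect LD: chromosomes TA, TA, CG, CG
  write_toy_vcf(tf, c("a", "b"), list(
    list(chrom = "3", pos = 100, id = "rs1", ref = "T", alt = "C",
         gts = c("0|0", "1|1")),
    list(chrom = "3", pos = 200, id = "rs2", ref = "A", alt = "G",
         gts = c("0|0", "1|1"))))
  rec2 <- haplotype_frequencies(tf, panel, c("rs1", "rs2"), "PEL")
  expect_equal(rec2$hap_freq[order(names(rec2$hap_freq))],
               c(CG = 0.5, TA = 0.5))
  expect_equal(rec2$n_snps, 2L)

  # unphased genotype is a hard error
  write_toy_vcf(tf, c("a", "b"), list(
    list(chrom = "3", pos = 100, id = "rs1", ref = "T", alt = "C",
         gts = c("0/1", "1|1"))))
  expect_error(haplotype_frequencies(tf, panel, "rs1", "PEL"), "unphased")
})

test_that("sampled haploblock fixture round-trips through the VCF path exactly", {
  fx <- gen_haploblock_fixture(c("b1", "b2", "b3"), c(0.7, 0.6, 0.8), 0.9,
                               "PEL", n_chrom = 500L, seed = 9L)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(fx$vcf_lines, vcf)
  panel <- population_panel(fx$sample_ids, rep("PEL", length(fx$sample_ids)))
  rec <- haplotype_frequencies(vcf, panel, c("b1", "b2", "b3"), "PEL")
  a <- rec$hap_freq[order(names(rec$hap_freq))]
  b <- fx$sampled_record$hap_freq[order(names(fx$sampled_record$hap_freq))]
  expect_equal(a, b)  # multinomial draw recovered exactly
  # counted frequencies approach the theoretical distribution at n = 500
  th <- fx$record$hap_freq[names(b)]
  expect_true(all(abs(b - th) <= 4 * sqrt(th * (1 - th) / 500) + 1e-12))
})

test_that("detect_blocks: greedy r^2 adjacency", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  set.seed(31)
  n <- 60L  # diploid samples
  panel <- population_panel(sprintf("s%03d", 1:n), rep("P1", n))

  # two independent SNPs: no blocks
  g1 <- rbinom(2 * n, 1, 0.5); g2 <- rbinom(2 * n, 1, 0.5)
  as_gt <- function(g) paste0(g[c(TRUE, FALSE)], "|", g[c(FALSE, TRUE)])
  write_toy_vcf(vcf, panel$sample, list(
    list(chrom = "3", pos = 100, id = "i1", ref = "T", alt = "C", gts = as_gt(g1)),
    list(chrom = "3", pos = 200, id = "i2", ref = "T", alt = "C", gts = as_gt(g2))))
  expect_length(detect_blocks(vcf, panel), 0L)

  # two perfectly linked SNPs: one block of 2
  write_toy_vcf(vcf, panel$sample, list(
    list(chrom = "3", pos = 100, id = "l1", ref = "T", alt = "C", gts = as_gt(g1)),
    list(chrom = "3", pos = 200, id = "l2", ref = "A", alt = "G", gts = as_gt(g1))))
  blks <- detect_blocks(vcf, panel)
  expect_length(blks, 1L)
  expect_equal(blks[[1L]]$snp_ids, c("l1", "l2"))

  # implanted 3-SNP block at high LD among independent SNPs is recovered
  fx <- gen_haploblock_fixture(c("b1", "b2", "b3"), c(0.6, 0.6, 0.6), 0.95,
                               "P1", n_chrom = 2L * n, seed = 13L,
                               pos_start = 300L)
  recs <- list(
    list(chrom = "3", pos = 100, id = "i1", ref = "T", alt = "C", gts = as_gt(g1)),
    list(chrom = "3", pos = 200, id = "i2", ref = "T", alt = "C", gts = as_gt(g2)))
  # re-use the fixture's VCF body lines for the block SNPs
  body <- fx$vcf_lines[-(1:3)]
  hdr_lines <- fx$vcf_lines[1:3]
  # fixture samples must match the panel: rebuild with panel sample names
  stopifnot(length(fx$sample_ids) == n)
  hdr_lines[3] <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                          "FILTER", "INFO", "FORMAT", panel$sample),
                        collapse = "\t")
  extra <- vapply(recs, function(r)
    paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", "PASS", ".", "GT", r$gts),
          collapse = "\t"), character(1))
  writeLines(c(hdr_lines, extra, body), vcf)
  blks2 <- detect_blocks(vcf, panel, r2_threshold = 0.8)
  expect_length(blks2, 1L)
  expect_equal(blks2[[1L]]$snp_ids, c("b1", "b2", "b3"))
})

test_that("frequency/block/env tables round-trip through TSV", {
  fm <- matrix(c(0.5, 0.9, 0.3, 0.7), 2,
               dimnames = list(c("s1", "s2"), c("P1", "P2")))
  ff <- multi_freqs(fm)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_freq_table(ff, tf)
  expect_equal(as.data.frame(read_freq_table(tf)), as.data.frame(ff))

  blks <- list(gen_haploblock_fixture(c("s1", "s2"), c(0.5, 0.7), 0.8, "P1")$record)
  tb <- withr::local_tempfile(fileext = ".tsv")
  write_blocks(blks, tb)
  back <- read_blocks(tb)
  expect_length(back, 1L)
  expect_equal(back[[1L]]$snp_ids, blks[[1L]]$snp_ids)
  expect_equal(sort(names(back[[1L]]$hap_freq)), sort(names(blks[[1L]]$hap_freq)))
  expect_equal(back[[1L]]$hap_freq[names(blks[[1L]]$hap_freq)],
               blks[[1L]]$hap_freq, tolerance = 1e-12)

  ev <- env_table(data.frame(parameter = "richness", population = c("P1", "P2"),
                             value = c(2, 10)))
  te <- withr::local_tempfile(fileext = ".tsv")
  write_env_table(ev, te)
  expect_equal(as.data.frame(read_env_table(te)), as.data.frame(ev))

  # malformed tables are rejected
  expect_error(freq_table(data.frame(snp_id = "s", chrom = "3", pos = 1,
                                     allele = "T", population = "P",
                                     freq = 0.5)),
               "exactly 2")
  expect_error(freq_table(data.frame(snp_id = "s", chrom = "3", pos = 1,
                                     allele = c("T", "C"), population = "P",
                                     freq = c(0.6, 0.6))),
               "sum to")
})
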