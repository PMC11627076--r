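# shared fixture builders; everything is generated in code at test time

## tiny long-format frequency table: freq_by_pop is a named list
## population -> target-allele ("T") frequency
tiny_freqs <- function(snp_id = "rs1", freq_by_pop = list(PEL = 0.7, TSI = 0.5),
                       alleles = c("T", "C"), chrom = "3", pos = 100L) {
  pops <- names(freq_by_pop)
  f <- unlist(freq_by_pop)
  freq_table(data.frame(
    snp_id = snp_id, chrom = chrom, pos = pos,
    allele = rep(alleles, each = length(pops)),
    population = rep(pops, 2L), freq = c(f, 1 - f)))
}

## stack several tiny_freqs for multiple SNPs with shared populations
multi_freqs <- function(freq_mat, alleles = c("T", "C")) {
  # freq_mat: matrix, rows = SNPs (rownames = ids), cols = populations
  parts <- lapply(seq_len(nrow(freq_mat)), function(i) {
    as.data.frame(tiny_freqs(rownames(freq_mat)[i],
                             setNames(as.list(freq_mat[i, ]), colnames(freq_mat)),
                             alleles, pos = 100L + 10L * i))
  })
  freq_table(do.call(rbind, parts))
}

## write a minimal phased VCF from explicit GT rows
write_toy_vcf <- function(path, samples, records) {
  # records: list of list(chrom, pos, id, ref, alt, gts)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- vapply(records, function(r)
    paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", "PASS", ".", "GT", r$gts),
          collapse = "\t"), character(1))
  writeLines(c(hdr, rows), path)
  path
}

## exhaustive joint-entropy oracle: full product distribution over unlinked
## SNPs and block haplotype distributions, enumerated outright
joint_entropy_oracle <- function(freqs, blocks, population) {
  ft <- as.data.frame(freqs)
  sub <- ft[ft$population == population, , drop = FALSE]
  blocks <- Filter(function(b) b$population == population, blocks)
  block_snps <- unlist(lapply(blocks, `[[`, "snp_ids"))
  p <- 1
  for (sid in setdiff(unique(sub$snp_id), block_snps)) {
    p <- as.vector(outer(p, sub$freq[sub$snp_id == sid]))
  }
  for (b in blocks) p <- as.vector(outer(p, unname(b$hap_freq)))
  pp <- p[p > 0]
  -sum(pp * log2(pp))
}

## normal-equations least-squares oracle (independent of the package's QR
## fitting route)
normal_eq_oracle <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  r <- y - X %*% beta
  list(beta = as.numeric(beta), rms = sqrt(mean(r^2)))
}

## random valid haploblock for property tests (uses plain RNG; caller seeds)
random_block <- function(max_snps = 5L) {
  n <- sample(2:max_snps, 1L)
  p <- runif(n, 0.05, 0.95)
  w <- runif(1)
  gen_haploblock_fixture(sprintf("s%d", seq_len(n)), p, w,
                         "POP", block_id = "rb")$record
}
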