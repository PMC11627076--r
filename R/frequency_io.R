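# Ingestion of genotype/frequency/panel/block/environment files and the
# phased-VCF operations: per-population allele frequencies, haplotype
# counting, and greedy r^2 block detection.

#' Read a sample-to-population panel
#'
#' @param path TSV with header columns `sample`, `population`.
#' @return A [population_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) gd_input_error("panel file not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  if (!all(c("sample", "population") %in% names(dt))) {
    gd_input_error("panel file must have columns sample, population: ", path)
  }
  population_panel(dt$sample, dt$population)
}

#' Write a panel to TSV
#' @param panel a [population_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  fwrite(as.data.frame(panel), path, sep = "\t")
  invisible(path)
}

## Load a VCF into plain structures; the only VCF parser used is
## VariantAnnotation::readVcf.  Non-bi-allelic-SNP records are masked here
## and skipped (with a count) by the callers.
load_vcf <- function(path) {
  if (!file.exists(path)) gd_input_error("VCF not found: ", path)
  v <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(v)
  alt <- VariantAnnotation::alt(v)
  n_alt <- S4Vectors::elementNROWS(alt)
  ref <- as.character(VariantAnnotation::ref(v))
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt >= 1L] <- vapply(as.list(alt[n_alt >= 1L]),
                              function(x) as.character(x)[1L], character(1))
  snp_ok <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L
  gt <- VariantAnnotation::geno(v)$GT
  if (is.null(gt)) gd_input_error("VCF has no GT field: ", path)
  list(snp_id = rownames(v),
       chrom = as.character(GenomeInfoDb::seqnames(rr)),
       pos = BiocGenerics::start(rr),
       ref = ref, alt = alt1,
       gt = gt,
       biallelic_snp = snp_ok)
}

## split diploid GT strings into a 2-row allele-index matrix (NA = missing)
split_gt <- function(gts) {
  parts <- strsplit(gts, "[|/]")
  bad <- lengths(parts) != 2L
  a <- suppressWarnings(vapply(parts, function(x)
    as.integer(c(x, NA, NA)[1:2]), integer(2)))
  a[, bad] <- NA_integer_
  a
}

#' Per-population allele frequencies from a VCF
#'
#' Counts alleles over diploid genotypes per population.  Missing genotypes
#' are excluded from numerator and denominator; counting is integer
#' arithmetic, divided once at the end.  Records that are not bi-allelic
#' SNPs are skipped, counted and logged.  Phasing is not required here.
#'
#' @param vcf path to a VCF (v4.x) with a GT FORMAT field.
#' @param panel a [population_panel()]; every VCF sample must be in it.
#' @return A [freq_table()] with attribute `n_skipped_multiallelic`.
#' @export
frequencies_from_vcf <- function(vcf, panel) {
  vv <- load_vcf(vcf)
  samples <- colnames(vv$gt)
  unknown <- setdiff(samples, panel$sample)
  if (length(unknown)) {
    gd_input_error("VCF sample '", unknown[1L], "' absent from panel")
  }
  pop_of <- setNames(panel$population, panel$sample)[samples]
  n_skip <- sum(!vv$biallelic_snp)
  if (n_skip > 0) {
    gd_log("freqs", sprintf("skipped %d non-bi-allelic-SNP record(s)", n_skip))
  }
  keep <- which(vv$biallelic_snp)
  pops <- sort(unique(pop_of))
  rows <- vector("list", length(keep) * length(pops) * 2L)
  k <- 0L
  for (i in keep) {
    al <- split_gt(vv$gt[i, ])
    for (pp in pops) {
      sel <- al[, pop_of == pp, drop = FALSE]
      n_alt <- sum(sel == 1L, na.rm = TRUE)
      n_tot <- sum(!is.na(sel))
      if (n_tot == 0L) {
        gd_input_error("no called genotypes for SNP '", vv$snp_id[i],
                       "' in population ", pp)
      }
      f_alt <- n_alt / n_tot
      k <- k + 1L
      rows[[k]] <- data.table(snp_id = vv$snp_id[i], chrom = vv$chrom[i],
                              pos = vv$pos[i],
                              allele = c(vv$ref[i], vv$alt[i]),
                              population = pp,
                              freq = c(1 - f_alt, f_alt))
    }
  }
  out <- freq_table(rbindlist(rows[seq_len(k)]))
  attr(out, "n_skipped_multiallelic") <- n_skip
  out
}

## phased chromosome allele-index matrix (2N columns) for one population;
## hard error on unphased or missing genotypes
phased_matrix <- function(vv, rows_idx, samples) {
  gts <- vv$gt[rows_idx, samples, drop = FALSE]
  unphased <- grepl("/", gts, fixed = TRUE) | grepl(".", gts, fixed = TRUE)
  if (any(unphased)) {
    w <- which(unphased)[1L] - 1L
    gd_input_error("unphased or missing genotype for SNP '",
                   vv$snp_id[rows_idx][w %% length(rows_idx) + 1L],
                   "', sample '", samples[w %/% length(rows_idx) + 1L], "'")
  }
  ## rows = SNPs, columns = chromosomes (two per sample)
  m <- matrix(NA_integer_, nrow = length(rows_idx), ncol = 2L * length(samples))
  for (j in seq_along(samples)) {
    a <- split_gt(gts[, j])
    m[, 2L * j - 1L] <- a[1L, ]
    m[, 2L * j]      <- a[2L, ]
  }
  m
}

#' Haplotype frequencies of a SNP set by phased counting
#'
#' Counts chromosome strings over the member SNPs directly from phased
#' genotypes (no statistical phasing).  Haplotype strings use the allele
#' bases (REF/ALT characters) in `snp_ids` order.
#'
#' @param vcf path to a phased VCF.
#' @param panel a [population_panel()].
#' @param snp_ids ordered member SNP ids (must be VCF ID values).
#' @param population population code to count within.
#' @param block_id identifier for the resulting block (default derived from
#'   population and first SNP).
#' @return A [haploblock_record()].
#' @export
haplotype_frequencies <- function(vcf, panel, snp_ids, population,
                                  block_id = NULL) {
  vv <- if (is.list(vcf) && !is.null(vcf$gt)) vcf else load_vcf(vcf)
  idx <- match(snp_ids, vv$snp_id)
  if (anyNA(idx)) {
    gd_input_error("SNP '", snp_ids[which(is.na(idx))[1L]], "' not in VCF")
  }
  if (!all(vv$biallelic_snp[idx])) {
    gd_input_error("block member '", snp_ids[which(!vv$biallelic_snp[idx])[1L]],
                   "' is not a bi-allelic SNP")
  }
  samples <- intersect(colnames(vv$gt), panel$sample[panel$population == population])
  if (!length(samples)) gd_input_error("no samples for population ", population)
  m <- phased_matrix(vv, idx, samples)
  base <- function(i, a) ifelse(a == 0L, vv$ref[idx[i]], vv$alt[idx[i]])
  hap <- apply(m, 2, function(col) {
    paste0(vapply(seq_along(col), function(i) base(i, col[i]), character(1)),
           collapse = "")
  })
  counts <- table(hap)
  if (is.null(block_id)) block_id <- paste0(population, "_", snp_ids[1L])
  haploblock_record(block_id, population, snp_ids,
                    setNames(as.numeric(counts) / sum(counts), names(counts)))
}

#' Greedy adjacency haploblock detection
#'
#' Left-to-right over position-sorted SNPs within each chromosome and
#' population: a SNP joins the current block while its pairwise r^2 with the
#' previous SNP is at least the threshold.  Deliberately simple; externally
#' supplied block definitions always take precedence in the pipeline.
#'
#' @param vcf path to a phased VCF.
#' @param panel a [population_panel()].
#' @param r2_threshold r^2 join threshold (default 0.8).
#' @return List of [haploblock_record()]s (size >= 2 only; possibly empty).
#' @export
detect_blocks <- function(vcf, panel, r2_threshold = 0.8) {
  vv <- load_vcf(vcf)
  keep <- which(vv$biallelic_snp)
  ord <- keep[order(vv$chrom[keep], vv$pos[keep])]
  out <- list()
  for (pp in sort(unique(panel$population))) {
    samples <- intersect(colnames(vv$gt), panel$sample[panel$population == pp])
    if (!length(samples)) next
    m <- phased_matrix(vv, ord, samples)
    runs <- list(); cur <- 1L
    for (i in seq_along(ord)[-1L]) {
      same_chrom <- vv$chrom[ord[i]] == vv$chrom[ord[i - 1L]]
      r2 <- if (!same_chrom) 0 else {
        x <- m[i - 1L, ]; y <- m[i, ]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) 0 else stats::cor(x, y)^2
      }
      if (r2 >= r2_threshold) cur <- c(cur, i)
      else { runs[[length(runs) + 1L]] <- cur; cur <- i }
    }
    runs[[length(runs) + 1L]] <- cur
    bi <- 0L
    for (r in runs) {
      if (length(r) < 2L) next
      bi <- bi + 1L
      out[[length(out) + 1L]] <- haplotype_frequencies(
        vv, panel, vv$snp_id[ord[r]], pp,
        block_id = sprintf("%s_blk%d", pp, bi))
    }
  }
  out
}

# ---------------------------------------------------------------------------
# TSV formats

#' Read / write allele-frequency tables
#'
#' TSV columns: `snp_id`, `chrom`, `pos`, `allele`, `population`, `freq`.
#' @param path file path.
#' @return [freq_table()] for the reader; `path` invisibly for the writer.
#' @export
read_freq_table <- function(path) {
  if (!file.exists(path)) gd_input_error("frequency table not found: ", path)
  freq_table(fread(path, sep = "\t", header = TRUE))
}

#' @rdname read_freq_table
#' @param freqs a [freq_table()].
#' @export
write_freq_table <- function(freqs, path) {
  fwrite(as.data.frame(freqs), path, sep = "\t")
  invisible(path)
}

#' Read / write haploblock definitions
#'
#' TSV columns: `block_id`, `population`, `snp_ids` (comma-separated), and —
#' when haplotype distributions are carried — `haplotypes` and `hap_freqs`
#' (comma-separated, parallel).  Without the haplotype columns the file is a
#' bare block specification and frequencies must be counted from a phased
#' VCF via [haplotype_frequencies()].
#'
#' @param path file path.
#' @return List of [haploblock_record()]s, or (bare specification) a
#'   data.table with a `snp_ids` list-column.
#' @export
read_blocks <- function(path) {
  if (!file.exists(path)) gd_input_error("block file not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  if (!all(c("block_id", "population", "snp_ids") %in% names(dt))) {
    gd_input_error("block file must have columns block_id, population, snp_ids: ", path)
  }
  split_csv <- function(x) strsplit(x, ",", fixed = TRUE)
  if (all(c("haplotypes", "hap_freqs") %in% names(dt))) {
    lapply(seq_len(nrow(dt)), function(i) {
      haploblock_record(dt$block_id[i], dt$population[i],
                        split_csv(dt$snp_ids[i])[[1L]],
                        setNames(as.numeric(split_csv(dt$hap_freqs[i])[[1L]]),
                                 split_csv(dt$haplotypes[i])[[1L]]))
    })
  } else {
    dt2 <- dt[, c("block_id", "population", "snp_ids"), with = FALSE]
    dt2$snp_ids <- split_csv(dt2$snp_ids)
    dt2
  }
}

#' @rdname read_blocks
#' @param blocks list of [haploblock_record()]s.
#' @export
write_blocks <- function(blocks, path) {
  if (length(blocks) == 0L) {
    writeLines("block_id\tpopulation\tsnp_ids\thaplotypes\thap_freqs", path)
    return(invisible(path))
  }
  dt <- rbindlist(lapply(blocks, function(b) data.table(
    block_id = b$block_id, population = b$population,
    snp_ids = paste(b$snp_ids, collapse = ","),
    haplotypes = paste(names(b$hap_freq), collapse = ","),
    hap_freqs = paste(format(unname(b$hap_freq), digits = 17, trim = TRUE,
                             scientific = FALSE), collapse = ","))))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read / write environment tables
#'
#' TSV columns: `parameter`, `population`, `value`.
#' @param path file path.
#' @return [env_table()] for the reader.
#' @export
read_env_table <- function(path) {
  if (!file.exists(path)) gd_input_error("environment table not found: ", path)
  env_table(fread(path, sep = "\t", header = TRUE))
}

#' @rdname read_env_table
#' @param env an [env_table()].
#' @export
write_env_table <- function(env, path) {
  fwrite(as.data.frame(env), path, sep = "\t")
  invisible(path)
}

#' Read / write per-population environmental potentials
#'
#' TSV columns: `population`, `t_env` (GEU).
#' @param path file path.
#' @return data.table with columns `population`, `t_env`.
#' @export
read_tenv <- function(path) {
  if (!file.exists(path)) gd_input_error("T_E table not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE)
  if (!all(c("population", "t_env") %in% names(dt))) {
    gd_input_error("T_E table must have columns population, t_env: ", path)
  }
  if (any(dt$t_env < 1)) gd_input_error("T_E table: T_E below 1 GEU")
  dt[, .(population = as.character(population), t_env = as.numeric(t_env))]
}

#' @rdname read_tenv
#' @param tenv data.frame with columns `population`, `t_env`.
#' @export
write_tenv <- function(tenv, path) {
  fwrite(as.data.frame(tenv)[, c("population", "t_env")], path, sep = "\t")
  invisible(path)
}

#' Write / read a potential table
#'
#' TSV serialization of the table built by [compute_potentials()]; absent
#' alleles serialize their potential as `Inf`.
#' @param path file path.
#' @return the potentials table for the reader.
#' @export
read_potentials <- function(path) {
  if (!file.exists(path)) gd_input_error("potential table not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE)
  structure(dt, class = c("genodyn_potentials", class(data.table::data.table())))
}

#' @rdname read_potentials
#' @param potentials a `genodyn_potentials` table.
#' @export
write_potentials <- function(potentials, path) {
  fwrite(as.data.frame(potentials), path, sep = "\t")
  invisible(path)
}
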