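# Domain containers.  All are thin S3 classes over data.frame/list so they
# print naturally and round-trip through TSV without loss.

#' Construct a population panel
#'
#' A panel maps each sample to exactly one population.
#'
#' @param sample character vector of sample identifiers.
#' @param population character vector of population codes (e.g. "PEL", "TSI").
#' @return A `genodyn_panel` data.frame with columns `sample`, `population`.
#' @examples
#' population_panel(c("s1", "s2"), c("PEL", "PEL"))
#' @export
population_panel <- function(sample, population) {
  sample <- as.character(sample)
  population <- as.character(population)
  if (length(sample) != length(population)) {
    gd_input_error("panel: sample and population lengths differ")
  }
  if (length(sample) == 0L) gd_input_error("panel: no samples")
  dup <- unique(sample[duplicated(sample)])
  if (length(dup)) {
    gd_input_error("panel: duplicate sample '", dup[1L], "'")
  }
  if (any(!nzchar(population) | is.na(population))) {
    gd_input_error("panel: empty population code for sample '",
                   sample[which(!nzchar(population) | is.na(population))[1L]], "'")
  }
  structure(data.frame(sample = sample, population = population,
                       stringsAsFactors = FALSE),
            class = c("genodyn_panel", "data.frame"))
}

#' Construct/validate an allele-frequency table
#'
#' Long format: one row per SNP x population x allele.  For every SNP and
#' population the table must hold exactly two alleles whose frequencies sum
#' to 1 (bi-allelic sites only); monomorphic sites keep both allele rows,
#' one with frequency 0.
#'
#' @param df data.frame with columns `snp_id`, `chrom`, `pos`, `allele`,
#'   `population`, `freq`.
#' @return A validated `genodyn_freqs` data.table.
#' @export
freq_table <- function(df) {
  dt <- as.data.table(df)
  need <- c("snp_id", "chrom", "pos", "allele", "population", "freq")
  miss <- setdiff(need, names(dt))
  if (length(miss)) gd_input_error("frequency table missing columns: ",
                                   paste(miss, collapse = ", "))
  dt <- dt[, need, with = FALSE]
  dt[, `:=`(snp_id = as.character(snp_id), chrom = as.character(chrom),
            pos = as.integer(pos), allele = as.character(allele),
            population = as.character(population), freq = as.numeric(freq))]
  if (any(dt$freq < -1e-12 | dt$freq > 1 + 1e-12)) {
    gd_input_error("frequency table: freq outside [0, 1]")
  }
  dt[, freq := pmin(pmax(freq, 0), 1)]
  chk <- dt[, .(n = .N, s = sum(freq)), by = .(snp_id, population)]
  bad <- chk[n != 2L]
  if (nrow(bad)) {
    gd_input_error("frequency table: SNP '", bad$snp_id[1L], "' in population '",
                   bad$population[1L], "' has ", bad$n[1L],
                   " allele rows (bi-allelic tables need exactly 2)")
  }
  badsum <- chk[abs(s - 1) > 1e-9]
  if (nrow(badsum)) {
    gd_input_error("frequency table: frequencies of SNP '", badsum$snp_id[1L],
                   "' in population '", badsum$population[1L],
                   "' sum to ", format(badsum$s[1L], digits = 15))
  }
  data.table::setkey(dt, snp_id, population, allele)
  structure(dt, class = c("genodyn_freqs", class(data.table::data.table())))
}

#' Major/minor allele labels per SNP
#'
#' The major allele is the one with the larger mean frequency across
#' populations (alphabetical tie-break, so the labelling is deterministic).
#'
#' @param freqs a `genodyn_freqs` table.
#' @return data.table with columns `snp_id`, `allele_major`, `allele_minor`.
#' @export
snp_alleles <- function(freqs) {
  mean_f <- NULL
  m <- as.data.table(freqs)[, .(mean_f = mean(freq)), by = .(snp_id, allele)]
  data.table::setorder(m, snp_id, -mean_f, allele)
  m[, .(allele_major = allele[1L], allele_minor = allele[2L]), by = snp_id]
}

#' Construct a haploblock record
#'
#' Holds the member SNPs of one block in one population together with its
#' haplotype frequency distribution.  Haplotype strings concatenate one
#' allele character per member SNP, in `snp_ids` order.
#'
#' @param block_id block identifier.
#' @param population population code.
#' @param snp_ids ordered character vector of member SNP ids.
#' @param hap_freq named numeric vector: names are haplotype strings, values
#'   frequencies summing to 1.
#' @return A `genodyn_block` list.
#' @export
haploblock_record <- function(block_id, population, snp_ids, hap_freq) {
  snp_ids <- as.character(snp_ids)
  n <- length(snp_ids)
  if (n < 1L) gd_input_error("haploblock '", block_id, "': no member SNPs")
  if (is.null(names(hap_freq)) || any(!nzchar(names(hap_freq)))) {
    gd_input_error("haploblock '", block_id, "': haplotype frequencies must be named")
  }
  if (any(nchar(names(hap_freq)) != n)) {
    gd_input_error("haploblock '", block_id, "': haplotype string length != ", n)
  }
  check_prob_vector(unname(hap_freq),
                    what = paste0("haploblock '", block_id, "' haplotype frequencies"))
  structure(list(block_id = as.character(block_id),
                 population = as.character(population),
                 snp_ids = snp_ids,
                 hap_freq = hap_freq,
                 n_snps = n),
            class = "genodyn_block")
}

#' @export
print.genodyn_block <- function(x, ...) {
  cat(sprintf("<haploblock %s | %s | %d SNPs, %d haplotypes>\n",
              x$block_id, x$population, x$n_snps, length(x$hap_freq)))
  invisible(x)
}

#' Marginal allele frequencies of a haploblock
#'
#' Marginalizes the haplotype distribution over all but one member SNP.
#'
#' @param block a `genodyn_block`.
#' @return A list (one element per member SNP, in order) of named numeric
#'   vectors of allele frequencies.
#' @export
block_marginals <- function(block) {
  haps <- names(block$hap_freq)
  lapply(seq_len(block$n_snps), function(i) {
    a <- substr(haps, i, i)
    tapply(unname(block$hap_freq), a, sum)
  })
}

## verify block marginals against the allele-frequency table (1e-9)
check_block_marginals <- function(block, freqs, tol = 1e-9) {
  marg <- block_marginals(block)
  ft <- as.data.table(freqs)
  for (i in seq_along(block$snp_ids)) {
    sid <- block$snp_ids[i]
    rows <- ft[snp_id == sid & population == block$population]
    if (nrow(rows) == 0L) {
      gd_input_error("haploblock '", block$block_id, "': member SNP '", sid,
                     "' absent from frequency table for population ",
                     block$population)
    }
    tab <- setNames(rows$freq, rows$allele)
    m <- marg[[i]]
    for (al in names(tab)) {
      mf <- if (al %in% names(m)) m[[al]] else 0
      if (abs(mf - tab[[al]]) > tol) {
        gd_input_error("haploblock '", block$block_id, "': haplotype marginal of SNP '",
                       sid, "' allele ", al, " (", format(mf, digits = 12),
                       ") disagrees with frequency table (",
                       format(tab[[al]], digits = 12), ")")
      }
    }
  }
  invisible(TRUE)
}

#' Construct/validate an environment table
#'
#' One scalar environmental value per population per parameter, e.g. the
#' richness (species count) of zoonotic viruses in a population's region.
#'
#' @param df data.frame with columns `parameter`, `population`, `value`.
#' @return A `genodyn_env` data.table.
#' @export
env_table <- function(df) {
  dt <- as.data.table(df)
  need <- c("parameter", "population", "value")
  miss <- setdiff(need, names(dt))
  if (length(miss)) gd_input_error("environment table missing columns: ",
                                   paste(miss, collapse = ", "))
  dt <- dt[, need, with = FALSE]
  dt[, `:=`(parameter = as.character(parameter),
            population = as.character(population), value = as.numeric(value))]
  if (anyNA(dt$value)) gd_input_error("environment table: missing values")
  dup <- dt[, .N, by = .(parameter, population)][N > 1L]
  if (nrow(dup)) {
    gd_input_error("environment table: duplicate entry for parameter '",
                   dup$parameter[1L], "', population '", dup$population[1L], "'")
  }
  structure(dt, class = c("genodyn_env", class(data.table::data.table())))
}
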