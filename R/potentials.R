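# The potential algebra: entropies, NIC, environmental potential T_E,
# allelic/SNP potentials, haplotype/haploblock potentials, and the
# distribution of block potentials back onto member SNPs.
#
# Conventions used throughout:
#   * entropies are in bits (log base 2);
#   * the genomic energy unit (GEU) is fixed by mu-check = 1, the potential
#     of a non-linked bi-allelic SNP of maximal variation (p = 0.5);
#   * an absent allele (p = 0) has potential +Inf and contributes 0 to any
#     frequency-weighted average (the 0 * log 0 := 0 limit).

#' Shannon entropy of a probability vector (bits)
#'
#' @param p numeric probability vector; entries in \[0, 1\] summing to 1
#'   (within 1e-9).
#' @return Entropy in bits, in \[0, log2(length(p))\].
#' @examples
#' shannon_entropy(c(0.5, 0.5)) # 1 bit
#' @export
shannon_entropy <- function(p) {
  p <- check_prob_vector(p, what = "probability vector")
  pp <- p[p > 0]
  max(-sum(pp * log2(pp)), 0)
}

#' Normalized information content
#'
#' `NIC = (s_max - s_genome) / s_max`: the degree of maintained order of a
#' population's genome, 1 for a fully ordered genome and 0 at maximal
#' variation.
#'
#' @param s_genome genome entropy in bits.
#' @param s_max entropy of maximal variation in bits (the number of
#'   bi-allelic SNPs).
#' @return NIC in \[0, 1\].
#' @export
nic <- function(s_genome, s_max) {
  if (!is.numeric(s_genome) || !is.numeric(s_max)) gd_input_error("nic: numeric inputs required")
  if (s_max <= 0) gd_input_error("nic: s_max must be > 0")
  if (s_genome < 0) gd_input_error("nic: s_genome must be >= 0")
  if (s_genome > s_max * (1 + 1e-12)) {
    gd_input_error("nic: s_genome (", s_genome, ") exceeds s_max (", s_max, ")")
  }
  (s_max - s_genome) / s_max
}

#' Environmental potential T_E
#'
#' `T_E = mu-check / NIC` in GEU: a temperature-like measure of a
#' population's intrinsic genomic disorder.  Populations with more disorder
#' (lower NIC) have higher T_E.
#'
#' @param nic_value NIC in (0, 1\].
#' @return T_E in GEU (>= 1).
#' @export
environmental_potential <- function(nic_value) {
  if (!is.numeric(nic_value) || anyNA(nic_value)) gd_input_error("environmental_potential: numeric NIC required")
  if (any(nic_value <= 0)) gd_input_error("environmental_potential: NIC = 0 (infinite disorder)")
  if (any(nic_value > 1 + 1e-12)) gd_input_error("environmental_potential: NIC > 1")
  MU_CHECK / nic_value
}

#' Allelic potential
#'
#' `mu_a = mu-check - T_E - T_E * log2(p)` in GEU.  At p = 0.5 the potential
#' is exactly 1 GEU for any T_E (the unit's definition); at p = 1 it equals
#' the fixing potential `mu-check - T_E`; at p = 0 the allele is absent and
#' the potential is the +Inf sentinel.
#'
#' @param p allele frequency (vectorized), in \[0, 1\].
#' @param t_env environmental potential T_E in GEU.
#' @return Potential(s) in GEU; `+Inf` for p = 0.
#' @export
allelic_potential <- function(p, t_env) {
  if (!is.numeric(p) || anyNA(p)) gd_input_error("allelic_potential: numeric p required")
  if (any(p < 0 | p > 1)) gd_input_error("allelic_potential: p outside [0, 1]")
  out <- MU_CHECK - t_env - t_env * log2(p)
  out[p == 0] <- Inf
  out
}

#' Fixing potential
#'
#' Potential of an allele fixed in the population (p = 1): `mu-check - T_E`.
#'
#' @param t_env environmental potential in GEU.
#' @return Fixing potential in GEU (<= 0 since T_E >= 1).
#' @export
fixing_potential <- function(t_env) MU_CHECK - t_env

#' SNP potential
#'
#' The frequency-weighted mean of a SNP's allelic potentials,
#' `mu_S = sum_a p_a mu_a = mu-check - T_E + T_E * s`, where s is the SNP's
#' allele entropy.  Its maximum, 1 GEU, is attained only at p = 0.5.
#'
#' @param freqs allele-frequency vector (length 2 for bi-allelic sites).
#' @param t_env environmental potential in GEU.
#' @return SNP potential in GEU.
#' @export
snp_potential <- function(freqs, t_env) {
  check_prob_vector(freqs, what = "allele frequencies")
  MU_CHECK - t_env + t_env * shannon_entropy(freqs)
}

#' Haplotype potential
#'
#' For a haplotype of frequency `p_h` spanning `n_snps` linked SNPs:
#' `mu_h = n_snps * (mu-check - T_E) - T_E * log2(p_h)`.  The baseline
#' `n_snps * (mu-check - T_E)` makes a fully fixed block carry exactly
#' `n_snps` fixing potentials, which keeps the block-distribution rules
#' mutually consistent (see the methods vignette).
#'
#' @param p_h haplotype frequency in (0, 1\] (vectorized); p_h = 0 yields +Inf.
#' @param n_snps number of member SNPs.
#' @param t_env environmental potential in GEU.
#' @return Potential(s) in GEU.
#' @export
haplotype_potential <- function(p_h, n_snps, t_env) {
  if (any(p_h < 0 | p_h > 1)) gd_input_error("haplotype_potential: p_h outside [0, 1]")
  out <- n_snps * (MU_CHECK - t_env) - t_env * log2(p_h)
  out[p_h == 0] <- Inf
  out
}

#' Haploblock potential
#'
#' The population average of the haplotype potentials,
#' `<mu_H> = sum_h p_h mu_h = n_snps * mu_fixed + T_E * s_H`,
#' where s_H is the entropy of the haplotype distribution.
#'
#' @param block a [haploblock_record()].
#' @param t_env environmental potential of the block's population in GEU.
#' @return A `genodyn_block_potential` list with elements `block_id`,
#'   `population`, `mu_haplotype` (named, GEU), `mu_block`, `n_snps`,
#'   `mu_fixed`, `s_block` (bits), `t_env`.
#' @export
haploblock_potential <- function(block, t_env) {
  stopifnot(inherits(block, "genodyn_block"))
  check_prob_vector(unname(block$hap_freq), what = "haplotype frequencies")
  mu_h <- haplotype_potential(unname(block$hap_freq), block$n_snps, t_env)
  s_h <- shannon_entropy(unname(block$hap_freq))
  mu_fixed <- fixing_potential(t_env)
  structure(list(block_id = block$block_id,
                 population = block$population,
                 mu_haplotype = setNames(mu_h, names(block$hap_freq)),
                 mu_block = block$n_snps * mu_fixed + t_env * s_h,
                 n_snps = block$n_snps,
                 mu_fixed = mu_fixed,
                 s_block = s_h,
                 t_env = t_env),
            class = "genodyn_block_potential")
}

#' Distribute a haploblock potential onto its member SNPs
#'
#' Apportions the block potential under three rules: (1) a SNP fixed in the
#' population receives exactly the fixing potential; (2) the distributed
#' potentials sum to the block potential; (3) the remainder above the fixed
#' baseline is shared proportional to per-SNP weights.  The weight of SNP s
#' is its marginal Shannon entropy, which vanishes exactly for fixed SNPs so
#' rule 1 is the continuous limit of rule 3.
#'
#' A fully fixed multi-SNP block has all weights zero; its members are then
#' treated as unlinked fixed SNPs (each receives `mu_fixed`, binding
#' potential 0) and the fallback is logged.
#'
#' @param block_potential a `genodyn_block_potential` from
#'   [haploblock_potential()].
#' @param marginal_entropies per-member-SNP marginal entropies in bits, in
#'   `snp_ids` order.  If `NULL`, computed from the haplotype marginals of
#'   `block`.
#' @param block the underlying [haploblock_record()]; required when
#'   `marginal_entropies` is `NULL`.
#' @return Named numeric vector of distributed SNP potentials (GEU), with
#'   attribute `degenerate_fixed` = TRUE for the all-fixed fallback.
#' @export
distribute_block_potential <- function(block_potential, marginal_entropies = NULL,
                                       block = NULL) {
  bp <- block_potential
  stopifnot(inherits(bp, "genodyn_block_potential"))
  if (is.null(marginal_entropies)) {
    if (is.null(block)) gd_input_error("distribute_block_potential: need marginal entropies or the block record")
    marginal_entropies <- vapply(block_marginals(block), shannon_entropy, numeric(1))
  }
  if (length(marginal_entropies) != bp$n_snps) {
    gd_input_error("distribute_block_potential: ", length(marginal_entropies),
                   " weights for ", bp$n_snps, " SNPs")
  }
  if (any(marginal_entropies < 0)) gd_input_error("distribute_block_potential: negative weight")
  w <- marginal_entropies
  ids <- if (!is.null(block)) block$snp_ids else paste0("snp", seq_len(bp$n_snps))
  if (sum(w) == 0) {
    if (bp$n_snps > 1L) {
      gd_log("potentials", sprintf(
        "block %s/%s fully fixed: members treated as unlinked fixed SNPs",
        bp$block_id, bp$population))
    }
    out <- setNames(rep(bp$mu_fixed, bp$n_snps), ids)
    attr(out, "degenerate_fixed") <- TRUE
    return(out)
  }
  remainder <- bp$mu_block - bp$n_snps * bp$mu_fixed  # = T_E * s_block >= 0
  out <- setNames(bp$mu_fixed + remainder * w / sum(w), ids)
  attr(out, "degenerate_fixed") <- FALSE
  out
}

#' Binding potential
#'
#' `eps = mu_S_distributed - mu_S_marginal`: the (non-positive) potential
#' lowering a SNP gains from linkage.  Zero exactly when the haplotype
#' distribution factorizes into its marginals.
#'
#' @param mu_distributed distributed SNP potential (GEU).
#' @param mu_marginal marginal SNP potential (GEU).
#' @return Binding potential in GEU.
#' @export
binding_potential <- function(mu_distributed, mu_marginal) {
  if (any(!is.finite(mu_distributed)) || any(!is.finite(mu_marginal))) {
    gd_input_error("binding_potential: inputs must be finite")
  }
  mu_distributed - mu_marginal
}

#' Distributed allelic potential
#'
#' Both alleles of a linked SNP share the lowered potential:
#' `mu_a_H = mu_a + eps_binding`.  An absent allele's +Inf sentinel is
#' preserved.
#'
#' @param mu_allele allelic potential(s), GEU (may be +Inf).
#' @param eps_binding binding potential, GEU.
#' @return Shifted potential(s) in GEU.
#' @export
distributed_allelic_potential <- function(mu_allele, eps_binding) {
  out <- mu_allele + eps_binding
  out[is.infinite(mu_allele)] <- Inf
  out
}

#' Genome entropy of one population
#'
#' Sums the maintained entropies of all SNPs: unlinked SNPs contribute their
#' marginal allele entropy; SNPs inside a haploblock contribute via the
#' block's joint haplotype entropy (not their marginals), so linkage lowers
#' the genome entropy.
#'
#' @param freqs a [freq_table()].
#' @param blocks list of [haploblock_record()]s (any population; only those
#'   matching `population` are used).  A SNP may belong to at most one block.
#' @param population population code to evaluate.
#' @return Genome entropy in bits.
#' @export
genome_entropy <- function(freqs, blocks = list(), population) {
  ft <- as.data.table(freqs)
  snp_id <- NULL
  keep_rows <- ft[["population"]] == population
  sub <- ft[keep_rows]
  if (nrow(sub) == 0L) gd_input_error("genome_entropy: no SNPs for population ", population)
  blocks <- Filter(function(b) b$population == population, blocks)
  block_snps <- unlist(lapply(blocks, `[[`, "snp_ids"))
  if (anyDuplicated(block_snps)) {
    gd_input_error("genome_entropy: SNP '", block_snps[duplicated(block_snps)][1L],
                   "' belongs to more than one block in population ", population)
  }
  missing_members <- setdiff(block_snps, unique(sub$snp_id))
  if (length(missing_members)) {
    gd_input_error("genome_entropy: block SNP '", missing_members[1L],
                   "' absent from frequency table")
  }
  unlinked <- sub[!snp_id %in% block_snps]
  s_marg <- if (nrow(unlinked)) {
    sum(unlinked[, .(s = shannon_entropy(freq)), by = snp_id]$s)
  } else 0
  s_blocks <- sum(vapply(blocks, function(b) shannon_entropy(unname(b$hap_freq)),
                         numeric(1)))
  s_marg + s_blocks
}

#' Per-population entropy profile
#'
#' Computes, for every population in the table: the genome entropy, the
#' maximal entropy (one bit per bi-allelic SNP, monomorphic sites included),
#' the NIC and the environmental potential T_E.
#'
#' @param freqs a [freq_table()].
#' @param blocks optional list of [haploblock_record()]s.
#' @return data.table with columns `population`, `s_genome`, `s_max`, `nic`,
#'   `t_env`.
#' @export
entropy_profile <- function(freqs, blocks = list()) {
  ft <- as.data.table(freqs)
  pops <- sort(unique(ft$population))
  rows <- lapply(pops, function(pp) {
    sub <- ft[ft$population == pp]
    s_max <- length(unique(sub$snp_id))
    s_gen <- genome_entropy(freqs, blocks, pp)
    nv <- nic(s_gen, s_max)
    data.table(population = pp, s_genome = s_gen, s_max = as.numeric(s_max),
               nic = nv, t_env = environmental_potential(nv))
  })
  rbindlist(rows)
}

#' Full potential table
#'
#' Builds the per-SNP, per-population potential table: allelic and SNP
#' potentials for every site, and — for SNPs that are members of a
#' haploblock in a given population — the distributed SNP potential, the
#' binding potential, and distributed allelic potentials.  Unlinked SNPs
#' carry their marginal values with binding potential 0.
#'
#' @param freqs a [freq_table()].
#' @param tenv data.frame with columns `population`, `t_env` (GEU), e.g.
#'   from [entropy_profile()] or read from file.  Must cover every
#'   population in `freqs`.
#' @param blocks optional list of [haploblock_record()]s; each is checked
#'   for marginal consistency against `freqs`.
#' @return A `genodyn_potentials` data.table, one row per SNP x population x
#'   allele, with columns `snp_id`, `population`, `allele`, `p`,
#'   `mu_allele`, `mu_snp`, `block_id`, `mu_snp_distributed`, `eps_binding`,
#'   `mu_allele_distributed`, `linked`.
#' @export
compute_potentials <- function(freqs, tenv, blocks = list()) {
  ft <- as.data.table(freqs)
  te <- as.data.table(tenv)
  if (!all(c("population", "t_env") %in% names(te))) {
    gd_input_error("tenv must have columns population, t_env")
  }
  pops <- unique(ft$population)
  missing_pop <- setdiff(pops, te$population)
  if (length(missing_pop)) {
    gd_input_error("no T_E supplied for population ", missing_pop[1L])
  }
  te_map <- setNames(te$t_env, te$population)

  ## per-population block membership with duplicate check
  by_pop_blocks <- split(blocks, vapply(blocks, `[[`, character(1), "population"))
  for (pp in names(by_pop_blocks)) {
    mem <- unlist(lapply(by_pop_blocks[[pp]], `[[`, "snp_ids"))
    if (anyDuplicated(mem)) {
      gd_input_error("SNP '", mem[duplicated(mem)][1L],
                     "' in two blocks for population ", pp)
    }
  }
  for (b in blocks) check_block_marginals(b, ft)

  if (nrow(ft) == 0L) {
    empty <- data.table(snp_id = character(0), population = character(0),
                        allele = character(0), p = numeric(0),
                        mu_allele = numeric(0), mu_snp = numeric(0),
                        block_id = character(0), mu_snp_distributed = numeric(0),
                        eps_binding = numeric(0),
                        mu_allele_distributed = numeric(0), linked = logical(0))
    return(structure(empty, class = c("genodyn_potentials", class(data.table::data.table()))))
  }
  snp_id <- population <- NULL
  base <- ft[, {
    t_e <- te_map[[.BY$population]]
    mu_a <- allelic_potential(freq, t_e)
    mu_s <- snp_potential(freq, t_e)
    list(allele = allele, p = freq, mu_allele = mu_a, mu_snp = mu_s)
  }, by = .(snp_id, population)]
  base[, `:=`(block_id = NA_character_,
              mu_snp_distributed = mu_snp,
              eps_binding = 0,
              mu_allele_distributed = mu_allele,
              linked = FALSE)]

  for (b in blocks) {
    t_e <- te_map[[b$population]]
    bp <- haploblock_potential(b, t_e)
    dist <- distribute_block_potential(bp, block = b)
    if (isTRUE(attr(dist, "degenerate_fixed"))) next  # unlinked fixed fallback
    for (i in seq_along(b$snp_ids)) {
      sid <- b$snp_ids[i]
      idx <- which(base$snp_id == sid & base$population == b$population)
      if (!length(idx)) {
        gd_input_error("block '", b$block_id, "' member SNP '", sid,
                       "' absent from frequency table")
      }
      eps <- binding_potential(dist[[i]], base$mu_snp[idx[1L]])
      data.table::set(base, idx, "block_id", b$block_id)
      data.table::set(base, idx, "mu_snp_distributed", dist[[i]])
      data.table::set(base, idx, "eps_binding", eps)
      data.table::set(base, idx, "mu_allele_distributed",
                      distributed_allelic_potential(base$mu_allele[idx], eps))
      data.table::set(base, idx, "linked", TRUE)
    }
  }
  structure(base, class = c("genodyn_potentials", class(data.table::data.table())))
}
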