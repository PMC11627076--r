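# Synthetic study designs: ten homeostatic populations with bi-allelic SNP
# frequencies, per-population environmental potentials T_E in the printed
# range of real panels (~1.10-1.24), environmental scalars spanning a
# factor-of-five range, implanted smooth potential-environment relationships
# with Gaussian residual noise on the potential scale, and optional
# haploblocks with controlled linkage.  Generator truth is always recorded
# so recovery tests can compare against it.

#' Invert an allelic potential to an allele frequency
#'
#' Solves `mu = mu-check - T_E - T_E*log2(p)` for p:
#' `p = 2^((mu-check - T_E - mu)/T_E)`.  Only potentials at or above the
#' fixing potential `mu-check - T_E` are reachable by an unlinked allele
#' (distributed potentials can lie below it, marginal ones cannot).
#'
#' @param mu_target target allelic potential (GEU), vectorized.
#' @param t_env environmental potential (GEU).
#' @return Allele frequency in (0, 1\].
#' @export
invert_potential_to_frequency <- function(mu_target, t_env) {
  fixed <- fixing_potential(t_env)
  if (any(mu_target < fixed - 1e-12)) {
    gd_input_error("potential ", format(min(mu_target), digits = 10),
                   " GEU is below the fixing potential (",
                   format(fixed, digits = 10),
                   ") and unreachable without linkage")
  }
  pmin(2^((MU_CHECK - t_env - mu_target) / t_env), 1)
}

#' Default scenario configuration
#'
#' Ten populations; T_E drawn uniformly from the observed panel range
#' \[1.10, 1.24\] GEU; one environmental parameter whose values span a
#' factor-of-five range; one implanted SNP per 100 null SNPs, with a linear
#' allelic-potential dependence of slope +0.1 GEU per lambda unit and
#' residual SD 0.03 GEU on the potential scale; one 3-SNP haploblock around
#' the implanted SNP in the lowest-lambda population (strong linkage),
#' emulating the pattern where only the least-exposed population keeps the
#' block's correlated variation.
#'
#' @param n_populations number of populations (default 10).
#' @param n_null number of null SNPs (default 100).
#' @param n_implants number of implanted SNPs (default 1).
#' @param seed integer seed; mandatory for reproducibility.
#' @return A `ScenarioConfig` list understood by [gen_scenario()].
#' @export
scenario_config <- function(n_populations = 10L, n_null = 100L,
                            n_implants = 1L, seed = 1L) {
  list(n_populations = as.integer(n_populations),
       n_null = as.integer(n_null),
       n_implants = as.integer(n_implants),
       t_env_range = c(1.10, 1.24),
       env_parameter = "zoonotic_virus_richness",
       env_range = c(2, 10),          # factor-of-five span of lambda
       maf_range = c(0.02, 0.5),
       implant_form = "linear",
       implant_slope = 0.1,           # GEU per lambda unit
       implant_mu_at_min = 0.0,       # GEU at the lowest lambda
       residual_sd = 0.03,            # GEU, potential-scale noise
       block_n_snps = 3L,
       block_ld = 0.95,
       seed = as.integer(seed))
}

#' Generate null SNP frequencies
#'
#' Frequencies are drawn independently per population with uniform minor
#' allele frequency in `maf_range`; they carry no environmental dependence.
#' Allele labels are REF = "T", ALT = "C"; the draw decides per population
#' which allele is minor, so a SNP's global major allele is data-driven.
#'
#' @param n_snps number of SNPs.
#' @param populations character vector of population codes.
#' @param maf_range minor-allele-frequency range (default c(0.02, 0.5)).
#' @param seed integer seed.
#' @param id_prefix prefix for generated SNP ids.
#' @param chrom chromosome label.
#' @param pos_offset first position.
#' @return A [freq_table()].
#' @export
gen_null_snps <- function(n_snps, populations, maf_range = c(0.02, 0.5),
                          seed = 1L, id_prefix = "null", chrom = "3",
                          pos_offset = 1000L) {
  if (n_snps == 0L) {
    return(freq_table(data.frame(snp_id = character(0), chrom = character(0),
                                 pos = integer(0), allele = character(0),
                                 population = character(0), freq = numeric(0))))
  }
  with_seed(seed, {
    rows <- vector("list", n_snps)
    for (i in seq_len(n_snps)) {
      maf <- runif(length(populations), maf_range[1L], maf_range[2L])
      f_T <- 1 - maf                      # T is the major allele on average
      rows[[i]] <- data.table(
        snp_id = sprintf("%s%05d", id_prefix, i), chrom = chrom,
        pos = pos_offset + 10L * i,
        allele = rep(c("T", "C"), each = length(populations)),
        population = rep(populations, 2L),
        freq = c(f_T, 1 - f_T))
    }
    freq_table(rbindlist(rows))
  })
}

#' Generate one implanted SNP
#'
#' The target allele's potential follows a stated curve of the
#' environmental parameter, `mu(lambda)` plus Gaussian noise of SD
#' `residual_sd` (noise lives on the potential scale, where the flagging
#' criterion operates), and is inverted to a frequency per population.
#' Draws that fall below the fixing potential are resampled (bounded
#' retries, logged).
#'
#' @param snp_id SNP identifier.
#' @param t_env_values named numeric: T_E per population (GEU).
#' @param env_values named numeric: lambda per population.
#' @param form_id `"linear"` (mu = mu0 + slope*(lambda - min lambda)) or
#'   `"constant"`.
#' @param slope GEU per lambda unit (linear form).
#' @param mu_at_min potential at the smallest lambda (GEU).
#' @param residual_sd Gaussian residual SD on the potential scale (GEU).
#' @param seed integer seed.
#' @param target_allele allele carrying the implanted curve (default "T").
#' @param other_allele the complementary allele label (default "C").
#' @param chrom,pos coordinates for the emitted rows.
#' @return A [freq_table()] for the one SNP, with attribute `truth`: list
#'   of the curve, per-population target potentials (noise-free and noisy)
#'   and the implied frequencies.
#' @export
gen_implanted_snp <- function(snp_id, t_env_values, env_values,
                              form_id = "linear", slope = 0.1,
                              mu_at_min = 0.0, residual_sd = 0.03, seed = 1L,
                              target_allele = "T", other_allele = "C",
                              chrom = "3", pos = 500L) {
  pops <- names(env_values)
  stopifnot(!is.null(pops), setequal(pops, names(t_env_values)))
  lam <- as.numeric(env_values)
  mu_true <- switch(match.arg(form_id, c("linear", "constant")),
                    linear = mu_at_min + slope * (lam - min(lam)),
                    constant = rep(mu_at_min, length(lam)))
  names(mu_true) <- pops
  with_seed(seed, {
    mu_noisy <- numeric(length(pops)); names(mu_noisy) <- pops
    p_target <- numeric(length(pops)); names(p_target) <- pops
    for (i in seq_along(pops)) {
      t_e <- t_env_values[[pops[i]]]
      ok <- FALSE
      for (try in 1:100) {
        cand <- mu_true[[i]] + rnorm(1L, 0, residual_sd)
        if (cand >= fixing_potential(t_e)) { ok <- TRUE; break }
      }
      if (!ok) {
        gd_log("simulate", sprintf(
          "implant %s/%s: potential repeatedly below fixing potential; clamping",
          snp_id, pops[i]))
        cand <- fixing_potential(t_e)
      }
      mu_noisy[[i]] <- cand
      p_target[[i]] <- invert_potential_to_frequency(cand, t_e)
    }
    ft <- freq_table(data.table(
      snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
      allele = rep(c(target_allele, other_allele), each = length(pops)),
      population = rep(pops, 2L),
      freq = c(p_target, 1 - p_target)))
    attr(ft, "truth") <- list(snp_id = snp_id, form_id = form_id,
                              slope = slope, mu_at_min = mu_at_min,
                              target_allele = target_allele,
                              residual_sd = residual_sd,
                              mu_true = mu_true, mu_noisy = mu_noisy,
                              p_target = p_target)
    ft
  })
}

## comonotone coupling of bi-allelic marginals: the maximal-linkage joint
## distribution given per-SNP major-allele probabilities p (threshold
## construction; support has at most n+1 haplotypes)
comonotone_haps <- function(p_major, labels_major, labels_minor) {
  cuts <- sort(unique(c(0, p_major, 1)))
  freqs <- diff(cuts)
  haps <- vapply(seq_along(freqs), function(k) {
    mid <- (cuts[k] + cuts[k + 1L]) / 2
    paste0(ifelse(mid < p_major, labels_major, labels_minor), collapse = "")
  }, character(1))
  tapply(freqs, haps, sum)
}

#' Generate a haploblock with controlled linkage
#'
#' Builds a haplotype distribution interpolating between the product of the
#' marginals (`ld_strength = 0`, no linkage) and the comonotone
#' maximal-linkage coupling (`ld_strength = 1`); marginal allele
#' frequencies are preserved exactly at every strength.  Optionally draws
#' `n_chrom` chromosomes multinomially and emits phased VCF lines so the
#' file-ingestion path can be round-tripped; the record's frequencies are
#' then the exact counted ones.
#'
#' @param snp_ids member SNP ids (order defines haplotype strings).
#' @param p_major per-SNP major-allele frequency in the population.
#' @param ld_strength linkage strength in \[0, 1\].
#' @param population population code.
#' @param block_id block identifier.
#' @param alleles_major,alleles_minor per-SNP allele characters (defaults
#'   "T"/"C").
#' @param n_chrom if > 0, also sample this many chromosomes (must be even
#'   for diploid VCF output).
#' @param seed integer seed (used only when sampling).
#' @param chrom,pos_start coordinates for emitted VCF lines.
#' @return A list: `record` (the theoretical-distribution
#'   [haploblock_record()]), and when `n_chrom > 0` also `sampled_record`
#'   (counted frequencies), `chromosomes` (character matrix), `vcf_lines`,
#'   `sample_ids`.
#' @export
gen_haploblock_fixture <- function(snp_ids, p_major, ld_strength,
                                   population, block_id = "blk1",
                                   alleles_major = NULL, alleles_minor = NULL,
                                   n_chrom = 0L, seed = 1L,
                                   chrom = "3", pos_start = 100L) {
  n <- length(snp_ids)
  stopifnot(length(p_major) == n, ld_strength >= 0, ld_strength <= 1)
  if (is.null(alleles_major)) alleles_major <- rep("T", n)
  if (is.null(alleles_minor)) alleles_minor <- rep("C", n)
  ## product-of-marginals component over all 2^n haplotypes
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), n))[, n:1, drop = FALSE]
  prod_freq <- apply(grid, 1L, function(is_major) {
    prod(ifelse(is_major, p_major, 1 - p_major))
  })
  prod_hap <- apply(grid, 1L, function(is_major) {
    paste0(ifelse(is_major, alleles_major, alleles_minor), collapse = "")
  })
  prod_tab <- tapply(prod_freq, prod_hap, sum)
  como_tab <- comonotone_haps(p_major, alleles_major, alleles_minor)
  haps <- union(names(prod_tab), names(como_tab))
  get0n <- function(tab, h) ifelse(h %in% names(tab), tab[h], 0)
  freqs <- (1 - ld_strength) * as.numeric(get0n(prod_tab, haps)) +
    ld_strength * as.numeric(get0n(como_tab, haps))
  keep <- freqs > 0
  rec <- haploblock_record(block_id, population, snp_ids,
                           setNames(freqs[keep] / sum(freqs[keep]), haps[keep]))
  out <- list(record = rec)
  if (n_chrom > 0L) {
    if (n_chrom %% 2L != 0L) gd_input_error("n_chrom must be even (diploid output)")
    with_seed(seed, {
      draw <- as.vector(stats::rmultinom(1L, n_chrom, rec$hap_freq))
    })
    counted <- setNames(draw / n_chrom, names(rec$hap_freq))
    counted <- counted[counted > 0]
    out$sampled_record <- haploblock_record(block_id, population, snp_ids, counted)
    chroms <- rep(names(rec$hap_freq), draw)
    ## pair chromosomes into diploid samples in draw order (deterministic)
    m <- matrix(chroms, nrow = 2L)
    sample_ids <- sprintf("%s_s%03d", population, seq_len(ncol(m)))
    gt_of <- function(hap_pair, i, a_major, a_minor) {
      code <- function(h) ifelse(substr(h, i, i) == a_major, "0", "1")
      paste0(code(hap_pair[1L]), "|", code(hap_pair[2L]))
    }
    vcf_rows <- vapply(seq_len(n), function(i) {
      gts <- vapply(seq_len(ncol(m)), function(j)
        gt_of(m[, j], i, alleles_major[i], alleles_minor[i]), character(1))
      paste(c(chrom, pos_start + 10L * (i - 1L), snp_ids[i],
              alleles_major[i], alleles_minor[i], ".", "PASS", ".", "GT", gts),
            collapse = "\t")
    }, character(1))
    out$chromosomes <- m
    out$sample_ids <- sample_ids
    out$vcf_lines <- c(vcf_header(sample_ids), vcf_rows)
  }
  out
}

## minimal VCF v4.2 header for emitted fixtures (writing only; parsing is
## always delegated to VariantAnnotation)
vcf_header <- function(sample_ids) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
}

#' Write a phased VCF + panel realizing a frequency table
#'
#' Draws `2 * n_per_pop` chromosomes per population per SNP (independent
#' Bernoulli per chromosome) and writes a phased VCF and matching panel.
#' The attribute `counted_freqs` records the realized allele counts, so the
#' ingestion round-trip is exact by construction.
#'
#' @param freqs a [freq_table()].
#' @param n_per_pop diploid samples per population.
#' @param vcf_path,panel_path output paths.
#' @param seed integer seed.
#' @return Invisibly, a [freq_table()] of the realized (counted)
#'   frequencies.
#' @export
gen_vcf_fixture <- function(freqs, n_per_pop, vcf_path, panel_path, seed = 1L) {
  ft <- as.data.table(freqs)
  pops <- sort(unique(ft$population))
  sample_ids <- unlist(lapply(pops, function(pp)
    sprintf("%s_s%03d", pp, seq_len(n_per_pop))))
  pop_of <- rep(pops, each = n_per_pop)
  al <- snp_alleles(freqs)
  snps <- unique(ft[, c("snp_id", "chrom", "pos")])
  data.table::setorder(snps, chrom, pos)
  realized <- vector("list", nrow(snps))
  lines <- character(nrow(snps))
  with_seed(seed, {
    for (i in seq_len(nrow(snps))) {
      sid <- snps$snp_id[i]
      ref <- al$allele_major[al$snp_id == sid]
      alt <- al$allele_minor[al$snp_id == sid]
      gts <- character(length(sample_ids))
      cnt <- list()
      for (pp in pops) {
        f_alt <- ft[ft$snp_id == sid & ft$population == pp & ft$allele == alt]$freq
        hap <- rbinom(2L * n_per_pop, 1L, f_alt)
        gts[pop_of == pp] <- paste0(hap[c(TRUE, FALSE)], "|", hap[c(FALSE, TRUE)])
        cnt[[pp]] <- data.table(
          snp_id = sid, chrom = snps$chrom[i], pos = snps$pos[i],
          allele = c(ref, alt), population = pp,
          freq = c(sum(hap == 0L), sum(hap == 1L)) / (2L * n_per_pop))
      }
      realized[[i]] <- rbindlist(cnt)
      lines[i] <- paste(c(snps$chrom[i], snps$pos[i], sid, ref, alt, ".",
                          "PASS", ".", "GT", gts), collapse = "\t")
    }
  })
  writeLines(c(vcf_header(sample_ids), lines), vcf_path)
  write_panel(population_panel(sample_ids, pop_of), panel_path)
  invisible(freq_table(rbindlist(realized)))
}

## Solve for the marginal target-allele frequency p such that, inside a
## block built from marginals c(p, p_others) at the given linkage strength,
## the SNP's distributed allelic potential equals mu_target.  The implanted
## curve is a statement about the potential the scan observes, which for a
## linked population is the distributed one; this inversion keeps the
## linked point on the curve.  Returns NA when mu_target is unreachable.
solve_linked_frequency <- function(mu_target, t_env, p_others, ld_strength) {
  g <- function(p) {
    fx <- gen_haploblock_fixture(paste0("m", seq_len(1L + length(p_others))),
                                 c(p, p_others), ld_strength, "tmp")
    bp <- haploblock_potential(fx$record, t_env)
    dist <- distribute_block_potential(bp, block = fx$record)
    eps <- if (isTRUE(attr(dist, "degenerate_fixed"))) 0
           else dist[[1L]] - snp_potential(c(p, 1 - p), t_env)
    allelic_potential(p, t_env) + eps - mu_target
  }
  lo <- 1e-6; hi <- 1 - 1e-9
  flo <- g(lo); fhi <- g(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) return(NA_real_)
  stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
}

#' Generate a complete synthetic scenario
#'
#' Emulates the study design end-to-end: `n_populations` homeostatic
#' populations named P01, P02, ...; per-population T_E drawn uniformly from
#' the configured range; an environmental parameter with evenly spaced
#' values over a factor-of-five range (shuffled across populations);
#' `n_null` null SNPs; `n_implants` SNPs with implanted linear
#' potential-environment dependencies; and a haploblock containing each
#' implanted SNP in the lowest-lambda population only.
#'
#' @param config a [scenario_config()] list.
#' @return A `genodyn_scenario` list: `freqs`, `blocks`, `tenv` (data.table
#'   `population`, `t_env`), `env` ([env_table()]), `truth` (per-implant
#'   generator truth and block membership), `config`.
#' @export
gen_scenario <- function(config = scenario_config()) {
  cfg <- config
  pops <- sprintf("P%02d", seq_len(cfg$n_populations))
  with_seed(sub_seed(cfg$seed, 1L), {
    t_env <- setNames(runif(cfg$n_populations, cfg$t_env_range[1L],
                            cfg$t_env_range[2L]), pops)
    lam <- setNames(sample(seq(cfg$env_range[1L], cfg$env_range[2L],
                               length.out = cfg$n_populations)), pops)
  })
  nulls <- gen_null_snps(cfg$n_null, pops, cfg$maf_range,
                         seed = sub_seed(cfg$seed, 2L))
  parts <- list(as.data.table(nulls))
  truth <- list(implants = list(), blocks = list())
  for (k in seq_len(cfg$n_implants)) {
    sid <- sprintf("implant%02d", k)
    imp <- gen_implanted_snp(sid, t_env, lam,
                             form_id = cfg$implant_form,
                             slope = cfg$implant_slope,
                             mu_at_min = cfg$implant_mu_at_min,
                             residual_sd = cfg$residual_sd,
                             seed = sub_seed(cfg$seed, 10L + k),
                             pos = 500L + k)
    truth$implants[[sid]] <- attr(imp, "truth")
    parts[[length(parts) + 1L]] <- as.data.table(imp)
  }
  freqs <- freq_table(rbindlist(parts))

  ## one block per implant, in the lowest-lambda population only (the
  ## pattern where only the least-exposed population keeps the correlated
  ## variation): the implanted SNP plus block_n_snps - 1 null SNPs, coupled
  ## at the configured linkage strength.  In the linked population the
  ## implant's marginal frequency is re-solved so that its *distributed*
  ## potential — what the scan observes there — lies on the implanted
  ## curve; the other members keep their null marginals.
  blocks <- list()
  if (cfg$n_implants > 0L && cfg$block_n_snps > 1L && cfg$n_null >= cfg$n_implants * (cfg$block_n_snps - 1L)) {
    low_pop <- names(lam)[which.min(lam)]
    ft <- as.data.table(freqs)
    for (k in seq_len(cfg$n_implants)) {
      sid <- sprintf("implant%02d", k)
      members <- c(sid, sprintf("null%05d", seq_len(cfg$block_n_snps - 1L) +
                                  (k - 1L) * (cfg$block_n_snps - 1L)))
      p_others <- vapply(members[-1L], function(s)
        ft[ft$snp_id == s & ft$population == low_pop & ft$allele == "T"]$freq,
        numeric(1))
      mu_target <- truth$implants[[sid]]$mu_noisy[[low_pop]]
      p_imp <- solve_linked_frequency(mu_target, t_env[[low_pop]],
                                      p_others, cfg$block_ld)
      if (is.na(p_imp)) {
        gd_log("simulate", sprintf(
          "implant %s: linked target unreachable in %s; keeping marginal frequency",
          sid, low_pop))
        p_imp <- truth$implants[[sid]]$p_target[[low_pop]]
      }
      data.table::set(ft, which(ft$snp_id == sid & ft$population == low_pop &
                                  ft$allele == "T"), "freq", p_imp)
      data.table::set(ft, which(ft$snp_id == sid & ft$population == low_pop &
                                  ft$allele == "C"), "freq", 1 - p_imp)
      fx <- gen_haploblock_fixture(members, c(p_imp, p_others), cfg$block_ld,
                                   low_pop, block_id = sprintf("blk_%s", sid))
      blocks[[length(blocks) + 1L]] <- fx$record
      truth$implants[[sid]]$p_target[[low_pop]] <- p_imp
      truth$blocks[[sprintf("blk_%s", sid)]] <-
        list(members = members, population = low_pop, ld = cfg$block_ld,
             linked_frequency = p_imp)
    }
    freqs <- freq_table(ft)
  }
  structure(list(
    freqs = freqs, blocks = blocks,
    tenv = data.table(population = pops, t_env = as.numeric(t_env)),
    env = env_table(data.table(parameter = cfg$env_parameter,
                               population = pops, value = as.numeric(lam))),
    truth = truth, config = cfg),
    class = "genodyn_scenario")
}

#' Write a scenario's tables to a directory
#'
#' Emits `freqs.tsv`, `blocks.tsv`, `tenv.tsv`, `env.tsv` and `truth.json`,
#' plus (optionally) a phased `genotypes.vcf` + `panel.tsv` realizing the
#' frequency table for the file-ingestion path.
#'
#' @param scenario a `genodyn_scenario`.
#' @param outdir output directory (created if needed).
#' @param vcf also write a sampled VCF/panel (default FALSE).
#' @param n_per_pop diploid samples per population for the VCF.
#' @return Named character vector of written paths, invisibly.
#' @export
write_scenario <- function(scenario, outdir, vcf = FALSE, n_per_pop = 50L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(freqs = file.path(outdir, "freqs.tsv"),
             blocks = file.path(outdir, "blocks.tsv"),
             tenv = file.path(outdir, "tenv.tsv"),
             env = file.path(outdir, "env.tsv"),
             truth = file.path(outdir, "truth.json"))
  write_freq_table(scenario$freqs, paths[["freqs"]])
  write_blocks(scenario$blocks, paths[["blocks"]])
  write_tenv(scenario$tenv, paths[["tenv"]])
  write_env_table(scenario$env, paths[["env"]])
  jsonlite::write_json(scenario$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  if (vcf) {
    paths <- c(paths, vcf = file.path(outdir, "genotypes.vcf"),
               panel = file.path(outdir, "panel.tsv"))
    gen_vcf_fixture(scenario$freqs, n_per_pop, paths[["vcf"]],
                    paths[["panel"]], seed = sub_seed(scenario$config$seed, 99L))
  }
  invisible(paths)
}
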