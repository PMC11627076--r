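# core potential algebra: entropies, NIC/T_E, allelic/SNP/haplotype/block
# potentials, distribution rules, binding potentials

test_that("shannon_entropy matches closed-form values and rejects bad input", {
  expect_identical(shannon_entropy(c(0.5, 0.5)), 1)
  expect_identical(shannon_entropy(c(1, 0)), 0)
  # frozen high-precision evaluation of -(0.9 log2 0.9 + 0.1 log2 0.1)
  expect_equal(shannon_entropy(c(0.9, 0.1)), 0.46899559358928122, tolerance = 1e-14)
  expect_error(shannon_entropy(c(0.6, 0.6)), "sum to 1")
  expect_error(shannon_entropy(c(-0.1, 1.1)), "outside")
})

test_that("nic and environmental_potential follow their defining relations", {
  expect_identical(nic(0, 100), 1)
  expect_identical(nic(100, 100), 0)
  expect_equal(nic(9.75, 100), 0.9025)
  expect_error(nic(101, 100), "exceeds")
  expect_identical(environmental_potential(1), 1)
  expect_identical(environmental_potential(0.5), 2)
  # round-trip of the defining relation at a printed panel value
  expect_equal(environmental_potential(1 / 1.108), 1.108, tolerance = 1e-12)
  expect_error(environmental_potential(0), "infinite disorder")
})

test_that("NIC/T_E round-trip holds to 1e-12 over random profiles", {
  set.seed(41)
  for (i in 1:50) {
    smax <- runif(1, 10, 1e5)
    s <- runif(1, 0, smax * 0.999)
    nv <- nic(s, smax)
    expect_equal(environmental_potential(nv) * nv, 1, tolerance = 1e-12)
  }
})

test_that("allelic potential: unit at p = 0.5, fixing potential at p = 1, sentinel at p = 0", {
  # the unit's definition: exactly 1 GEU at maximal variation for any T_E
  for (t_e in seq(1, 3, by = 0.1)) {
    expect_identical(allelic_potential(0.5, t_e), 1)
  }
  expect_equal(allelic_potential(1, 1.108), -0.108, tolerance = 1e-12)
  expect_identical(allelic_potential(1, 1.108), fixing_potential(1.108))
  expect_identical(allelic_potential(0.25, 1), 2)
  expect_identical(allelic_potential(0, 1.2), Inf)
  expect_error(allelic_potential(1.2, 1.1), "outside")
})

test_that("snp_potential equals mu-check - T_E + T_E*s and is maximal only at p = 0.5", {
  expect_equal(snp_potential(c(0.5, 0.5), 1.108), 1, tolerance = 1e-15)
  expect_equal(snp_potential(c(1, 0), 1.108), -0.108, tolerance = 1e-12)
  expect_equal(snp_potential(c(0.9, 0.1), 1), 0.46899559358928122, tolerance = 1e-14)
  set.seed(42)
  for (i in 1:200) {
    p <- runif(1)
    t_e <- runif(1, 1, 3)
    mu <- snp_potential(c(p, 1 - p), t_e)
    expect_lte(mu, 1 + 1e-12)
    if (abs(p - 0.5) > 1e-3) expect_lt(mu, 1)
  }
})

test_that("haplotype and haploblock potentials follow the adopted baseline", {
  expect_equal(haplotype_potential(1, 2, 1.108), -0.216, tolerance = 1e-12)
  expect_identical(haplotype_potential(0.5, 2, 1), 1)
  expect_equal(haplotype_potential(0.25, 3, 1.108), 1.892, tolerance = 1e-12)
  expect_identical(haplotype_potential(0, 2, 1.1), Inf)

  # two independent p = 0.5 SNPs: block potential equals the sum of the two
  # unlinked SNP potentials (zero binding)
  b <- haploblock_record("b1", "PEL", c("s1", "s2"),
                         c(TT = 0.25, TC = 0.25, CT = 0.25, CC = 0.25))
  bp <- haploblock_potential(b, 1)
  expect_equal(bp$mu_block, 2, tolerance = 1e-12)
  expect_equal(bp$mu_block, 2 * snp_potential(c(0.5, 0.5), 1), tolerance = 1e-12)

  # perfect LD pair: one bit of joint entropy
  b2 <- haploblock_record("b2", "PEL", c("s1", "s2"), c(TT = 0.5, CC = 0.5))
  expect_equal(haploblock_potential(b2, 1)$mu_block, 1, tolerance = 1e-12)

  # fully fixed 3-SNP block: n * fixing potential
  b3 <- haploblock_record("b3", "PEL", c("s1", "s2", "s3"), c(TTT = 1))
  expect_equal(haploblock_potential(b3, 1.108)$mu_block, 3 * (1 - 1.108),
               tolerance = 1e-12)
})

test_that("distribution rules: fixed SNPs, sum conservation, weight proportionality", {
  # 1-SNP block: distributed potential is the marginal SNP potential
  b1 <- haploblock_record("b", "P", "s1", c(T = 0.7, C = 0.3))
  d1 <- distribute_block_potential(haploblock_potential(b1, 1.2), block = b1)
  expect_equal(as.numeric(d1), snp_potential(c(0.7, 0.3), 1.2), tolerance = 1e-12)

  # perfect-LD pair, T_E = 1: equal weights halve the remainder
  b2 <- haploblock_record("b", "P", c("s1", "s2"), c(TT = 0.5, CC = 0.5))
  d2 <- distribute_block_potential(haploblock_potential(b2, 1), block = b2)
  expect_equal(as.numeric(d2), c(0.5, 0.5), tolerance = 1e-12)
  # binding potential of each member: 0.5 - 1.0
  expect_equal(binding_potential(d2[[1]], snp_potential(c(0.5, 0.5), 1)), -0.5,
               tolerance = 1e-12)

  # SNP1 fixed, SNP2 at p = 0.5: rule 1 exactly, rule 2 gives the rest
  b3 <- haploblock_record("b", "P", c("s1", "s2"), c(TT = 0.5, TC = 0.5))
  bp3 <- haploblock_potential(b3, 1)
  d3 <- distribute_block_potential(bp3, block = b3)
  expect_identical(unname(d3[1]), fixing_potential(1))
  expect_equal(unname(d3[2]), bp3$mu_block - bp3$mu_fixed, tolerance = 1e-12)

  # fully fixed multi-SNP block: fallback, every member gets mu_fixed
  b4 <- haploblock_record("b", "P", c("s1", "s2"), c(TT = 1))
  d4 <- suppressMessages(distribute_block_potential(haploblock_potential(b4, 1.2),
                                                    block = b4))
  expect_true(attr(d4, "degenerate_fixed"))
  expect_equal(as.numeric(d4), rep(fixing_potential(1.2), 2), tolerance = 1e-15)
})

test_that("conservation and binding-sign properties hold on random blocks", {
  set.seed(101)
  for (i in 1:100) {
    b <- random_block()
    t_e <- runif(1, 1, 1.5)
    bp <- haploblock_potential(b, t_e)
    d <- distribute_block_potential(bp, block = b)
    # rule 2: sum of distributed SNP potentials equals the block potential
    expect_lt(abs(sum(d) - bp$mu_block), 1e-9)
    marg <- block_marginals(b)
    for (k in seq_along(d)) {
      eps <- binding_potential(d[[k]], snp_potential(unname(marg[[k]]), t_e))
      expect_lte(eps, 1e-9)  # linkage cannot raise a potential
    }
  }
  # eps is exactly 0 when the haplotype distribution factorizes
  b0 <- gen_haploblock_fixture(c("a", "b", "c"), c(0.7, 0.4, 0.55), 0, "P")$record
  bp0 <- haploblock_potential(b0, 1.3)
  d0 <- distribute_block_potential(bp0, block = b0)
  m0 <- block_marginals(b0)
  for (k in 1:3) {
    expect_equal(d0[[k]], snp_potential(unname(m0[[k]]), 1.3), tolerance = 1e-9)
  }
})

test_that("distributed allelic potentials shift both alleles equally and keep sentinels", {
  expect_identical(distributed_allelic_potential(1, 0), 1)
  expect_identical(distributed_allelic_potential(1, -0.5), 0.5)
  expect_identical(distributed_allelic_potential(Inf, -0.5), Inf)
  # allele difference is preserved under the shift
  t_e <- 1
  mus <- allelic_potential(c(0.5, 0.5), t_e)
  sh <- distributed_allelic_potential(mus, -0.37)
  expect_equal(diff(sh), diff(mus), tolerance = 1e-12)
  expect_error(binding_potential(Inf, 1), "finite")
})

test_that("genome_entropy: additivity, joint blocks, and the exhaustive oracle", {
  f3 <- multi_freqs(matrix(0.5, 3, 1, dimnames = list(paste0("s", 1:3), "P")))
  expect_equal(genome_entropy(f3, list(), "P"), 3, tolerance = 1e-12)

  # two SNPs in perfect LD contribute one bit, not two
  f2 <- multi_freqs(matrix(0.5, 2, 1, dimnames = list(c("s1", "s2"), "P")))
  blk <- haploblock_record("b", "P", c("s1", "s2"), c(TT = 0.5, CC = 0.5))
  expect_equal(genome_entropy(f2, list(blk), "P"), 1, tolerance = 1e-12)

  # random 20-SNP configuration with one 3-SNP block vs. full enumeration
  set.seed(77)
  fm <- matrix(runif(20, 0.05, 0.95), 20, 1,
               dimnames = list(sprintf("s%02d", 1:20), "P"))
  ff <- multi_freqs(fm)
  bx <- gen_haploblock_fixture(c("s01", "s02", "s03"), fm[1:3, 1], 0.8, "P")$record
  expect_equal(genome_entropy(ff, list(bx), "P"),
               joint_entropy_oracle(ff, list(bx), "P"), tolerance = 1e-9)

  # a SNP in two blocks is rejected
  b2 <- haploblock_record("b2", "P", c("s01", "s04"), c(TT = 0.5, CC = 0.5))
  expect_error(genome_entropy(ff, list(bx, b2), "P"), "more than one block")
})

test_that("entropy_profile and compute_potentials assemble consistent tables", {
  fm <- matrix(c(0.5, 0.9, 1.0, 0.5, 0.8, 0.7), nrow = 3,
               dimnames = list(c("s1", "s2", "s3"), c("P1", "P2")))
  ff <- multi_freqs(fm)
  prof <- entropy_profile(ff)
  expect_equal(prof$nic, (prof$s_max - prof$s_genome) / prof$s_max, tolerance = 1e-12)
  expect_equal(prof$t_env * prof$nic, rep(1, 2), tolerance = 1e-12)
  # monomorphic s3/P1 still counts toward s_max
  expect_equal(prof$s_max, rep(3, 2))

  pot <- compute_potentials(ff, prof)
  expect_equal(nrow(pot), 3 * 2 * 2)
  expect_false(any(pot$linked))
  row <- pot[pot$snp_id == "s1" & pot$population == "P1" & pot$allele == "T", ]
  expect_equal(row$mu_allele, 1)
  # absent allele carries the +Inf sentinel
  fixed <- pot[pot$snp_id == "s3" & pot$population == "P1", ]
  expect_true(any(is.infinite(fixed$mu_allele)))
  expect_equal(min(fixed$mu_allele),
               fixing_potential(prof$t_env[prof$population == "P1"]),
               tolerance = 1e-12)

  # linked SNPs get distributed values; block marginals are verified
  blk <- gen_haploblock_fixture(c("s1", "s2"), fm[1:2, 1], 1, "P1")$record
  pot2 <- compute_potentials(ff, prof, list(blk))
  l1 <- pot2[pot2$snp_id == "s1" & pot2$population == "P1", ]
  expect_true(all(l1$linked))
  expect_lt(l1$eps_binding[1], 0)
  expect_equal(l1$mu_allele_distributed, l1$mu_allele + l1$eps_binding,
               tolerance = 1e-12)
  # inconsistent marginals are a hard error
  bad <- haploblock_record("bb", "P1", c("s1", "s2"),
                           c(TT = 0.6, CC = 0.4))
  expect_error(compute_potentials(ff, prof, list(bad)), "disagrees")
})
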