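# genodyn

Information-theoretic genomic potentials for population variant data, and a
scanner for smooth dependencies of those potentials on quantified
environmental parameters.

## The problem and who it is for

Population-genetics association tools typically test SNP–trait links
without a *dimensional* measure of the pressure an environment exerts on a
variant. `genodyn` implements an alternative, thermodynamics-flavored
formulation for population geneticists and statistical-genetics
methodologists: the maintained allele distribution of a homeostatic
population (one in equilibrium-like stability across generations) is scored
by Shannon information, which yields

- a normalized information content
  `NIC = (s_max − s_genome)/s_max` per population,
- a temperature-like environmental potential `T_E = μ̌ / NIC` (in *genomic
  energy units*, GEU; `μ̌ = 1` GEU is the potential of a non-linked
  bi-allelic SNP of maximal variation),
- allelic potentials `μ_a = μ̌ − T_E − T_E·log2(p_a)` and SNP potentials
  `μ^(S) = Σ_a p_a μ_a`,
- haploblock potentials for SNPs in linkage disequilibrium, distributed
  back onto member SNPs (fixed SNPs get the fixing potential `μ̌ − T_E`;
  the parts sum to the block potential; the remainder is shared by marginal
  entropy), defining non-positive binding potentials
  `ε = μ_S^(H) − μ^(S)`.

Potentials are then scanned across populations against environmental
scalars λ (e.g. zoonotic-virus richness, a species count). A dependency is
**flagged** when the RMS residual of the best simple fitted form (constant,
linear, quadratic, saturating exponential) is within 10% of the observed
potential range, and the **adaptive force** `f_a = −∂μ_a/∂λ` is reported
(negative force = rising potential with exposure = pressure against the
allele).

A synthetic-data module generates complete ten-population study designs
with implanted potential–environment relationships, controlled-linkage
haploblocks, and recorded generator truth, so the whole pipeline is
testable without external data.

## Worked example

Generate the default scenario (10 populations, T_E ∈ [1.10, 1.24] GEU,
λ spanning 2–10, 100 null SNPs plus one implanted SNP whose major-allele
potential rises by 0.1 GEU per λ unit with 0.03 GEU noise, linked in a
3-SNP haploblock only in the least-exposed population), compute potentials,
and scan:

```r
library(genodyn)
scn <- gen_scenario(scenario_config(seed = 1))
pot <- compute_potentials(scn$freqs, scn$tenv, scn$blocks)
sc  <- scan_all(pot, scn$env)
subset(as.data.frame(sc), flagged,
       c(snp_id, target, best_form, relative_rms, force_linear, force_curve))
```

```
    snp_id       target best_form relative_rms force_linear force_curve
 implant01 allele_major    expsat       0.0299      -0.1025     -0.1025
 implant01          snp quadratic       0.0895      -0.0737     -0.0737
```

The implanted dependency is flagged (relative RMS 0.030, well inside the
10% criterion) and its adaptive force is recovered as −0.10 GEU per λ unit
— the negative of the implanted slope. The scan-wide flag fraction here is
0.0066: nulls rarely pass the criterion. The per-population detail shows
the linked point (the lowest-λ population, carrying the distributed
potential from its haploblock) on the same smooth curve:

```r
attr(sc, "details")[["implant01|zoonotic_virus_richness|allele_major"]]$points
```

```
   population lambda     mu linked
8         P08   2.00 0.0076   TRUE
1         P01   2.89 0.0303  FALSE
...
6         P06  10.00 0.8266  FALSE
```

The same flow runs from files (VCF + panel TSV, or precomputed frequency
tables) via `run_pipeline()` or the CLI wrapper
(`inst/cli/genodyn`): subcommands `freqs`, `blocks`, `potentials`, `scan`,
`simulate`, `run`; every run writes a `manifest.json` with input/output
digests, seeds and per-stage counts, and identical seeds reproduce
identical digests.

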