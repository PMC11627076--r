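---
title: "Genomic potentials and environmental scanning: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic potentials and environmental scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genodyn)
```

## The model

`genodyn` treats the maintained distribution of bi-allelic SNP variants in a
homeostatic population — one that has kept the same variant distribution
over generations, the genomic analogue of thermodynamic equilibrium — as an
information-bearing system. All quantities derive from Shannon entropy in
bits, $s = -\sum_a p_a \log_2 p_a$, over allele (or haplotype) frequencies
$p_a$.

For a population genotyped at $N$ bi-allelic SNPs:

* **Genome entropy** $s_{genome}$ sums per-SNP entropies, with SNPs in
  linkage disequilibrium (a *haploblock*) contributing their joint haplotype
  entropy instead of their marginals (`genome_entropy()`).
* **Normalized information content**
  $NIC = (s_{max} - s_{genome})/s_{max}$ with $s_{max} = N$ bits (one bit
  per bi-allelic site, monomorphic sites included): the degree of
  maintained order, in $[0, 1]$.
* **Environmental potential** $T_E = \check\mu / NIC$, a temperature-like
  measure of intrinsic disorder. The unit $\check\mu$, one *genomic energy
  unit* (GEU), is the potential of a non-linked bi-allelic SNP of maximal
  variation; it is a global constant (1), never configurable.
* **Allelic potential**
  $\mu_a = \check\mu - T_E - T_E \log_2 p_a$: the pressure on an allele at
  frequency $p_a$. At $p = 0.5$ it equals exactly 1 GEU for any $T_E$
  (this is the definition of the unit); at $p = 1$ it equals the *fixing
  potential* $\check\mu - T_E \le 0$; at $p = 0$ the allele is absent and
  the potential is reported as a $+\infty$ sentinel which contributes 0 to
  any frequency-weighted average (the $0 \log 0$ limit).
* **SNP potential** $\mu^{(S)} = \sum_a p_a \mu_a = \check\mu - T_E + T_E
  s$, maximal (1 GEU) only at $p = 0.5$.

### Haploblocks and distributed potentials

Haplotypes of a block of $n$ linked SNPs get potentials
$\mu_h = n(\check\mu - T_E) - T_E \log_2 p_h$ and the block potential is
their frequency average,
$\langle\mu^{(H)}\rangle = n\,\mu_{fixed} + T_E\, s_H$, with $s_H$ the
haplotype entropy. Because downstream association evidence is organized per
SNP, the block potential is apportioned back to members under three rules:
a SNP fixed in the population receives exactly $\mu_{fixed}$; the
distributed values sum to the block potential; and the remainder above the
fixed baseline is shared proportional to per-SNP weights $\bar P_s$:

$$\mu_S^{(H)} = \mu_{fixed} + \bigl[\langle\mu^{(H)}\rangle - n\,
\mu_{fixed}\bigr]\,\frac{\bar P_s}{\sum_{s'} \bar P_{s'}}.$$

The **binding potential** $\varepsilon = \mu_S^{(H)} - \mu^{(S)} \le 0$
measures the potential lowering a SNP gains from linkage (subadditivity of
entropy guarantees the sign), and both alleles of a linked SNP share it:
$\mu_a^{(H)} = \mu_a + \varepsilon$.

Two points here were genuinely open and are this package's design choices:

* **Haplotype baseline.** With a per-haplotype baseline of $\check\mu$, a
  fully fixed block would carry potential $\check\mu - T_E \ne n(\check\mu
  - T_E)$ and the fixed-SNP rule and the sum rule could not hold at once.
  We use the baseline $n(\check\mu - T_E)$, the unique affine choice that
  makes the rules mutually consistent in the fixed limit.
* **Weights $\bar P_s$** ("occurrence of the alleles") are taken to be the
  marginal Shannon entropy of each member SNP. This makes the weight vanish
  exactly for fixed SNPs, so the fixed-SNP rule is the continuous limit of
  the proportional rule rather than an exception. A fully fixed multi-SNP
  block has all weights zero; it is treated as unlinked fixed SNPs and the
  fallback is logged.

## Environmental scanning and flagging

For each SNP, each target (major allele, minor allele, SNP potential) and
each environmental parameter $\lambda$ (e.g. zoonotic-virus *richness*, a
count of unique species in a region), the scan assembles one point per
population: the *distributed* potential where the SNP is in a block in that
population, the marginal potential otherwise, each point carrying its
linked flag. Candidate forms — constant, linear, quadratic, saturating
exponential $a + b e^{-c\lambda}$ — are fitted by least squares (QR for
polynomials; a deterministic multi-start over decay rates with the linear
coefficients profiled out for the exponential). The library is deliberately
minimal: flat, monotone trends, and a single saturation/downturn are the
only shapes the smoothness criterion targets.

A dependency is **flagged** when the relative RMS — RMS residual of the
best fit divided by the max–min of the *observed* population potentials —
is at most 10%. The denominator is the observed spread, not the fitted
curve's, which is the literal reading of a criterion about "the
distribution of the allelic potentials of the populations". Monotonicity
over the observed $\lambda$ range is required of allelic-potential fits
(not SNP-potential fits); a quadratic whose vertex falls inside the range
is inadmissible for allelic targets.

The **adaptive force** is $f_a = -\partial\mu_a/\partial\lambda$. Linear
fits report the constant $-b$; nonlinear fits report the mean derivative
over the observed range (equal to minus the chord slope) as the headline
value, with the pointwise derivative available as a function. A rising
potential with exposure therefore yields a negative force. No
multiple-testing correction is applied — the 10% criterion is the whole
rule — but the scan-wide flag fraction is reported for context.

### Numerical conventions

* Entropy base 2 throughout; conservation identities checked at `1e-9`;
  algebraic round-trips (NIC–$T_E$, potential inversion) at `1e-12`.
* Ties between candidate forms (equal relative RMS within `1e-12`) resolve
  toward fewer parameters.
* Zero observed potential range: the constant fit and a zero force are
  reported, but the relative criterion is undefined and the scan is never
  flagged ("no variation").
* Fewer than 3 usable populations (finite potentials with known
  $\lambda$): scan skipped with a logged reason.
* All stochastic steps take explicit integer seeds; identical seeds give
  byte-identical outputs (the run manifest records digests to make this
  checkable).

One stated property deserves a caveat: adding a population whose point
lies exactly on the fitted curve can only *lower* the best relative RMS
(the old fit remains feasible and gains an exact point), so a flagged scan
stays flagged — but a near-threshold unflagged scan can in principle
become flagged, since the mean-square residual shrinks. The test suite
asserts the provable direction.

## The synthetic-data generator

`gen_scenario()` emulates the study design the scan was built for, not
real human cohorts:

* **10 populations**, matching the ten-panel design of reference-panel
  studies; per-population $T_E$ drawn uniformly from $[1.10, 1.24]$ GEU,
  the range printed for real panels (about 1.106–1.237).
* One environmental parameter whose values span a **factor-of-five range**
  ($\lambda \in [2, 10]$, evenly spaced, shuffled across populations).
* **Null SNPs** with minor-allele frequencies uniform in $[0.02, 0.5]$,
  independent across populations — no environmental dependence.
* **Implanted SNPs** (default: 1 per 100 nulls) whose target-allele
  potential follows $\mu(\lambda) = \mu_0 + 0.1 (\lambda -
  \lambda_{min})$ GEU plus Gaussian noise of SD 0.03 GEU, inverted to
  frequencies via $p = 2^{(\check\mu - T_E - \mu)/T_E}$. Noise lives on
  the potential scale because that is where the flagging criterion
  operates; the defaults bracket the relative-RMS regime (0.03–0.06) the
  method is meant to flag. Draws below the fixing potential are resampled
  (bounded retries, logged).
* **One haploblock per implant, in the lowest-**$\lambda$ **population
  only** (3 SNPs, linkage strength 0.95), emulating the pattern where only
  the least-exposed population retains the block's correlated variation.
  The haplotype distribution interpolates between the product of marginals
  and the comonotone maximal-linkage coupling, which preserves marginals
  exactly at every strength. Crucially, the implanted curve is a statement
  about the potential the scan *observes*: in the linked population that
  is the distributed allelic potential, so the generator solves (1-D root
  find) for the marginal frequency whose distributed potential lands on
  the noisy curve value. Without this, the binding shift of the linked
  point would bias the recovered force by about $-0.01$ GEU/unit
  systematically.
* $T_E$ values are generator *inputs*, not recomputed from the synthetic
  genomes — mirroring how the analysis consumes them; the
  `entropy_profile()` path (NIC $\to T_E$) is exercised separately on
  small frequency sets.

What a green test on this generator does **not** establish: realism of
demography, drift, or selection dynamics (no coalescent model), realism of
environmental measurement error, or any claim about real loci. It
establishes that the pipeline's algebra is self-consistent and that the
scan recovers implanted dependencies of the stated size (slope 0.1 GEU per
$\lambda$ unit, noise 0.03 GEU, 10 populations) with the stated
reliability.

## Known limitations

* Bi-allelic SNPs only; multi-allelic records are skipped and counted.
* Haplotype frequencies come from phased genotypes by direct counting — no
  EM phasing, no imputation.
* Block *detection* (`detect_blocks()`) is a deliberately simple greedy
  adjacent-$r^2$ merge (default threshold 0.8) provided for completeness;
  externally supplied block definitions always take precedence, since the
  block inference used for real panels is upstream of this package.
* Whole-genome $T_E$ recomputation at reference-panel scale is supported
  in principle by the same operations but not exercised at that scale.
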