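Package: genodyn
Title: Information-Theoretic Genomic Potentials and Environmental Association Scanning
Version: 0.1.0
Authors@R: person("Genodyn", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes information-theoretic potentials for population genomic
    variants (allelic, SNP, haplotype, haploblock, and linkage-distributed
    potentials, all expressed in genomic energy units) from per-population
    bi-allelic allele frequencies, scans those potentials across populations
    for smooth functional dependencies on quantified environmental parameters,
    flags dependencies by a relative root-mean-square criterion, and reports
    adaptive forces as negative potential gradients.  Includes a synthetic-data
    generator emulating a ten-population study design with implanted
    potential-environment relationships, VCF/TSV ingestion, and a command-line
    pipeline with reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    data.table,
    GenomeInfoDb,
    jsonlite,
    S4Vectors,
    stats,
    SummarizedExperiment,
    tools,
    utils,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
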