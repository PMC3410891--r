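Package: vargwas
Title: Variance-Heterogeneity Genome-Wide Association Scans for Inbred Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome scans for variance-controlling loci (vGWAS) in panels of
    fully homozygous lines. Implements the per-marker Brown-Forsythe
    (Levene-type, median-centred) test of variance heterogeneity alongside a
    Wilcoxon rank-sum scan for mean effects, genomic control of the resulting
    one-degree-of-freedom chi-square scores by zero-intercept regression on
    null quantiles or by the median ratio, and a single-locus decomposition of
    the phenotypic variance into a mean-shift component and a
    variance-heterogeneity component (h2_m and h2_d) with the closed-form
    low-variance-allele frequency that maximises both. Includes rank-based
    candidate-gene enrichment across scans, a synthetic-data generator for
    inbred biallelic populations with optional Balding-Nichols population
    structure, power and false-positive-rate simulation studies, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    vcfR,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
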