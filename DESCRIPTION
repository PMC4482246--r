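Package: genemeta
Title: Genetic-Model Meta-Analysis of Case-Control Genotype Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meta-analysis of candidate-SNP case-control association studies
    starting from per-study genotype counts. Collapses the three genotype
    classes into the five classical genetic-model contrasts (homozygous,
    heterozygous, recessive, dominant and allele comparison), computes crude
    odds ratios with Woolf confidence intervals, and pools them by
    Mantel-Haenszel fixed effects or DerSimonian-Laird random effects with
    Cochran's Q heterogeneity. Includes Hardy-Weinberg equilibrium screening
    of control genotypes, subgroup and leave-one-out sensitivity analysis,
    Egger and Begg publication-bias tests, funnel- and forest-plot data
    export, and a genotype-count simulator with known per-allele effects for
    parameter-recovery experiments. Ships the genotype counts of two
    published PSCA polymorphism meta-analyses (rs2294008, rs2976392) as a
    worked fixture.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
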