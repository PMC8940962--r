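Package: nitromat
Title: Millimeter-Scale Nitrogen-Cycling Analysis of Microbial Mat Depth Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for gene-centric analysis of vertical nitrogen cycling in
    laminated microbial mats sampled at 1-mm resolution. Implements dual-basis
    normalization of qPCR/RT-qPCR gene and transcript copy numbers with
    cDNA/DNA expression ratios and nonparametric layer comparisons
    (Kruskal-Wallis, Conover-Iman, compact letter displays); nitrogen-focused
    coverage-per-million (N-CPM) and fraction-of-depth-integrated-coverage
    (FDIC) normalizations of metagenome gene coverage with pathway accounting
    and depth-trend summaries; PRIMER-style multivariate layer statistics
    (Bray-Curtis resemblance, group-average clustering with SIMPROF
    permutation tests, non-metric multidimensional scaling with Spearman
    vector overlays); and active-site motif plus neighbor-joining phylogenetic
    classification of hydroxylamine dehydrogenase (HAO) family proteins.
    A synthetic-data module generates all pipeline inputs with known ground
    truth so every stage can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    ape,
    Biostrings,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
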