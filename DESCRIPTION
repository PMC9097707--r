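Package: clonemeth
Title: Transgenerational DNA Methylation Analysis for Clonal Daphnia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential DNA methylation analysis of whole-genome bisulfite
    CpG counts in clonal Daphnia exposed to environmental stressors, with
    transgenerational persistence calling across generations F1, F2 and F4.
    Implements beta-binomial Wald tests with empirical-Bayes dispersion
    shrinkage and a logistic-regression alternative, per-generation
    Benjamini-Hochberg correction, three-generation DMP intersection with
    permutation-based validation (whole-analysis label shuffling and
    CpG-set overlap resampling), positional and GO-term annotation of DMPs,
    and Euler-Lotka fitness estimation from brood records. A synthetic-data
    generator with planted, persistence-controlled DMPs provides
    ground-truth recovery testing without any sequencing download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
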