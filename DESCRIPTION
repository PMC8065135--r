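Package: epimyo
Title: Integrative Methylome-Transcriptome Analysis of Muscle Stem Cell
    Differentiation in Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("epimyo", "maintainers", email = "epimyo@example.org",
           role = c("aut", "cre"))
Description: Reusable, tested implementation of an integrative epigenomic
    analysis of paired human myoblast/myotube cohorts (normal glucose
    tolerance versus type 2 diabetes): covariate-adjusted differential
    expression, paired Wilcoxon signed-rank methylation dynamics with
    opposite-direction site detection, methylation-expression correlation
    screening with genomic-context enrichment, candidate-gene
    prioritization, preranked gene-set enrichment, GO search-term
    frequency enrichment, and promoter motif (PWM) enrichment. Includes a
    synthetic cohort generator with planted ground truth for calibration
    and power checks, plus readers and writers for the plain-text formats
    involved (TSV matrices, sample sheets, probe manifests, GMT, JASPAR
    PFM, FASTA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
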