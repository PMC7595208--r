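Package: promusage
Title: Alternative-Promoter Usage from Splice-Junction Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies alternative 5'-exon (alternative-promoter) usage of a
    multi-promoter gene locus from per-sample splice-junction read counts.
    Junction tables (STAR SJ.out.tab dialect or generic TSV) are filtered,
    normalized to junctions per million spliced reads, and aggregated to
    5'-exon events and protein-isoform groups via a curated junction
    annotation. Two-tier differential-usage statistics compare disease and
    control groups: within-experiment Mann-Whitney U tests with
    Benjamini-Hochberg correction, and a combined two-experiment Gamma GLM
    with Wald tests. Companion tools classify promoters as focused or
    dispersed from transcription start site positions, analyse
    dual-luciferase reporter assays (repeated-measures ANOVA with
    Greenhouse-Geisser correction and Dunnett's test), and simulate
    negative-binomial junction datasets with known ground truth so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    mvtnorm,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
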