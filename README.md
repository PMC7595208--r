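# promusage

Quantification of **alternative-promoter (alternative 5′-exon) usage** from
splice-junction read counts, with the two-tier differential statistics used
to compare disease and control cohorts. The package was built around the
*TCF4* locus — a multi-promoter gene whose intronic CTG trinucleotide-repeat
expansion causes Fuchs' endothelial corneal dystrophy (FECD) — but every
step is generic: any locus whose first exons are distinguished by the splice
junction joining them to an internal acceptor exon can be analysed the same
way.

## Who it is for

Transcriptomics analysts who already have per-sample splice-junction tables
(STAR `SJ.out.tab` files or a generic junction TSV) and want per-event,
per-isoform-group usage estimates plus defensible two-cohort statistics,
without read-level realignment or EM-based isoform deconvolution.

## The method

**Quantification.** Junctions are filtered per dataset (mitochondrial
junctions and non-canonical intron motifs removed; dataset-wide support
< 6 reads removed; in-gene junctions additionally need ≥ 4 dataset-wide
reads) and normalized to junctions per million spliced reads:

```
jpm(j, s) = count(j, s) / Σ_j' count(j', s) × 10⁶
```

with the denominator fixed genome-wide after dataset filtering. Extended 5′
exons (transcription reading straight into an internal exon, so no junction
exists) are counted as reads whose aligned block covers both bases of a 2-bp
window immediately transcript-upstream of the internal exon. Junction-level
values are summed to 5′-exon *events* (`"4aI-4"` = 5′ exon 4aI spliced to
internal exon 4) and to protein *isoform groups* (TCF4-A…I).

**Differential usage.** Two tiers, as is standard for a two-cohort,
two-experiment design:

1. *Within experiment*: Mann–Whitney U on CTRL vs FECD jpm values per event
   (exact p for these group sizes when tie-free), Benjamini–Hochberg FDR
   across the event family within each experiment.
2. *Combined*: per event, a Gamma GLM on the pooled data,
   `jpm + 0.01 ~ Experiment + Disease + Experiment:Disease`
   (inverse link by default), Wald test of the Disease coefficient, BH
   across the family.

**Companion analyses.** Promoter TSS sets are classified focused vs
dispersed (spread ≥ 100 bp and ≥ 3 distinct starts) and checked for whether
any start would place the repeat tract in a transcript's 5′ UTR.
Dual-luciferase reporter series are normalized (firefly/Renilla, then
relative to the 11-repeat construct per experiment) and tested with one-way
repeated-measures ANOVA with Greenhouse–Geisser correction followed by
Dunnett's many-to-one test against the 11-repeat control.

**Simulator.** `simulate_dataset()` generates the full study design — two
experiments (6/8 and 9/6 CTRL/FECD samples), negative-binomial junction
counts over a TCF4-like demo gene model, per-sample library sizes of 1–3
million spliced reads, decoy junctions that exercise every filter branch,
and a disease profile (proximal events down, distal 5′ exons up, some flat)
— with ground truth attached, so the entire pipeline is testable offline.

## Worked example

```r
library(promusage)
library(dplyr)

sim    <- simulate_dataset(sim_config(seed = 42))   # two cohorts, 29 samples
quants <- quantify_simulated(sim)                   # filter + jpm + aggregate
res    <- combined_analysis(lapply(quants, `[[`, "events"), sim$meta)

res |>
  filter(row_id %in% c("4aI-4", "4c", "3c-3")) |>
  select(row_id, experiment, U, p, q, glm_coef, wald_q, direction_combined)
#> # A tibble: 6 × 8
#>   row_id experiment     U        p        q glm_coef   wald_q direction_combined
#>   <chr>  <chr>      <dbl>    <dbl>    <dbl>    <dbl>    <dbl> <chr>
#> 1 3c-3   2019          22 0.852    1        -0.00359 0.863    up
#> 2 3c-3   2020          11 0.0663   0.0840   -0.00359 0.863    up
#> 3 4aI-4  2019          48 0.000666 0.00158   0.126   0.000319 down
#> 4 4aI-4  2020          54 0.000400 0.000690  0.126   0.000319 down
#> 5 4c     2019          10 0.0813   0.110    -0.0314  0.0806   up
#> 6 4c     2020           0 0.000400 0.000690 -0.0314  0.0806   up
```

Reading this: event `4aI-4` (a 5′ exon immediately downstream of the repeat
tract) is strongly reduced in FECD in both experiments — extreme U
statistics, exact Mann–Whitney p ≈ 4×10⁻⁴ at 9 vs 6 samples, and a combined
Wald q ≈ 3×10⁻⁴ with a positive inverse-link coefficient (higher 1/µ =
lower mean). The flat control event `3c-3` is not significant anywhere, and
the extended exon `4c` trends up, reaching within-experiment significance in
the larger-control 2020 cohort. `glance(res)` summarises: 19 events tested,
13 significant at Wald q < 0.05.

The reporter tier works the same way:

```r
ra <- analyze_reporter(simulate_reporter(seed = 42))
ra$dunnett |> filter(condition == "144")
#> # A tibble: 2 × 6
#>   promoter condition estimate statistic    df      p_adj
#> 1 p4a      144         -0.710     -9.31    10 0.00000634
#> 2 p4abc    144         -0.785     -6.87    10 0.000153
```

i.e. the 144-repeat construct reduces relative promoter activity by ~71%
and ~79% in this simulation, Dunnett-adjusted p ≪ 0.05 against the
11-repeat control.

`plot_usage()`, `autoplot()` on a `usage_difftest`, and `plot_reporter()`
give the corresponding ggplot2 figures; `tidy()`/`glance()` methods cover
the fitted objects.

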