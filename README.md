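# paralogdiv

Human paralogs arise either from small-scale duplication (SSD) of
individual genes or as ohnologs retained from the two rounds of
whole-genome duplication (WGD) in early vertebrate evolution. Because the
two event types perturb the genome differently — a WGD duplicates every
interaction partner at once, an SSD unbalances its network — the two
duplicate classes are expected to diverge differently. `paralogdiv` is an
analysis pipeline that quantifies those differences for anyone studying
duplicate-gene evolution: shared Gene Ontology annotation between the
members of a pair, subcellular colocalization, tissue expression-profile
correlation, ortholog-based evolutionary rate, multifunctionality, and
the proportions of essential and disease-associated genes.

At its core are four quantities:

- the Dice coefficient of two genes' GO term sets,
  `sim(i,j) = 2 |T_i ∩ T_j| / (|T_i| + |T_j|)`, computed separately for
  the biological-process, molecular-function and cellular-component
  domains;
- the Pearson correlation `r` of two genes' expression profiles across a
  panel of ≥ 27 normal tissues;
- gene-level dN and dN/dS against one-to-one mouse and chimp orthologs
  (records with dS ≥ 3 discarded as saturated), compared between genes
  having only SSD paralogs and genes having only WGD paralogs;
- the pooled two-proportion Z statistic
  `z = (p1 − p2) / sqrt(p̄(1−p̄)(1/n1 + 1/n2))` for essentiality and
  disease-association enrichment.

Pair-level contrasts are stratified into five dN bins
(`[0,0.1), [0.1,0.2), [0.2,0.3), [0.3,0.4), [0.4,∞)`) so SSD and WGD
pairs are compared at matched sequence divergence, and each stratum is
tested with a two-tailed Mann–Whitney U test. Because the original input
databases require live extractions, the package ships a seeded generator
(`synthetic_config()` / `generate_dataset()`) that emulates the joint
statistical structure of all five input tables with configurable
per-class effect sizes.

## Worked example

```r
library(paralogdiv)

ds <- generate_dataset(synthetic_config(seed = 1))  # 5000 pairs per class
report <- run_full_analysis(ds)
print(report)
```

```
<analysis_report>
  overall metric comparisons (SSD vs WGD):
    BP_similarity        0.709 (n=6988) vs 0.417 (n=7012), p < 1e-06
    CC_colocalization    0.779 (n=6988) vs 0.536 (n=7012), p < 1e-06
    MF_similarity        0.844 (n=6988) vs 0.660 (n=7012), p < 1e-06
    expression_r         0.404 (n=6988) vs 0.194 (n=7012), p < 1e-06
  chimp orthologs: mean dN 0.0120 vs 0.0060, mean dN/dS 0.478 vs 0.255
  mouse orthologs: mean dN 0.0874 vs 0.0607, mean dN/dS 0.136 vs 0.101
  essential: 4.77% of 9976 SSD-only vs 11.19% of 10024 WGD-only, Z = -16.75
  disease: 27.42% of 9976 SSD-only vs 62.05% of 10024 WGD-only, Z = -49.25
```

Reading this: SSD pairs share more annotation than WGD pairs in every GO
domain (e.g. mean BP Dice 0.709 vs 0.417) and are more strongly
co-expressed (mean r 0.404 vs 0.194); WGD-only genes evolve more slowly
against both outgroups (lower dN and dN/dS) and are enriched for
essential and disease genes (negative Z = SSD proportion below WGD). The
per-bin breakdown, exclusion accounting and provenance hashes live in
`report$binned`, `report$exclusions` and `report$provenance`;
`write_report(report, dir)` serialises everything as TSV plus a JSON
summary.

The same statistics are available directly, e.g. the Z test on published
group proportions:

```r
two_proportion_z(0.04601, 2692, 0.11344, 5730)
#> <proportion_test> p1 = 0.0460 (n = 2692) vs p2 = 0.1134 (n = 5730): Z = -9.990, p = 1.69e-23
```

## The analysis workflow

The `analysis/` directory holds the narrative drivers, each a thin script
over the package functions, writing its tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generates the study dataset and writes the five input TSVs |
| `02_main_analysis.R` | runs the full pipeline; writes the comparison tables |
| `03_robustness.R` | closest-pair-only, stricter identity thresholds, old-SSD-only variants |
| `04_null_calibration.R` | 20 null seeds; checks per-bin tests reject at ~5% |

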