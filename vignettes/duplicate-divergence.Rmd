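---
title: "Comparing small-scale and whole-genome duplicate gene pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing small-scale and whole-genome duplicate gene pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Human paralogs come from two very different kinds of event. Small-scale
duplication (SSD) copies one or a few genes and happens continuously;
whole-genome duplication (WGD) pairs — ohnologs — trace back to the two
rounds of genome duplication in early vertebrate evolution. Because a WGD
duplicates every interaction partner simultaneously while an SSD unbalances
its network's stoichiometry, the two duplicate classes are expected to
diverge differently. `paralogdiv` implements the comparative analysis that
quantifies this across six axes: shared Gene Ontology annotation in the
biological-process and molecular-function domains, shared cellular
component (subcellular colocalization), tissue expression-profile
correlation, ortholog-based evolutionary rate, multifunctionality, and the
proportions of essential and disease-associated genes.

A central confounder is sequence divergence itself: WGD pairs are ancient,
so they have higher dN (nonsynonymous substitutions per nonsynonymous
site) than a typical SSD pair, and annotation overlap decays with dN. All
pair-level contrasts are therefore stratified into five dN bins —
`[0, 0.1)`, `[0.1, 0.2)`, `[0.2, 0.3)`, `[0.3, 0.4)`, `[0.4, Inf)` — so
that SSD and WGD pairs are compared at matched sequence divergence.

## The measures

**Shared-annotation similarity.** For genes $i, j$ with term sets in one
GO domain, the Dice coefficient

$$\mathrm{sim}(i,j) = \frac{2\,|T_i \cap T_j|}{|T_i| + |T_j|}$$

is 1 for identical annotation and 0 for disjoint annotation. Term sets are
used exactly as annotated — no ancestor propagation — because the input
tables are flat Biomart-style exports; `score_all_pairs()` exposes a
`propagate` hook for callers who want to expand sets first. A pair in
which either gene has no annotation in the domain is *excluded* from that
metric with a logged reason, not scored zero: absence of annotation is
missing data, and zero-filling would deflate group means by annotation
coverage rather than biology.

**Expression correlation.** The Pearson product-moment correlation of the
two genes' expression profiles across a panel of normal tissues (27 by
default). It is computed in the centred two-sum form, which is
algebraically identical to the raw-sums textbook formula but numerically
stable; the equivalence is asserted in the test suite. Profiles constant
across tissues have undefined correlation and are excluded with a logged
reason, as are genes with no profile.

**Evolutionary rate.** Gene-level, not pair-level: each human gene's dN
and dN/dS against a one-to-one ortholog in an outgroup (mouse and
chimpanzee under the defaults), compared between genes whose paralogs are
*all* SSD ("SSD-only") and genes whose paralogs are all WGD ("WGD-only").
Genes with paralogs of both kinds are excluded from every gene-level
analysis, because they cannot be attributed to either class. Records with
dS ≥ 3 are discarded as mutationally saturated. A record with dS = 0
keeps its dN but contributes no ratio — discarding the whole gene would
throw away valid dN evidence to fix a division problem.

**Importance.** Essentiality and disease association are binary gene
flags; the SSD-only vs WGD-only contrast is a pooled two-proportion Z
test,

$$z = \frac{p_1 - p_2}{\sqrt{\bar p(1-\bar p)(1/n_1 + 1/n_2)}},
\qquad \bar p = \frac{p_1 n_1 + p_2 n_2}{n_1 + n_2},$$

which accepts proportions directly (published analyses print rounded
proportions, not counts; feeding the printed proportions back reproduces
the printed Z values to two decimals, which the acceptance tests check).
Multifunctionality is the count of unique GO biological-process terms per
gene, with Pfam domain count as a structural proxy.

**The test.** Distributional comparisons use the two-tailed Mann–Whitney U
test. U is computed by midrank rank-sum. For combined samples of at most
12 values without ties the two-tailed p is exact (twice the smaller tail
of the null U distribution, capped at 1); otherwise the normal
approximation with tie correction and continuity correction is used. Group
*means* are reported alongside for display, as is conventional, but the
test is rank-based. No multiple-testing correction is applied across bins
— per-stratum raw p-values are the reported quantity — and p-values below
`p_floor` (default 1e-6) are only *displayed* as a bound; stored values
stay numeric.

## Assembly rules and their edge cases

* **Origin labelling.** The WGD reference list is authoritative: a pair on
  it is WGD even at low identity (ohnolog calls rest on synteny-aware
  evidence, not pairwise identity). Every other pair is SSD iff its
  percent identity clears the threshold, *inclusively* (≥ 50 by default,
  matching the usual export-filter convention).
* **dN bins are half-open** with the last bin unbounded, so bin counts sum
  exactly to the filtered total; dN = 0.1 falls in `0.1-0.2`.
* **Pairs are unordered and counted once.** Published tabulations of this
  design sometimes count each pair in both orientations (all-even group
  sizes are the telltale); `mirror_pairs = TRUE` reproduces that
  convention, doubling every N without changing means.
* **Closest-pair robustness.** Each gene nominates its minimum-dN pair
  within each origin class (dN is the divergence axis throughout;
  identity is only a tie-break, then lexicographic partner id), and a pair
  survives if nominated by at least one member. This controls for large
  gene families dominating the pair-level averages.
* **Young/old SSD split.** A pair is young when *both* members' phylostratum
  rank exceeds the threshold (rank 1 = oldest). The threshold has no
  canonical value and must be supplied; the analysis scripts use 10 of the
  generator's 16 SSD strata.

## What the generator emulates

`synthetic_config()` encodes the study conditions; `generate_dataset()` is
a pure function of the config (seed included). Per origin class it
controls: the mean Dice similarity per GO domain, the mean pairwise
expression correlation, the pair dN distribution, the dS/dN multiplier,
essentiality and disease rates, ortholog dN and dN/dS means per outgroup,
mean annotation-set sizes, and Pfam domain means. The shipped defaults are
the published group-level values this pipeline is calibrated against:
Dice 0.710/0.415 (BP), 0.840/0.659 (MF), 0.782/0.541 (CC); expression r
0.403/0.193 over the 27-tissue normal panel; essentiality 4.601%/11.344%;
disease 27.89%/61.46%; mouse ortholog dN 0.089/0.062 and dN/dS
0.135/0.101; chimp 0.012/0.006 and 0.480/0.257; BP term-count means 5/10;
Pfam means 1.61/2.02; 5000 pairs per class.

Construction choices that matter:

* **Annotation overlap** is generated by giving both genes of a pair the
  same term count $n = 1 + \mathrm{Poisson}(\mu - 1)$ and a shared count
  $s \sim \mathrm{Binomial}(n, d)$, so the expected Dice equals the target
  $d$ *exactly* for any $d \in [0,1]$, including the boundary $d = 1$
  (identical sets). Unequal set sizes within a pair would make some
  targets infeasible; equal sizes trade a little realism for an exactly
  calibrated mean. No GO graph is simulated — the analysis consumes flat
  term sets, so a DAG would add nothing testable.
* **Expression** is a latent bivariate normal per tissue, shifted by
  `expr_location` and scaled by `expr_scale`, then clamped at zero and
  rounded to 4 decimals. The defaults (8 and 1.5) make clamping
  negligible, so the monotone shift preserves Pearson r. The latent
  correlation carries the small-sample adjustment
  $\rho' = \rho + \rho(1-\rho^2)/(2(N-1))$ because the sample correlation
  over $N$ tissues is biased low by that amount; without it the mean
  recovered r would sit just under the target.
* **dN** is gamma per origin (shape 1.8, mean 0.25 for SSD; shape 2.2,
  mean 0.55 for WGD), which populates all five bins in both classes at the
  default sample sizes while placing the WGD mass higher — the older
  duplicate class is the more diverged one. dS is dN times
  `min + gamma`, so dS ≥ dN whenever `min ≥ 1`. Dispersions are free
  parameters: the calibration targets are group means, and no published
  dispersions exist to match.
* **Both-origin genes.** With probability `frac_both` (default 0.2,
  roughly the observed fraction of duplicated human genes carrying both
  pair types) a base gene acquires an extra pair of the opposite origin,
  built with that origin's Dice and correlation targets against the
  existing gene. Importance flags are only assigned to single-origin genes,
  which is exactly the population the gene-level analyses use. One known
  side effect: the cross-pair partner inherits the base gene's
  annotation-set *size*, so with `frac_both > 0` the gene-level mean term
  counts of the two classes shrink toward each other (the pair-level Dice
  targets are unaffected). Gene-level term-count recovery is therefore
  checked with `frac_both = 0`.
* **Identity** is uniform on 50–99% for SSD (the class is defined above
  the threshold) and 30–99% for WGD; ortholog dN is gamma (shape 2) around
  the per-origin mean with dS derived via a gamma-distributed dN/dS ratio
  (shape 8), so the ratio's mean recovers the configured dN/dS.

What the generator does **not** emulate: real GO term co-occurrence
structure, tissue-specific expression biology, gene-family size
distributions (each base gene has one base pair), identity–dN coupling,
and outgroup-specific ortholog availability. Green tests therefore
demonstrate that the *pipeline* measures what it claims under a known
joint distribution — parameter recovery, correct test calibration,
conservation of records — not that real Ensembl/HPA/OGEE/HGMD extractions
would yield any particular value.

## Numerical and degenerate-input conventions

Empty annotation sets and constant expression profiles: excluded, logged,
never zero-filled. Missing dN: pair excluded from binned analyses,
counted. A bin empty in one group: row emitted with the test marked not
applicable. Zero-variance Z test (pooled proportion 0 or 1): a classed
degenerate error. Mann–Whitney with every value tied: p = 1. All
exclusions accumulate into the report's `exclusions` table, and the tests
assert the reconciliation `analyzed + excluded = input` at every stage.
All analysis-path code is deterministic; the only randomness in the
package is in `generate_dataset()`.

## Problem sizes

The test suite exercises the generator at 200–2000 pairs per class for
module-level properties, the full shipped configuration (5000 per class)
for end-to-end recovery and directionality, and 20 seeds of 600 pairs per
class for the null-calibration check that per-bin tests reject at about
the nominal 5% rate when the two classes are generated identically. The
`analysis/` scripts run the same stages at the shipped scale and write
their tables under `results/`.

## Limitations

The pipeline consumes pre-reconciled gene identifiers; it does not resolve
cross-database id mappings, recompute dN/dS from sequences, or infer
ohnolog status (the WGD reference list is an input). GO evidence codes are
not filtered — all provided terms are used. The two-proportion Z test
assumes independent genes; paralogs violate independence mildly, as they
do in the published analyses this mirrors.
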