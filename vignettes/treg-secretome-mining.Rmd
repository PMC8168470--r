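---
title: "Mining Treg transcriptomes and secretomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining Treg transcriptomes and secretomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tregmine)
```

## The problem

Regulatory T cells (Tregs) adapt their transcriptional programs to the
tissue they sit in: normal lymphoid and non-lymphoid tissues, injured or
fibrotic tissue, tumor-bearing spleens, and tumors themselves. A recurring
analysis pattern in this literature compares CD4+Foxp3+ Tregs against
conventional CD4+Foxp3− T cells (Tconv) dataset by dataset, and then asks
set-algebra questions of the resulting differentially expressed gene (DEG)
lists: how many DEGs encode secreted proteins (and through which secretion
route), which signaling pathways the DEGs activate or inhibit, how much of
the Treg program is attributable to master regulators (Foxp3, CTLA-4,
PD-1), and how much is shaped by reactive oxygen species (ROS).

`tregmine` implements that workflow as a tested, reusable pipeline. Every
stage takes and returns ordinary tibbles so results chain with the pipe,
and a synthetic-data generator with planted ground truth makes the whole
pipeline verifiable end to end without downloading any external dataset.

## DEG calling

Each dataset is a genes × samples matrix with case (Treg) and control
(Tconv) arms. Arrays are tested on log2 intensities directly; RNA-seq
counts are normalized to counts per million and transformed
`log2(CPM + 0.5)` first. The per-gene test is the Welch unequal-variance
t-test; a pooled-variance mode is available but not the default, since
small-replicate expression arms rarely justify equal-variance assumptions.
The calling rule is threshold-based:

* up: `log2FC > 1` and `p < 0.05`
* down: `log2FC < −1` and `p < 0.05`
* otherwise non-significant.

Both comparisons are strict ("more than 2-fold"); genes sitting exactly on
a boundary are not called. `deg_thresholds(strict = FALSE)` switches to
inclusive boundaries for users whose upstream tools used `>=`. The raw
p-value is thresholded — this mirrors the GEO2R-style screening practice
the pipeline reproduces — while Benjamini–Hochberg q-values are reported
alongside for information only.

Housekeeping QC guards each contrast: nine stably expressed genes (ACTB,
GAPDH, PGK1, PPIA, B2M, YWHAZ, SDHA, HMBS, TBP) must have log2 fold
changes inside a tolerance band, `(-1.3, 1.3)` by default. The band is a
configurable QC rule, wide enough to accommodate the fold-change spread
such genes show in practice across heterogeneous platforms. Housekeeping
genes absent from a platform are reported missing, not failing.

## Catalogs and decomposition

Four secretome catalogs represent the known secretion routes: the
canonical signal-peptide/ER–Golgi secretome (2,641 genes), the caspase-1–
gasdermin-D-dependent (961) and caspase-4–dependent (1,223) non-canonical
secretomes, and the exosome-carried secretome (6,560). The four are
pairwise disjoint by construction and union to 11,385 genes. Three
screening panels (191 immunometabolism enzymes, 102 trained-immunity
enzymes, 165 ROS-regulatome genes) may overlap the secretomes, as real
enzyme panels do. Catalogs are exchanged as GMT; the real curated lists
are not redistributed — users supply their own GMT, and the synthetic
generator produces catalogs of exactly the published sizes for testing.
(The literature prints both 2,640 and 2,641 for the canonical list; the
catalog size is treated as data here and the synthetic default is 2,641.)

Symbols are matched on a shared canon — trimmed, upper-cased, no
orthology mapping — so mouse `Il6` and human `IL6` intersect, exactly as
plain list intersections do in the source workflow.

`decompose()` intersects a contrast's up/down DEG lists with a catalog and
reports percentages **of the contrast's total DEG count** (up + down over
all genes). That denominator, and rounding half away from zero to 2
decimals, are the conventions that reproduce the published per-dataset
table cells exactly (e.g. 356 exosome up-DEGs of 1,584 total DEGs →
22.47%; 86/2,608 → 3.30%). Half-to-even rounding happens to agree on
every checked cell, but half-away-from-zero is what `percent()`
implements and documents.

## Pathway activation calls

The pathway layer re-implements the *calling algorithm* of commercial
enrichment suites on user-supplied signatures; the proprietary knowledge
bases (and hence the published pathway *names*) are deliberately out of
scope. A signature is a gene set whose members carry an expected
regulation direction (+1 / −1 / 0 = unknown). For one contrast:

* overlap enrichment: hypergeometric upper tail `P(X ≥ k)` with the
  universe defined as the genes measured in that dataset (standard
  enrichment practice, and the only defensible default);
* activation z-score: over DEG members with nonzero expected direction,
  `z = (c − d) / √(c + d)` where `c` counts sign-consistent and `d`
  sign-opposite members. Direction-unknown members count toward `k` but
  not toward `z`;
* call: activated if `p < 0.05` and `z ≥ 2`, inhibited if `p < 0.05` and
  `z ≤ −2`, else not called. The p boundary is strict and the z boundary
  inclusive, matching the stated cutoffs.

Group accounting labels each pathway called at least once in a dataset
group: *shared* (≥ 2 datasets, consistent sign — the 2 is configurable),
*specific* (exactly one dataset), *dual* (called in opposite directions
within the group). The three labels partition the called set, and
cross-group overlaps are plain set algebra per direction.

## Regulator collaboration quadrants

A regulator perturbation contrast (Foxp3 knockout, anti-CTLA-4 or
anti-PD-1 blockade vs control) is compared with each Treg contrast under a
fixed polarity convention: a gene *down* in the perturbation is a
candidate regulator-induced gene, *up* a candidate regulator-suppressed
gene (blockade shares the knockout convention). Treg-up ∩ perturbation-
down genes are *induced*, Treg-down ∩ perturbation-up are *suppressed*,
and every other Treg DEG is *non-collaboration* by its Treg direction.
Two genuinely open design points are resolved explicitly:

* same-direction overlaps (Treg-up ∧ perturbation-up) are classified
  non-collaboration — the source definitions name only the two
  cross-direction quadrants and a "not overlapped" remainder;
* Treg DEGs unmeasured in the perturbation count as non-collaboration by
  default (indistinguishable from non-DEG in DEG-table inputs); a strict
  mode drops them from the partition and denominators instead.

Because the published non-collaboration ranges are ambiguous about their
denominator, `noncollab_fraction()` reports both conventions: percentage
of all Treg DEGs, and upregulated non-collaboration genes as a
percentage of Treg up-DEGs.

## ROS regulatome

ROS-regulated genes are defined from two knockouts with opposite effects
on ROS: NOX2 KO (less ROS) and NRF2 KO (more ROS). Genes DEG in **both**
contrasts are partitioned: up-in-NOX2-KO ∧ down-in-NRF2-KO →
ROS-promoted; the reverse → ROS-suppressed; same sign in both →
uncertain. Genes DEG in only one contrast are excluded — this reading of
"identified in both knockouts" is required for the three classes to sum
to the published total (1,384 + 936 + 10 = 2,330). The partition is
conserved (classes sum to the dual-DEG intersection) and antisymmetric
(swapping inputs swaps promoted and suppressed). Treg contrasts are then
screened against the classes by plain intersection, and the downregulated
ROS-suppressed counts compared across condition groups.

## Group statistics

All group-level claims go through one engine: per-group mean ± SEM
(sample SD / √n; single-dataset groups report SEM missing) plus a
two-sample test of a focus group (default the tumor-tissue group) against
all remaining datasets pooled. The published "±" dispersion is read as
SEM, and the unnamed test defaulted to the Welch t, with an exact
Mann–Whitney fallback recommended below n = 4 per group; every result
carries its method name. No multiple-testing correction is applied across
the handful of group comparisons (BH q is available alongside). Note one
arithmetic check made while freezing test oracles: for the values
{44, 47, 50, 52} the sample SD is exactly 3.5, so the SEM is 1.75.

## The synthetic-data generator

The generator is first-class, tested code. It emulates the structure of
the mined datasets: small replicate numbers (4 vs 4 by default — the real
per-dataset replicate counts are not printed, so this is a stated
convention), array-style Gaussian log2 intensities (baseline N(7, 2),
within-arm SD 0.5) or negative-binomial RNA-seq counts (dispersion 0.1,
library sizes log-normal around 10^6, sdlog 0.2), planted DEG fractions
(5% up + 5% down by default) with per-gene effect sizes drawn uniformly
on [1.2, 3] log2 units, planted catalog membership quotas, planted
regulator-overlap fractions, and planted dual-knockout class sizes.

Three generator properties matter for testing:

* **Exact planting.** All planted counts are `round(fraction × n)`,
  never Bernoulli draws, so truth sizes are deterministic and recovery
  tests can assert equality.
* **Seed splitting.** Randomness is split by documented offsets from the
  master seed (dataset: `seed`; regulator contrast *i*: `seed + 10000 +
  i`; dual-KO: `seed + 20000`; catalogs: `seed + 30000`; signatures:
  `seed + 40000`), so adding a later stage never perturbs earlier draws,
  and identical configs are bit-identical.
* **Characterized operating point.** At the default conditions (10,000
  genes, 5%+5% planted, mean effect 2, noise SD 0.5, 4 vs 4), the
  threshold caller's mean sensitivity over 20 seeds is ≈ 0.95 and its
  FDR ≈ 0.03; the test suite asserts the frozen bounds sensitivity
  ≥ 0.9 and FDR ≤ 0.1.

What the generator does **not** emulate: batch effects, probe-level
structure, single-cell sparsity, correlated genes, or realistic pathway
co-membership. Passing tests therefore demonstrate that the *algorithms*
are correct and their operating points hold under clean planted signal —
not that any biological conclusion transfers to a particular real
dataset.

## Numerical and degenerate-input choices

* Genes with zero variance in both arms get `p = 1` and a
  `zero_variance` flag rather than NaN.
* Zero-denominator percentages are `NA` ("missing"), never 0 or Inf.
* An empty Treg DEG list yields an empty collaboration partition with
  missing fractions; an empty DEG list in either knockout yields an
  empty ROS partition.
* `two_group_test` with zero variance in both groups and equal means
  returns `p = 1` (degenerate identity), and errors below the minimum
  group sizes.
* The end-to-end pipeline writes plain TSV/JSON and a manifest of MD5
  checksums; re-running on the same inputs is byte-identical, which the
  suite asserts.

## Worked example

```{r example}
cfg <- sim_config(seed = 7)
sim <- simulate_dataset(cfg)
ct <- compute_contrast(sim$dataset)
glance(ct)

housekeeping_qc(ct)$pass

dk <- simulate_dual_ko(sim_config(seed = 3, n_genes = 5000))
glance(classify_ros(dk$nox2, dk$nrf2))
```

Problem sizes used throughout the shipped tests and demo: 10,000-gene
simulated datasets for caller characterization, a 12,000–14,000-gene
universe for the full catalog suite, 8 demo datasets (2 per condition
group) for the end-to-end run. These sizes exercise every stage at
realistic scale while keeping a full check run comfortably fast on a
laptop.

## Known limitations

* Pathway names from commercial knowledge bases are not reproducible;
  only the calling/accounting algorithm is.
* No probe-to-gene collapsing, no empirical-Bayes variance shrinkage, no
  count-model differential expression; users wanting limma/DESeq2-style
  inference can import their own DEG tables via `read_deg_table()`.
* Symbol matching is by uppercased identity, not orthology; genes renamed
  between annotation releases will silently fail to intersect.
* The focus-vs-rest group test pools heterogeneous "other" groups; it
  reproduces the screening-style comparison, not a full ANOVA design.
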