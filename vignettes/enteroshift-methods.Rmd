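---
title: "Enterotype stability and probiotic response: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enterotype stability and probiotic response: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enteroshift)
```

This vignette documents the statistical models behind `enteroshift`, the
parameters that matter, the numerical conventions, and the design decisions
taken where the methodology was genuinely open. It is the package's own
account; every number quoted here is computed by the test suite or by
`scripts/acceptance.R`, not asserted.

## 1. Abundance model and normalization

The unit of analysis is a sample-by-genus matrix of integer read counts
with per-sample metadata (rat, dosing group `single`/`multiple`, time point,
environment `fecal`/`GMM`/`GMM_probiotic`, control flag). All inference
operates on *relative* abundances:

* **Marker panel** (`select_marker_panel`): a genus is tracked if its
  percentage reaches the threshold in at least one dataset. The default
  threshold is **0.01 %**; a stricter 0.1 % convention is in circulation for
  the same kind of analysis, so the threshold is a first-class config knob
  (`thresholds$marker_percent`) rather than a constant. Panel order is
  deterministic (descending maximum abundance, lexicographic ties).
* **Outlier masking** (`mask_outliers`): contaminating cells are supplied
  explicitly as (sample, genus) pairs and are removed from both numerator
  and denominator, so remaining genera are renormalized to 100 % and their
  mutual ratios are preserved exactly. An advisory detector
  (`flag_outliers`) lists cells exceeding 10× the genus's 95th percentile
  but never masks on its own — masking is an audit decision, not an
  automatic one.
* **Pseudocount** (`percentages(..., pseudocount = 1)`): in the
  fold-change context every zero-count panel genus receives one read before
  normalization, making all ratios finite (a genus absent from a 9,999-read
  sample becomes 0.01 %). Clustering uses `pseudocount = 0`; the zero
  handling there is part of the distance definition (below).

## 2. Enterotyping

**Distance.** Jensen–Shannon distance between renormalized rows,
`d(p, q) = sqrt(KL(p‖m)/2 + KL(q‖m)/2)` with `m = (p + q)/2`. Zeros are
replaced by a small `pseudo` on the proportion scale and rows renormalized.
Defaults: `pseudo = 1e-10` and the natural logarithm — the conventions of
the widely used reference enterotyping script — giving a metric bounded by
`sqrt(log 2) ≈ 0.8326`; base 2 is available. The metric axioms are
property-tested on random compositions.

**Clustering.** Partition around medoids on the distance matrix.
`pam_partition` solves the medoid problem *exactly* by enumeration whenever
`choose(n, k) ≤ 500` (e.g. any n ≤ 8 fixture, or the 21-sample control set
at k = 2) and otherwise uses the deterministic BUILD+SWAP search of
`cluster::pam`. The exact branch exists because BUILD+SWAP, although a
local optimum under single-medoid swaps, measurably misses the global
optimum even on 7-sample inputs; for the small matrices this package deals
in, exactness costs microseconds. Either branch is deterministic; the
`seed` argument is accepted for interface symmetry but has no effect.

**Cluster number.** The Calinski–Harabasz scan is adapted to a pure
distance setting using medoid-based dispersions:
`B = Σ_c n_c · d(m_c, m_*)²`, `W = Σ_i d(i, m_{c(i)})²`,
`CH(k) = (B/(k−1)) / (W/(n−k))`, with `m_*` the global medoid. The scan is
exploratory: enterotype grids always use k = 2, which the scan selects on
two-enterotype cohorts (checked at 21 samples).

**Stability voting.** Because cluster assignments depend on which
time-point datasets are pooled, every combination of size ≥ 2 of the
available sets is re-clustered (five sets give 10 pairs, 10 triplets,
5 quartets, 1 quintet — 26 grids). Per combination each sample gets a
silhouette score `S = (b − a)/max(a, b)` (singletons score 0) and a
harmonized label. An assignment is *true* when `S > 0.1`; the sample's call
is the label with the majority of true assignments. Ties and all-below-
threshold cases yield `unstable` rather than inheriting the prior call —
the conservative reading of a vote rule that does not specify a
tie-breaker.

**Label harmonization.** Raw PAM cluster ids are arbitrary, so each pooled
clustering is mapped onto the reference enterotypes (from clustering the
control set, larger cluster named E1) by majority overlap of its member
*control* samples with the reference partition. Combinations that pool no
control set fall back to a majority vote over the member rats' reference
enterotypes — each rat's label is that of its own control sample. This
fallback is this package's design choice; without it, combinations such as
48h_72h could not be harmonized at all. If both clusters favor the same
label, the cluster with the stronger majority keeps it.

**Ordination.** `pcoa_coordinates` is classical metric MDS
(`stats::cmdscale`); negative eigenvalues are truncated with a warning.

## 3. Paired fold-change-ratio statistics

For a pair (control, experimental) of the same lineage,
`FCR = experimental % / control %` on pseudocounted percentages. Pairing
schemes: `dosing` (each sample taken while dosing is ongoing vs the rat's
0 h control), `recovery` (post-treatment samples vs the *same* 0 h control —
the pairs share a control and are therefore not independent, which the
documentation states rather than hides), and `in_vitro` (GMM culture vs the
parallel probiotic-supplemented culture). Hand-curated pair exclusions are
supported for suspected sample swaps.

**Inclusion filter.** A pair qualifies for a genus when the percentage on
the side of the change reaches 0.01 % (experimental side for increases,
control side for suppressions); a genus is tested when ≥ 3 pairs qualify.

**Test.** `z = (mean(FCR) − 1) / (sd/√n)`, one-sided tail in the observed
direction, `p = 1 − Φ(|z|)` evaluated as
`pnorm(|z|, lower.tail = FALSE)`; the log-scale tail is carried alongside
so `−log10 p` stays finite even where p underflows double precision. The
denominator is a genuine ambiguity in the originating convention (a
spreadsheet z-score can be read as sd or sd/√n); the standard error is the
default because testing against a null parameter implies a one-sample
z-test, and `denominator = "sd"` is exposed for the other reading. FCRs are
tested on the raw ratio scale; no multiple-testing correction feeds the
headline tiers (p ≤ 0.001 / p < 0.05), matching the analysis this package
reimplements, and a Benjamini–Hochberg column is exported as advisory only.

**Known limitation — null calibration.** The z approximation is
anticonservative for small n. Two effects compound: choosing the tail by
the observed sign makes the asymptotic null exceedance of `p < 0.05` equal
to `P(|Z| > 1.645) = 0.10`, and estimating sd from n = 6 pairs widens the
tails further (`P(|t₅| > 1.645) ≈ 0.16`). `scripts/acceptance.R` measures
the realized fraction on null cohorts; users should treat the 0.05 tier as
a screening threshold, not a calibrated error rate — as in the spreadsheet
convention the method reproduces.

**Cross-context summaries.** `concordance` labels genera significant in
both contexts as `similar`/`opposite` by direction agreement;
`overlap_summary` compares an observed set intersection with the
`|A|·|B|/|U|` chance expectation and attaches an advisory hypergeometric
tail probability.

## 4. Diversity and representative taxa

Shannon H′ is computed directly from proportions (`−Σ p log p`), default
base 2; `n_taxa` counts genera with ≥ 1 read. Two-group comparisons use a
Shapiro–Wilk gate at 0.05 on each group: Student's t (pooled variance) when
both pass, Mann–Whitney otherwise; constant groups are flagged degenerate
and routed to the rank-sum branch.

Representative-taxon selection is a greedy stepwise procedure: from the
candidate pool (genera with a ≥ 2-fold change at p < 0.05 in at least one
time point), cycle through an ordered list of composition profiles
(alternating enterotypes along the time course) for five rounds, each step
taking the not-yet-selected pool genus most abundant in the current profile;
ties break lexicographically so reruns are identical. Ten profiles and five
rounds yield 50 taxa; the dominant taxon of each control profile is then
removed post hoc (48 remain with two control profiles) to stop one genus
from compressing the scale. The normalizing sector
`N(profile) = max(total) − total(profile)` pads every profile to the same
selected-taxa total so charts are directly comparable.

## 5. The synthetic cohort generator

`build_template` + `simulate_cohort` generate cohorts with the structure
the analysis assumes, plus ground truth for recovery testing:

* **Two templates** over ~220 genera in six phyla. Phylum mass targets put
  Bacteroidota + Bacillota above 50 % in both enterotypes, with B/F ratios
  2.06 (E1) and 2.1 (E2) and a Verrucomicrobiota load that is marginal in
  E1 (0.1 %) and a few percent in E2 — the discriminators the phylum
  summary is meant to pick up. Within each phylum genus masses follow a
  rank power law whose order is permuted independently per enterotype
  (dominant Bacteroidota genus pinned: Muribaculum in E1, Prevotella in
  E2), so the enterotypes are separable at the genus level.
* **Rat individuality**: each rat's baseline is a Dirichlet draw with
  concentration `rat_overdispersion × template` (default 200). The value
  reproduces visible within-enterotype individuality while keeping the
  enterotypes separable; no quantitative dispersion estimate exists for
  the system being emulated, so this is an exposed free parameter, chosen
  once.
* **Planted effects**: per (genus, enterotype, dose) log2 fold effects. A
  dose reaches full effect over the following day and then decays
  exponentially with a genus-specific half-life (persistent responders get
  half-lives ≫ 14 d; the default model mirrors lactobacilli expansion,
  bifidobacteria suppression in E2, and sign-flipped responders between
  enterotypes). Composition at time t is the baseline times
  `2^(Σ dosed effects × decay)`, renormalized; reads are one multinomial
  draw at `depth` (default 30,000 — small enough for desk-scale runs,
  deep enough that the 0.01 % thresholds are meaningfully exercised).
* **What it does not emulate**: read-level errors, chimeras, taxonomic
  misclassification, compositional interactions beyond closure, species
  resolution. Passing recovery tests therefore demonstrate that the
  pipeline's logic is sound under its own assumptions, not that real
  libraries behave this well.

A note on closure: planting a strong positive effect on abundant genera
mechanically depresses every other genus's relative abundance
(`FCR ≈ 1/Z` with Z the renormalization mass). The differential module
sees these as genuine suppressions — as any relative-abundance method
would — which is useful for exercising concordance logic but is also a
reminder that "suppressed" means *relatively* suppressed throughout.

## 6. Problem sizes and determinism

The validation suites run at the cohort scale the package targets: 21 rats
(14 E1 / 7 E2), 220 genera, depth 30,000. Recovery suites use 200 replicate
cohorts for enterotype recovery (three time-point sets per cohort, vote
over their 4 pooled combinations) and for planted 4-fold effect detection
(6 pairs), and ≥ 2000 genus-groups for the null calibration; the full suite
completes in about two minutes on one core. Every random draw flows from a
single integer seed (`config$seed`): templates, rat baselines and
multinomial sampling; clustering and selection are deterministic by
construction (exact enumeration or deterministic heuristics, lexicographic
tie-breaks). Re-running the pipeline with the same config and seed
reproduces every tabular output byte for byte, which the acceptance script
verifies on each run.

## 7. Degenerate inputs

* A sample with zero unmasked reads, or a fully masked sample, is an error
  (`degenerate-sample`), never silently dropped.
* Constant FCR vectors (sd = 0) are flagged `degenerate` with p omitted.
* Combinations pooling fewer than 4 samples are skipped with a warning and
  recorded in the grid's `skipped` field.
* A candidate pool too small for the requested selection raises a
  `short_selection_error` carrying the partial result; the pipeline instead
  falls back to ranking all panel genera and records a warning in the run
  report.
* `Bacillota = 0` yields an infinite B/F sentinel rather than an error.
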