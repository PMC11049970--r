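# enteroshift

Enterotype stability and probiotic response analysis for genus-level
16S read-count tables.

## The problem

Gut microbiomes of laboratory rats (as of humans) fall into discrete
compositional clusters — *enterotypes* — distinguished by their dominant
taxa and by the Bacteroidota/Bacillota percentage ratio (the **B/F ratio**).
In probiotic dosing studies (lactobacilli + bifidobacteria given once or on
three consecutive days, fecal samples collected at 0 h, 24 h, 48 h, 72 h and
14 d), two questions recur:

1. **Is a sample's enterotype assignment stable**, and does dosing shift it?
   Cluster calls depend on which time-point datasets are pooled before
   clustering, so a single partition is not trustworthy.
2. **Which genera respond to the probiotic**, in which direction, and do the
   responses agree between enterotypes, or between in vivo and ex vivo
   (gut-microbiota-medium, GMM) cultures?

`enteroshift` implements the full analysis pipeline for these questions,
plus a Dirichlet-multinomial cohort simulator with planted ground truth used
to validate every stage.

## Methods at a glance

* **Marker panel** — genera reaching an abundance threshold (default 0.01 %)
  in at least one dataset; percentages are renormalized after masking
  hand-flagged outlier cells, and a one-read pseudocount keeps ratios finite.
* **Enterotyping** — Jensen–Shannon distance
  `d(p,q) = sqrt(KL(p‖m)/2 + KL(q‖m)/2)`, `m = (p+q)/2`, fed to
  partition-around-medoids (PAM, k = 2); the cluster number is checked with a
  medoid-based Calinski–Harabasz scan
  `CH = (B/(k−1))/(W/(n−k))`.
* **Stability voting** — every pooled combination of the five time-point
  datasets (10 pairs, 10 triplets, 5 quartets, 1 quintet) is re-clustered;
  a sample's assignment counts as *true* when its silhouette score exceeds
  0.1, and the enterotype call is the majority of true assignments
  (ties → `unstable`).
* **Differential response** — per genus, paired fold-change ratios
  `FCR = experimental % / control %` are averaged and tested against
  `FCR = 1` with `z = (mean − 1)/(sd/√n)` (one-sided tail in the observed
  direction); inclusion requires ≥ 0.01 % on the changing side in ≥ 3 pairs.
  Volcano tiers at p ≤ 0.001 and p < 0.05, concordance labels
  (similar/opposite) across contexts, and set overlaps against the
  `|A|·|B|/|U|` chance expectation.
* **Diversity & representatives** — Shannon H′ per sample, normality-gated
  two-group comparisons, and a stepwise greedy selection of representative
  taxa (5 rounds over an ordered profile list, dominant control taxa removed,
  a normalizing sector N equalizing per-profile totals).

## Worked example

```r
library(enteroshift)
report <- run_pipeline(default_config(seed = 1))
print(report)
#> enteroshift run_report
#>  samples: 105; marker panel: 220 genera
#>  CH-optimal k (controls): 2
#>  reference enterotypes: E1=14, E2=7
#>  pooled combinations: 26; unstable calls: 0
```

With no input files the pipeline simulates the default cohort: 21 rats
(14 E1, 7 E2), 220 genera, 30,000 reads per sample, with planted
dose-dependent probiotic effects. The report says that the Calinski–Harabasz
scan over PAM partitions of the control JSD matrix picked two clusters, that
the 21 control samples split 14/7 between the two enterotypes, and that the
vote over all 26 pooled time-point combinations produced a decisive call for
every one of the 105 samples.

Phylum-level structure of the typed controls:

```r
ph <- report$phylum_summary
md <- report$table$metadata
ctrl <- md$is_control
tapply(ph$bf_ratio[ctrl], report$reference[md$sample_id[ctrl]],
       function(x) round(mean(x), 2))
#>   E1   E2
#> 2.09 2.11
```

The B/F ratios of the simulated control enterotypes sit at their configured
values (2.06 and 2.1). Differential results live in
`report$differential$E1` / `$E2` (one row per genus and dose/recovery
group: n, mean FCR, z, p, direction); `report$shifts` tabulates each rat's
enterotype call over time against its control call.

To analyze your own tables instead, point the config at files:

```r
cfg <- default_config(seed = 1)
cfg$input <- list(counts = "counts.tsv",       # wide or long dialect
                  metadata = "metadata.tsv",   # sample_id, rat_id, group, ...
                  phylum_map = "phyla.tsv")    # genus -> phylum
report <- run_pipeline(cfg, out_dir = "results/run1")
```

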