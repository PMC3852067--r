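# cofactorscreen

Detection of cell-type-specific and TF-specific transcriptional cofactor
binding-site motifs in compendia of TF ChIP-seq peaks.

## What it does, and for whom

ChIP-seq against a transcription factor (TF) captures more than the
target's own binding sites: cross-linking pulls down whole protein
assemblies, so peaks also harbor binding-site motifs of *cofactors*.
Given a compendium of experiments (many TFs × many cell types), this
package screens for non-target ("non-canonical") motifs whose enrichment
pattern across experiments is specific — either to one **cell type**
(enriched across experiments of that cell type regardless of targeted
TF) or to one **TF** (enriched wherever that TF is targeted, across cell
types).  It is aimed at regulatory genomicists who want candidate
TF–cofactor interactions from peak data alone, without protein
interaction assays.

The pipeline: curation (drop general machinery/CTCF, orphan TFs, TFs
without canonical motifs; remove peaks in high-occupancy-target (HOT)
regions covered by peaks from > 50% of experiments) → partition of each
experiment's peaks by presence of the target's canonical motif(s) →
per-experiment **abundance** of every library motif in positive
("proximal") and negative ("distal") peaks → within-experiment flagging
above the 95th abundance percentile → cross-experiment **ubiquity**
filter (flag fraction < 20% proximal / < 10% distal) → specificity
screens (cell type: ≥ 10 supporting experiments, > 3 TFs, abundance
> 15%; TF: ≥ 3 sister experiments in distinct cell types, abundance
> 20% in all) → removal of candidates too similar to the target's own
motif (empirical similarity p < 0.05).

At its core sit two reusable statistical components:

* **Exact motif-scan p-values.**  Log-odds scores are integer-scaled
  (scale 1000, offset = minimum score), and the null distribution of the
  window score under an i.i.d. background is computed exactly by dynamic
  programming over achievable integer scores; $p = P(S \ge s)$.  A peak
  "contains" a motif iff its best double-strand window has
  $p \le 10^{-4}$.
* **Empirical motif similarity.**  Best ungapped alignment (mean Pearson
  correlation of aligned columns, both orientations), with a seeded
  column-shuffle null: $p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\}) /
  (n_{\mathrm{null}} + 1)$.

A seeded synthetic-compendium generator plants canonical and cofactor
motifs in five scenario kinds (cell-type-specific, TF-specific,
ubiquitous, decoy-similar-to-canonical, HOT-only) with a truth table, so
the whole decision cascade is testable against known ground truth.

## Worked example

Generate the default synthetic compendium (137 experiments, 133 after
curation; 300 × 200-nt peaks each; 35-motif library) and screen it:

```r
library(cofactorscreen)

comp <- generate_compendium(compendium_design(seed = 42L), out_dir = "comp")
cfg <- pipeline_config(
  genome        = "comp/genome.fa",
  peaks_dir     = "comp/peaks",
  metadata      = "comp/experiments.tsv",
  motifs        = "comp/motifs.jaspar",
  canonical_map = "comp/canonical_map.tsv",
  out_dir       = "results", seed = 1L)
res <- run_pipeline(cfg)
res$calls[, c("motif_id", "scope", "key", "cls", "n_support",
              "n_distinct", "min_abundance")]
```

Output of that run (stderr log abridged, then the final call table):

```
curation: 137 -> 133 experiments
HOT regions: 2
peaks: 40100 -> 39900 after HOT removal
ubiquity-retained motif/class pairs: 65
specificity calls before similarity removal: 3
final calls: 2

  motif_id     scope  key      cls n_support n_distinct min_abundance
1 COF_CT01 cell_type CT01 proximal        12          6     0.4343434
2 COF_TF01        tf TF01 proximal         5          4     0.2924528
```

Reading it: the planted cell-type cofactor `COF_CT01` is recovered in
all 12 CT01 experiments spanning 6 TFs with abundance ≥ 0.43 (planted at
rate 0.6 of positive peaks; the scanner misses a fraction of
PWM-sampled words).  The planted TF cofactor `COF_TF01` is supported by
5 experiments of TF01 in 4 cell types, ≥ 0.29 abundance everywhere.
Three calls existed before similarity removal: the third was the planted
decoy (one perturbed column away from TF03's canonical motif), removed
as a false positive.  The planted ubiquitous motif (flag fraction ≈ 40%
≥ 20%) and the HOT-only motif (its peaks were discarded with the HOT
regions) produce no calls:

```r
ev <- evaluate_against_truth(res$calls, comp$truth)
ev$precision   # 1
ev$recall      # 1
```

## Command line

```sh
Rscript -e 'cofactorscreen::cli_main()' simulate --seed 42 --out comp
Rscript -e 'cofactorscreen::cli_main()' screen --dir comp --out results
Rscript -e 'cofactorscreen::cli_main()' evaluate --calls-dir results --truth comp/truth.csv
```

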