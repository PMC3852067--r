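---
title: "Screening ChIP-seq peak compendia for cell-type- and TF-specific cofactor motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening ChIP-seq peak compendia for cell-type- and TF-specific cofactor motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A TF ChIP-seq experiment pulls down more than the targeted transcription
factor's own binding sites.  Because formaldehyde cross-linking captures
whole protein assemblies, peaks also contain binding-site motifs of
*cofactors* bound near (or instead of) the target.  Across a compendium of
experiments — many TFs assayed in many cell types — the recurrence pattern
of a non-target motif carries a signal: a motif enriched in the peaks of
many experiments of *one cell type* regardless of the targeted TF suggests
a cell-type-restricted cofactor; a motif enriched wherever *one TF* is
targeted, across cell types, suggests a TF-specific partner.

`cofactorscreen` implements that screening procedure end to end, and pairs
it with a synthetic-compendium generator that plants known cofactor
patterns so every decision rule can be tested against ground truth.

## The procedure

1. **Curation.**  Experiments targeting general transcription machinery
   (Pol II/III, TBP) and the non-canonical factor CTCF are removed, then
   *orphan* experiments — TFs assayed in only one cell type, for which
   specificity cannot be assessed — then experiments whose TF has no
   canonical motif in the supplied map.  High-occupancy-target (HOT)
   regions, where peaks from more than 50% of all experiments pile up,
   are detected by a sweep line over per-base distinct-experiment
   coverage; every peak overlapping a HOT interval ("HOT peak") is
   discarded, the remainder are the COLD peaks that enter the analysis.
2. **Partition.**  Each experiment's COLD peaks are scanned for the
   target TF's canonical motif(s); a peak containing any of them is
   *positive*, the rest are *negative*.  Non-target motifs enriched in
   positive peaks co-occur *proximally* (same peak as the target's site),
   those enriched in negative peaks co-occur *distally*.
3. **Abundance.**  For every experiment, library motif (excluding the
   experiment's own canonicals) and class, the abundance is the fraction
   of the class's peaks containing the motif.
4. **Flagging and ubiquity.**  Within each (experiment, class), a motif
   is flagged as co-occurring when its abundance exceeds the 95th
   percentile of all motif abundances in that group.  Motifs flagged in
   too large a fraction of experiments (proximal: at or above 20%,
   distal: 10%) are non-specific and dropped; motifs never flagged carry
   no signal.
5. **Specificity screens.**  *Cell-type-specific*: at least 10 supporting
   experiments (flagged, abundance > 0.15) in one cell type spanning at
   least 4 distinct TFs.  *TF-specific*: at least 3 flagged sister
   experiments of one TF in distinct cell types with abundance > 0.20 in
   every one of them.
6. **Similarity false positives.**  A surviving candidate whose motif is
   statistically similar (empirical p < 0.05) to a relevant canonical
   motif may simply be the target motif rediscovered, and is removed.

## Motif scanning and exact p-values

Motifs are position weight matrices (JASPAR count dialect, UniPROBE
probability dialect, or generated).  Scanning uses integer-scaled
log-odds scores: real score $s(b,i) = \log_2(p'(b,i)/q(b))$ with $p'$ the
pseudocount-smoothed probability and $q$ the background; integer score
$\mathrm{round}(\mathrm{scale}\cdot(s - \min s))$ with scale 1000, so all
entries are non-negative and the de-scaled scores are exact to 1/1000.
The null distribution of the total window score under i.i.d. background
bases is computed *exactly* by convolving the per-column score
distributions over the achievable integer scores; a hit's p-value is the
tail $P(S \ge s)$ of that distribution.  Tests verify the tail against
brute-force enumeration over all $4^w$ words to $10^{-12}$.

Choices worth knowing:

* **Background** (default): zero-order frequencies of the scanned peak
  set, estimated per experiment and floored at 0.01 per base.  A global
  or uniform background is a config switch.
* **Presence rule**: a peak contains a motif iff its best window on
  either strand has $p \le 10^{-4}$ (the common FIMO-style default; the
  procedure's original description does not state a cutoff).
  Configurable as `presence_p`.
* **Both strands** are scanned with the same score distribution; the
  strand-symmetry invariant (identical p-values at mirrored coordinates
  when sequence and motif are both reverse-complemented) holds exactly
  for complement-symmetric backgrounds.
* **q-values** use Benjamini–Hochberg instead of a bootstrap FDR:
  deterministic and testable.  They are reported in hit exports but play
  no role in presence calls.
* Windows containing any non-ACGT letter are skipped.

## Motif similarity

Similarity of two motifs is the best *ungapped alignment*: the mean
Pearson correlation of aligned probability columns, maximized over all
offsets with at least `min_overlap = min(4, widths)` aligned columns and
both orientations of the target (ties: larger overlap, smaller |offset|,
forward).  Significance is an empirical p-value against `n_null = 999`
column-order shuffles of the target, $p = (1 + \#\{null \ge obs\}) /
(n_{null}+1)$, seeded and reproducible.  The decision rule — candidates
with $p < 0.05$ against the target's canonical motif(s) are false
positives — is the contractual part; the exact null of the original
TOMTOM-based analysis is *not* reproduced, and its printed p-values are
not comparison targets.

Two consequences of this design are worth stating plainly.  First, for
genuinely unrelated motif pairs the empirical p-value is uniform by
construction (verified by a calibration test over 200 seeded pairs), so
the 0.05 rule removes ~5% of true unrelated cofactors per canonical
target tested.  The synthetic generator therefore *guarantees* its
planted cofactors are dissimilar (p ≥ 0.2) from every canonical motif by
rejection at generation time — mirroring what the screen needs to be
able to succeed.  Second, that same uniformity makes "all library pairs
dissimilar at p ≥ 0.2" unattainable by rejection for a ~36-motif library
(acceptance rate ≈ $0.8^{630}$); unrelated *background* motifs are
instead only guarded against accidental near-duplication (best alignment
mean column score < 0.8).

## The synthetic world

The generator emits a complete compendium — genome FASTA, per-experiment
BED peaks, metadata and canonical-map TSVs, a JASPAR-dialect motif file,
and a truth table — as a pure function of a seeded design.

* **Scale.**  The screens' own thresholds dictate the scale: a cell-type
  call needs ≥ 10 supporting experiments in one cell type, yet the motif
  must stay under the 20% proximal ubiquity ceiling, and the percentile
  flag rule marks ~5% of experiments per motif by chance alone.  The
  default design therefore has 137 experiments (133 after curation; the
  compendium the procedure was designed for had a comparable 81), built
  from 6 cell types and 14 TFs plus CTCF with treatment replicates, with
  12 experiments across 6 TFs in cell type CT01.  It includes one CTCF
  experiment, one orphan TF and one TF without a canonical motif so all
  curation filters fire.  Peaks are 200 nt, 300 per experiment — enough
  for abundance fractions with ~1% resolution while keeping a full run
  inside a few minutes on one CPU.
* **Planting.**  ~35% of each experiment's peaks receive a word *sampled
  from* the TF's canonical PWM (not the consensus, so realized abundance
  exercises the scanner's sensitivity), at a uniform offset on a random
  strand; one TF has two canonical motifs planted alternately.  Scenario
  motifs cover the five pattern kinds: cell-type-specific (rate 0.6 in
  all CT01 experiments), TF-specific (0.4 in all experiments of TF01),
  ubiquitous (0.5 in 40% of all experiments — must be removed by the
  ubiquity rule), a decoy built by perturbing one column of TF03's
  canonical motif (must be called and then removed as a similarity false
  positive), and a HOT-only motif planted exclusively inside planted HOT
  regions (must vanish with the HOT peaks).  Plant rates are ≥ 1.5× the
  abundance thresholds they must clear.
* **Proximal-only scenarios.**  All scenario plants are proximal.  Under
  the 10% distal ubiquity ceiling, the structural ~5% chance-flag rate
  leaves so little headroom that robust distal recovery would need
  several hundred experiments; distal screen logic is instead validated
  exactly on constructed abundance tables.
* **Non-overlap.**  Peaks of different experiments never overlap except
  inside planted HOT regions.  Without this, planted canonical words
  would leak across experiments (~10% genome coverage per experiment
  would put any planted motif at ~20%+ apparent abundance everywhere,
  destroying both ubiquity filtering and specificity).  Real compendia
  do share regulatory regions; the synthetic world deliberately isolates
  the screens' decision logic from that confound, and a green end-to-end
  test establishes correctness of the logic, not robustness to
  correlated peak placement.
* **HOT regions** are planted by giving 75% of curated experiments one
  peak inside each designated interval, guaranteeing a detectable > 50%
  pile-up.

What the generator does *not* emulate: read-level noise, peak-width
variation, composition biases beyond zero-order GC, chromatin covariates,
and correlated peak locations between biologically related experiments.

## Numerical and tie-breaking conventions

* Coordinates are 0-based half-open (BED) everywhere internally; only the
  FIMO-like hit export is 1-based inclusive.
* Percentiles use type-7 linear interpolation between order statistics;
  flagging demands abundance strictly above the percentile, so a group of
  identical abundances flags nothing.
* "More than 50%", "> 3 TFs" (≥ 4), "at least three sisters" (≥ 3, in
  distinct cell types), "< 20% / < 10%" ubiquity and "< 0.05" similarity
  are all strict as written.
* Best-hit ties break by smallest position, then '+' strand; alignment
  ties by larger overlap, then smaller |offset|, then forward
  orientation.
* The HOT occupancy denominator counts experiments surviving the
  excluded-TF filter (configurable to the fully curated set); a motif's
  ubiquity denominator is the fully curated experiment count.
* JASPAR counts get a 0.25 pseudocount per cell; UniPROBE probabilities
  are renormalized, never reconstructed into counts; log-odds smoothing
  uses pseudocount 0.01 against the background.

## Known limitations

* Pure-R scanning: a compendium of ~40k peaks × 35 motifs takes a few
  minutes; genome-scale use would want a compiled inner loop.
* The empirical similarity null is per-pair; no correction for the
  number of canonical targets tested in the false-positive rule (the
  original procedure's database-wide correction is unclear), so each
  additional canonical target removes ~5% of true unrelated cofactors.
* The cell-type screen follows the stricter of the two published
  descriptions (≥ 10 experiments within one cell type); the alternative
  reading (> 10 cell types) is not implemented.
* Whether TF-specific calls must additionally be *absent* in other TFs'
  experiments beyond what the ubiquity filter enforces is left to the
  ubiquity filter, as in the procedure's formal description.
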