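---
title: "Species delineation from 454 amplicon reads: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species delineation from 454 amplicon reads: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motu454)
```

## The problem

Metabarcoding profiles a bulk community sample by sequencing one marker
amplicon — here the hypervariable V1–V2 expansion segments near the 5'
end of the nuclear 18S rRNA gene, an amplicon of roughly 450 bp in
marine metazoans. Reads are attributed to species by clustering them
against a Sanger-sequenced reference library at a similarity threshold;
reads that match nothing are clustered de novo into molecular
operational taxonomic units (MOTUs) and classified taxonomically.
Because 454 pyrosequencing mis-calls the length of homopolymer runs at
rates that grow steeply with run length, both reads and reference must
be made commensurate before identity comparison — the package's device
for this is *run capping*: every homopolymer run longer than `k` bases
is truncated to exactly `k`.

`motu454` implements this workflow end to end — quality filtering,
run capping, a greedy identity-clustering engine, threshold
optimization, reference-guided assignment, residual MOTU calling,
lowest-common-ancestor classification, and community statistics —
together with a calibrated 454-style read simulator, so that every
stage can be exercised and validated without any external data.

## Pairwise identity and its denominator

All clustering rests on one primitive: the identity of two sequences
under an optimal global alignment (Needleman–Wunsch with affine gaps;
match +2, mismatch −3, gap opening 5, gap extension 2 — the familiar
BLASTN-style nucleotide scores, configurable via `identity_params()`).
Identity is the number of identically aligned A/C/G/T bases divided by
a denominator, and the choice of denominator matters more than it
first appears:

* `shorter_sequence` (the default, and the convention of greedy
  clustering tools in this field): identity 1.0 means one sequence
  aligns into the other without mismatch. Insertions and deletions are
  **invisible** to this definition under an optimal aligner — a read
  that differs from its source only by run-length miscalls still
  scores identity 1.0, because every base of the shorter sequence
  finds its partner.
* `alignment_columns`: gap columns count against identity, so indel
  errors genuinely cost similarity.

This distinction decides how the benefit of run capping is measured.
Under `shorter_sequence` with an exact aligner, capping cannot change
which reads are assignable when the only errors are run-length
miscalls (they were never penalized in the first place); the
historical gains reported for capping arose from heuristic, banded,
word-filtered aligners for which indels are not free. The package's
capping-rescue experiment (`tests` and the acceptance script)
therefore runs under `alignment_columns`, where a ±1 run-length
miscall demonstrably pushes a read below a 99% threshold and capping
demonstrably rescues it. Both denominators are first-class options.

Ties and floating point: identities are compared against thresholds
with a 10⁻⁹ guard band; equal-length sequences are ordered by
ascending id; equal identities in best-fit assignment go to the
lowest cluster index. Alignment arguments are ordered canonically
before the DP so that identity is exactly symmetric even when distinct
optimal alignments tie on score with different match counts.

## The greedy clustering engine

Sequences are processed in decreasing length order (ties by ascending
id). The first founds cluster 0; each subsequent sequence is compared
to existing cluster *representatives* in creation order and joins one
whose identity meets the threshold, else founds a new cluster:

* de novo clustering uses **first-fit** (join the first qualifying
  representative — the convention of the greedy clustering programs
  this engine re-implements);
* reference-guided assignment uses **best-fit** (species attribution
  should be the best hit, not the first).

No k-mer pre-filter is used: every candidate pair is aligned in full
(a provable composition bound is the only pruning — it can only skip
pairs whose identity cannot reach the threshold). Correctness is
preferred over speed at desk scale; the engine is validated against an
independently coded quadratic re-implementation whose identities come
from a different aligner.

## Read filtering

Three rejection rules, applied in order per read: mean Phred quality
below 10; more than 2 mismatches between the forward primer and the
read prefix (Hamming, anchored at position 0 — 454 amplicons begin
with the sequencing primer once adaptors are clipped; `N` counts as a
mismatch); trimmed length below 200 bp. The primer (and, when
configured, the reverse complement of the reverse primer at the 3'
end) is removed from kept reads, and the length rule is evaluated
after trimming, since it is the biological insert that matters
downstream. The quality rule reads "mean Phred < 10" — the one
interpretation of an average-quality cutoff that yields a single
numeric rule; for quality-less input it is disabled explicitly
(`min_mean_quality = NA`) rather than silently skipped. Coordinates
are 0-based and half-open throughout.

## Threshold optimization

`threshold_sweep()` clusters the reference library at every
combination of similarity threshold (default 0.97–1.00) and
homopolymer cap (default uncapped, 5, 4, 3, 2 — produced by the same
`cap_runs()` the reads receive). A species is *resolved* when its
single reference sequence forms a singleton cluster; `pick_threshold()`
selects the threshold maximizing the resolved fraction, breaking ties
toward the lower (more merge-tolerant) threshold. Cluster counts are
non-decreasing in the threshold for every cap — asserted as a property
over random libraries, since for a greedy engine this is an empirical
regularity of realistic data rather than a theorem.

## Residual MOTUs and classification

Reads that match no reference species at the assignment threshold
(default 0.99) are clustered de novo at the same threshold; clusters
with fewer than 10 reads are discarded as probable noise (the
minimum-read rule; the laxer 5-read variant is exposed and, by
construction, only adds MOTUs). Each surviving MOTU's representative
(its longest member) is searched against the annotated library by
local Smith–Waterman alignment under the same scoring. A hit counts
only if its raw score exceeds 100 **and** its identity (matches per
alignment column — the local-search convention) exceeds 90%. The
best-scoring hit names the MOTU at species rank; when several species
tie — identities equal after rounding to 0.1%, because exact float
equality is meaningless — the MOTU is named by the deepest taxonomic
rank shared by all tied lineages (two tied congeners of *Calanus*
yield "*Calanus* sp." at genus rank). The raw-score gate stands in
for a database-search bit score; raw scores are scoring-scheme
dependent, so the gate is configurable.

## Community statistics

Reproducibility between technical replicates ("aliquots") and
dependence of read counts on per-species covariates (input DNA
concentration, GC content of the marker) are measured by Spearman rank
correlation over per-species read counts — zeros included over the
full library species domain, raw counts rather than proportions (rank
correlations are insensitive to the distinction only when totals
match, and raw counts are what the instrument reports). p-values use
the t-approximation with n−2 degrees of freedom; an exact permutation
p-value is available for small tie-free samples. Detection accounting
compares the species detected at a minimum read count (default 1)
against the known composition; the unexpected set — species detected
though never pooled — is the contamination signal.

## The simulator

The generator emulates the statistical structure the analysis assumes:

* **Reference library**: a root amplicon (default 450 bp) seeded with
  homopolymer runs up to 9 bases is evolved along a random bifurcating
  species tree; branch lengths are calibrated — and re-tuned up to 8
  times against measured identities — so that all pairwise identities
  fall in a configured window (default 0.90–0.98, the regime where a
  97–100% threshold sweep is informative). Taxonomy is read off the
  tree: shallow clades become genera, deeper ones families and orders,
  so congeneric tie cases exist by construction. An infeasible window
  fails loudly with the achieved range.
* **Reads**: each read draws its source species from the
  (contaminant-adjusted) abundance vector — uniform, lognormal, or
  fixed; for multi-aliquot studies the lognormal vector is drawn once
  per study, because aliquots are replicates of one pool. Errors:
  per-run length miscalls of exactly ±1 base with probability
  `1 − hp_accuracy(k)`, where accuracy is anchored at 99% for 3-mers
  and 64% for 9-mers and interpolated log-linearly in run length
  between the anchors (the two anchors are the published operating
  points; the interpolation form between them is an assumption and is
  configurable); independent per-base substitutions (default 0.2%,
  a realistic non-indel error floor for this chemistry); and
  single-breakpoint two-parent chimeras (default 1% of reads, typical
  of pooled-amplicon PCR). Phred qualities have a high baseline
  (30–40) and are degraded (18–28) across homopolymer runs. Every
  read carries exactly one ground-truth record.
* **Study presets**: `alldna` (all 30 species, equimolar), `zpdna`
  (12-species subset plus one library species leaking in at 5% — the
  contamination scenario), `zphts` (lognormal community with 3 species
  withheld from the written reference, so their reads can only
  surface as de novo MOTUs).

What the simulator does **not** emulate: flowgram-level signal, PCR
amplification bias as a mechanistic process (abundance skew is imposed
directly), primer-template mismatch bias, and chimera removal (the
pipeline deliberately does not filter chimeras). Passing tests
therefore demonstrate correctness of the algorithms under the stated
error model, not performance on real 454 data, where primer bias and
marker resolution dominated the detection failures.

## Numerical and scale choices

Deterministic behavior is part of the contract: a single global RNG
stream per simulated study, seeds mandatory in simulation configs and
echoed in the run manifest, and byte-identical outputs on rerun. The
test-suite and acceptance problem sizes — mock communities of 30
species at 2 × 2000 reads, oracle instances of at most 12 sequences,
10,000-trial error-model calibrations — were chosen as the smallest
sizes at which the statistical assertions (3-standard-error calibration
bands, detection rates, rank correlations) are stable; they run in a
few minutes on one core.

## Known limitations

* The greedy engine reproduces the *semantics* of the classic
  clustering tools, not their heuristics; on real data, cluster counts
  can differ by a few units from word-filtered, banded
  implementations.
* Under the `shorter_sequence` denominator a strict containment scores
  identity 1.0; fragments therefore always join their parent's
  cluster, which is intended for length-variable amplicon reads but
  can surprise on curated libraries.
* LCA naming is only as good as the reference taxonomy's rank
  structure; absent ranks are skipped, never guessed.
* The per-run ±1 error model ignores rarer multi-base slips; the
  log-linear accuracy interpolation between the two anchors is an
  assumption.
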