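---
title: "markerscan: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{markerscan: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerscan)
```

`markerscan` inventories energy-metabolism and ROS-neutralization marker
gene transcripts in assembled (meta)transcriptomes. This vignette is the
package's account of its own science: the models it implements, the
parameters that matter, what the synthetic benchmark does and does not
emulate, and the choices made where the design was genuinely open.

## The profile HMM and its scoring model

A `ProfileHMM` holds, for `M` match states over the 20 standard amino
acids, match and insert emission distributions, a per-node 7-tuple of
transition probabilities (M→M, M→I, M→D, I→M, I→I, D→M, D→D for nodes
0..M, node 0 being the begin node), and a background distribution. All
parameters are stored in probability space; every emission row, each
transition group and the background must sum to 1 within 1e-6.

`score_local()` implements single-hit local Viterbi alignment in a
plan7-like architecture:

* uniform entry into any match state, costing `-log2(M)` bits;
* free exit after any match state;
* unaligned flanking residues cost nothing;
* the score is `log2 P(aligned residues, path | HMM) /
  P(aligned residues | background)`;
* a hit is reported only when the best alignment scores above 0 bits.

Multi-hit (J-state) alignment is deliberately omitted: the inventory
counts gene variants per ORF, so only the single best local hit per ORF
matters. Forward-algorithm E-values are likewise out of scope — hits are
gated on calibrated bit-score cutoffs, not on significance estimates, so
Viterbi is the right (and fully deterministic) semiring. The dynamic
programming runs entirely in log2 space to avoid underflow; ties between
equal-scoring alignments resolve to the smallest sequence start, then the
smallest node start. Unknown residues (`X`) emit with a log-odds
contribution of exactly 0, i.e. they neither reward nor penalize any
alignment. The same contract is implemented a second time in
`score_local_reference()` by exhaustive enumeration of every
(subsequence, node interval, state path) triple with probability-space
arithmetic; on models with `M ≤ 3` and peptides of length ≤ 4 the two
routes agree to < 1e-9 bits over hundreds of random models, which is the
package's primary correctness anchor for the scorer.

## HMMER3 text and profile construction

`parse_hmm3()`/`write_hmm3()` speak the `HMMER3/f` ASCII dialect:
parameters as negative natural logs, `*` for probability zero, `GA`,
`TC`, `NC` cutoff lines. Two reading conventions are worth stating
plainly. First, the `COMPO` line is interpreted as the model's
background (null) distribution; files without it get a uniform
background. Second, values are written with seven decimals (more than
HMMER's five) so that a write/parse round trip reproduces probabilities
within 1e-6; models re-read from fixed-precision text are validated with
a correspondingly looser sum tolerance (1e-4), because five-decimal
encodings of a legitimate distribution can leave row sums a few parts
per million off 1.

`build_from_alignment()` constructs a profile from an alignment of
family members: columns at least 50% occupied (configurable
`match_fraction`) become match states; match emissions are
Laplace-smoothed column counts `(count + κ) / (total + 20κ)` with
pseudocount `κ = 1` by default; transitions are counted from each
sequence's observed match/delete/insert path with the same smoothing;
the background is the alignment-wide residue frequency. Insert states
emit the background, so inserted residues carry zero log-odds — this
keeps the enumeration oracle simple and is the conventional neutral
choice when no insert model has been estimated. Alignments that imply
D→I or I→D steps (a deletion abutting an insertion) update the state
path without contributing counts, since plan7 has no such transitions.

## ORF extraction

`six_frame_orfs()` reports every maximal stop-free stretch of at least
`min_aa_len` residues (default 30 aa) in all six frames, translated with
NCBI table 11; codons containing `N` become `X`. ORFs are stop-to-stop:
no initiator codon is required, because assembled transcripts are often
fragmentary and requiring ATG would discard genuine gene fragments.
Coordinates are always 0-based half-open on the forward strand,
whichever strand carries the ORF. Note that a protein-coding region read
in a shifted frame frequently lacks stop codons for 30+ codons, so
contigs carrying a real gene typically yield several spurious ORFs as
well; these are not an error — they are exactly what the downstream
bit-score screen exists to reject.

## Cutoff calibration and decoy screening

`derive_cutoffs()` turns labeled score sets into a `CutoffPair`:
`trusted` = minimum true-homolog score, `noise` = maximum non-target
score (−∞ if none), and the operational `gathering` cutoff at their
midpoint when the sets separate (equal to `trusted` when no
false-positive set exists). Overlapping sets are flagged
`separable = FALSE` and the gathering threshold falls back to maximizing
classification accuracy over the labeled scores, ties resolved toward
the stricter (larger) threshold. The midpoint rule is this package's own
concrete realization of cutoff calibration; it is pure, testable, and
overridable per gene in the registry (`gathering_override`). Sequences
with no positive-scoring local alignment enter calibration with score 0,
keeping all labeled scores finite.

`competitive_assign()` then screens each ORF: every registry model —
targets and decoys — scores the ORF, the best model wins, a decoy win
rejects the ORF, and a target win is accepted only at or above its
gathering cutoff (the threshold is inclusive). Ties prefer the decoy,
then the lexicographically smallest target, making the screen
conservative and deterministic. Screening is monotone-restrictive:
adding a decoy model can only remove acceptances, never add them.

## Variant counting and the inventory

"Transcript copies" are counted as distinct sequence variants, not
read-depth abundance (read mapping is out of scope). `count_variants()`
sorts accepted ORF translations by length (descending) then
lexicographically and clusters greedily: a sequence joins the first
cluster whose representative it matches at ≥ `identity_threshold` over
the shorter sequence under the best ungapped overlap. At the default
threshold 1.0 this is exact dereplication (duplicates and exact
fragments collapse); the threshold is exposed because the right notion
of "distinct variant" — and whether it should be protein- or
nucleotide-level — is a judgment call that depends on assembly quality.

`build_inventory()` groups accepted ORFs by (lineage, gene). Lineage
comes from an externally supplied mapping (ORF id first, contig id as
fallback); taxonomic classification itself is intentionally not
re-implemented, and unmapped ORFs are kept under `"unclassified"` so
that totals remain conserved. The export table (`export_inventory_table()`)
is sorted by site, depth, lineage and gene and is byte-deterministic;
`category_scores()` sums variant counts per process category, optionally
normalized to per-sample proportions.

## The synthetic benchmark

`make_dataset()` emulates the statistical skeleton of a per-sample
metatranscriptome assembly at toy scale — enough structure to exercise
every pipeline stage, with a machine-readable truth table:

* **families**: a root drawn uniformly over the residues, members by
  independent per-site substitution (no indels, so members double as a
  seed alignment and identities are closed-form); decoy roots copy a
  stated fraction of a target root's sites (40% by default), which makes
  calibration and competition genuinely non-trivial;
* **planting**: each planted variant is a distinct family member,
  reverse-translated with uniform synonymous codons and embedded between
  stop-rich flanks (≥ 30 nt) on a random strand, with an in-frame stop
  forced immediately on both sides so recorded coordinates are exactly
  the maximal ORF;
* **random contigs**: random blocks (≤ 30 nt) interleaved with a
  stop-codon motif whose reverse complement is also stop-dense, so no
  frame can hold an ORF of benchmark length; a reject-and-regenerate
  guard verifies this;
* **determinism**: one global seed fans out to per-family and per-sample
  substreams via a stable identifier hash, so adding a sample or family
  never perturbs the others, and outputs are byte-identical across runs.

The default study conditions (chosen once): three samples emulating two
depths of a sulfate-containing margin site (5 and 91 mbsf) and one
sample below sulfate depletion in a brackish basin (42 mbsf); six marker
genes (cyc2 — iron oxidation, sdo and sqr — sulfur oxidation, nar —
nitrate reduction, katG — catalase, sodA — superoxide dismutase) with
nar planted exclusively in the 91-mbsf sample to exercise
sample-exclusive detection; family size 30, root lengths 120–170
residues, substitution rate 0.05; two decoy families; 8 decoy ORFs and
50 random contigs per sample; seed 42.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: sequencing error and quality profiles,
assembly artifacts and chimeras, indel evolution, rRNA contamination,
uneven coverage, and real taxonomic assignment. Perfect precision/recall
on the benchmark demonstrates the correctness of the machinery
(ORF calling, scoring, calibration, screening, counting, export), not
field performance on noisy assemblies.

## Numerical and interface choices

* All Viterbi arithmetic in log2; `-Inf` represents probability zero and
  is handled explicitly in the dynamic programming.
* Tie-breaks everywhere are deterministic (radix/byte order, not locale
  collation), and no output embeds timestamps, so reruns are
  byte-identical.
* `derive_cutoffs()` requires finite labeled scores; the no-hit floor is
  0 bits, consistent with "no alignment better than background".
* Degenerate inputs have defined outcomes rather than errors where the
  field expects tolerance: contigs too short for any ORF yield an empty
  table; an empty contig file yields empty outputs and a warning; an
  empty inventory yields an all-zero category row.
* Problem sizes used in the shipped validation: 200 random tiny models
  against the enumeration oracle, 100 round-trip models, 20+20 training
  and 20+20 held-out sequences for calibration, and the default demo
  plan above for the end-to-end checks. These sizes make the full
  validation run in tens of seconds while leaving each property
  statistically meaningful.

## Known limitations

* Single-hit local alignment only: multi-domain proteins contribute one
  hit. For presence/absence variant inventories this is the intended
  behavior.
* No E-values; scores are only comparable through calibrated cutoffs.
* The greedy variant clustering is order-normalized but not an optimal
  clustering; at thresholds below 1.0, cluster counts can depend on the
  greedy representative choice in ways a single-linkage clustering
  would not.
* Lineage assignment is consumed, not computed; the quality of the
  inventory's taxonomic dimension is bounded by the supplied mapping.
* The command-line layer is a thin wrapper; an ROS-only versus a
  lithotrophy-only survey differs purely in the registry rows selected
  via `--categories ros` or `--categories litho` — the screening engine
  is identical.
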