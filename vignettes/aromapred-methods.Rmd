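---
title: "Methods: composition-based SVM prediction of aromatase-related proteins"
author: "aromapred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition-based SVM prediction of aromatase-related proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aromapred)
```

## The problem and the model

Aromatase (CYP19A1) converts androgens to estrogens and is a central drug
target in estrogen-receptor-positive breast cancer. The task this package
addresses is binary: given a protein's primary sequence, decide whether it
is aromatase-related. The method is deliberately simple and fully
sequence-based — a support vector machine over fixed-length composition
encodings — because composition signatures (notably a high leucine
fraction, elevated F/P/S/V, depleted C/W) separate curated aromatase sets
from generic background proteins.

A C-SVM with RBF kernel $K(x,y) = \exp(-\gamma\lVert x-y\rVert^2)$ is
trained on $+1$ (aromatase-like) versus $-1$ (background) examples. The
classifier's continuous decision value is exposed alongside the thresholded
class call, because the threshold is a property of *prediction*, not of the
model: sweeping it trades sensitivity against specificity, and the package
reports that whole curve rather than a single operating point.

## Feature encodings

All encoders use one canonical residue order — alphabetical one-letter
codes A, C, D, ..., Y — for vector components. PSI-BLAST PSSM files keep
their native column order (A R N D C Q E G H I L K M F P S T W Y V) on
disk and are remapped at composition time.

* **AAC** (20): residue frequencies $n_i/L$. Sums to 1.
* **DPC** (400): overlapping dipeptide frequencies $n_{ij}/(L-1)$, indexed
  (first residue, second residue). The denominator is the number of
  overlapping dipeptides, $L-1$, not the constant 400, so the vector is a
  frequency distribution summing to 1 — consistent with AAC and with the
  term "dipeptide frequencies".
* **HYBRID** (420): concatenation $[\mathrm{AAC} \,\|\, \mathrm{DPC}]$.
* **PSSM composition** (400): the profile is min-max normalized over all
  $L \times 20$ cells, $v' = (v-\min)/(\max-\min)$, then component
  $(i,j)$ is $\frac{1}{L}\sum_{p:\,s_p = i} v'_{p j}$, the per-length mass
  of normalized column-$j$ scores at positions holding residue $i$.

Three choices here were genuinely open and are fixed as follows:

* *Normalization scope.* Min and max are taken per profile, over all
  cells. Per-profile scaling is deterministic and self-contained (no
  external constants); a constant matrix maps to all zeros by convention.
* *Composition divisor.* The $(i,j)$ sums are divided by the sequence
  length $L$, not by per-residue counts, so residues that occur once do
  not produce inflated components; every component is bounded by the
  residue's frequency.
* *Non-standard residues* (B, J, O, U, X, Z, gaps, stops) are removed at
  ingestion with a warning, and composition denominators use the cleaned
  length, because the encodings are defined only over the 20 standard
  amino acids.

## Dataset curation

Curation mimics how a high-quality positive set is built from UniProt:

1. **Annotation filter** — drop records whose description contains any of
   *fragment, isoform, potential, similarity, probable*
   (case-insensitive substring match, so singulars catch plurals). Matching
   is restricted to the description because that is where UniProt-style
   annotation words live.
2. **Redundancy reduction** — a deterministic stand-in for CD-HIT.
   Pairwise identity is computed from a global Needleman–Wunsch alignment
   scored match = 1, mismatch = 0, zero gap penalties; identity =
   identical aligned positions / alignment length (terminal gaps counted).
   Records are visited longest-first (ties by id, C-locale), and a record
   is kept iff its identity to every already-kept record is ≤ the
   threshold (default 0.90). CD-HIT's word-filter heuristics are *not*
   reproduced: exact alignment is slower but deterministic and testable,
   and on datasets of hundreds of sequences the cost is negligible.
   The filter is applied before redundancy reduction; both steps are
   idempotent, and the kept-set size is non-decreasing in the threshold.

Because zero-penalty optimal alignments are not unique, alignment *length*
(and hence identity) can differ slightly between equally match-maximal
alignments. The package's tests therefore arbitrate clustering decisions
with an independent dynamic-programming oracle on fixtures whose
identities sit far from the 0.90 boundary (~0.96 versus < 0.5), where any
tie-break discrepancy is irrelevant.

## Classifier configuration

| Scheme | kernel | γ | C | rationale |
|---|---|---|---|---|
| DPC | RBF | 3 | 375 | published tuned values for the dipeptide model |
| AAC / HYBRID / PSSM | RBF | 1 | 100 | tuned values never published; a moderate default, overridable |

Other fixed numerical conventions:

* Features are used unscaled (they are already in $[0,1]$), and the solver
  convergence tolerance is tightened to $10^{-5}$ so retraining on
  reordered examples reproduces decision values to ~4 decimals.
* Decision values are oriented positive-for-positive-class regardless of
  label order in the training data.
* A decision value exactly at the threshold is called $+1$; the tie rule
  must be fixed for reproducibility and the positive call is the
  convention here.
* Models persist as a versioned serialized container; loading validates
  the format marker, version and scheme/dimension consistency.

## Evaluation

Five-fold cross-validation is stratified: each class is shuffled under the
run's seed and dealt round-robin, so per-class fold sizes differ by at most
one and no fold can lose a class entirely (which would leave SN or SP
undefined). The shuffle is keyed by sorted record id, making fold
assignment — and therefore every cross-validated number — invariant to the
order records happen to arrive in.

The headline metrics are the unweighted mean of per-fold ACC, SN, SP and
MCC ("average of the test scores"); metrics recomputed from pooled
confusion counts are also available as a secondary output. MCC is
implemented with the square root over the denominator product,
$\mathrm{MCC} = (TP\cdot TN - FP\cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}$,
and defined as 0 when any factor is zero; without the root the statistic
is not bounded by $[-1,1]$. Counts are widened to doubles before the
product, which otherwise overflows 32-bit integers near $n = 10^4$.

Threshold sweeps default to 101 evenly spaced cutoffs spanning the
observed decision values; sensitivity is non-increasing and specificity
non-decreasing along the grid, which the tests assert as a property. The
prediction-score graph reports per-sequence scores split by class plus the
false-negative and false-positive counts and FPR at a fixed threshold.

## The synthetic generator

`simulateProteins()` draws sequences residue-i.i.d. from two 20-point
distributions: the background is uniform; the positive class multiplies
uniform weights by L × 2.0, F/P/S/V × 1.5, C/W × 0.3 and renormalizes.
This mirrors the qualitative residue profile of curated aromatase sets
(L above 10%, F/P/S/V above 6%, C/W below 2%) rather than exact read-off
values, which are only available as a figure. Default lengths are uniform
on 100–500 residues — bracketing the 503-residue human aromatase while
keeping short sequences in play — and the default class sizes are
100 + 100. All randomness in a run flows from a single seed, so output is
byte-identical across runs.

Two companions complete the fixture set: `addRedundantPairs()` appends
mutated copies (per-residue substitution probability `mutationRate`; at
rate 0.02 and length 300 the probability of falling below 90% identity is
a ~$10^{-13}$ binomial tail), and `simulatePSSMFixtures()` writes ASCII
PSSM files whose matching-residue column scores high (4–9) against a low
background (−4–2), so profile features carry the same class signal as the
sequences.

What the generator deliberately does **not** emulate: positional structure,
domains, evolutionary relatedness, realistic alignment-derived PSSMs, or
the hard negatives (other cytochrome P450s) that make the real problem
harder. Passing the recovery tests therefore demonstrates that the
pipeline is correct and can extract a composition signal — not that the
reported synthetic accuracies transfer to real UniProt data, where
published accuracies for this family of models sit in the 84–92% range.

## Problem sizes and determinism in the shipped tests

The test-suite runs the recovery experiment at 100 + 100 sequences (seed
42), where AAC five-fold accuracy must reach at least 95% and the
no-signal control must stay within 40–60%; oracle-arbitrated clustering
uses ≤ 20-sequence fixtures (the pure-R alignment oracle is quadratic);
metric equivalence is checked over 1,000 random confusion tables and
composition sums over 1,000 random sequences. `scripts/acceptance.R`
re-runs the full four-encoding study at 100 + 100 with all seeds derived
from `--seed`.

## Known limitations

* The negative class in any real application must be curated by the user;
  the package ships no UniProt client by design.
* PSSM profiles are treated as given inputs (or synthesized); the package
  does not run PSI-BLAST, and profile quality depends entirely on how the
  profiles were produced.
* Redundancy reduction is exact-alignment greedy clustering; for datasets
  of tens of thousands of sequences a word-based tool (CD-HIT) is the
  right choice and this implementation is not.
* The SVM is binary only, with no probability calibration; the decision
  value is a margin, not a probability.
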