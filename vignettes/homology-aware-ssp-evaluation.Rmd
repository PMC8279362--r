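---
title: "Homology-aware evaluation of secondary structure prediction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-aware evaluation of secondary structure prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Machine-learning predictors of protein secondary structure (SSP) are built
from three kinds of datasets: a *reference* set searched for homologs when
building the PSSM feature profiles, *query* sets for training and testing,
and *independent* query sets of novel proteins for the final evaluation.
Sequence homology connects all of them. When a homology relation is left
unreduced, part of the measured accuracy can be information leakage rather
than generalisation; when the wrong relation is reduced, accuracy can also be
*under*-estimated. `homssp` is a desk-scale laboratory for separating those
effects: it generates a synthetic protein universe with fully known family
structure, manipulates each homology relation independently, and measures
how apparent accuracy (training/testing) and practical accuracy
(independent test) respond.

The package treats the *overfit gap* — training minus independent-test
micro-Q — as the operational sign of overestimation.

# The synthetic universe

Real inputs of such a study (a structural database snapshot and novel-protein
test sets) cannot be shipped or rebuilt at desk scale, so the generator
emulates the properties of those datasets that the experiments depend on:

* **Families with a controlled identity ladder.** Each family is grown from
  an ancestor by point substitutions to target identities on a dense grid
  (1.0 down to 0.28 by default). Substitutions are uniform over positions
  with no indels, so identity control is exact and verifiable; the
  replacement residue is drawn from the local state's propensity row.
  A *dense* grid matters: databases contain a continuum of redundancy, and
  pairs just under a cutoff (e.g. mutual identity 0.87 surviving an NR90
  reduction) are what makes redundancy respond to the cutoff ladder.
* **Heavy-tailed family sizes.** Per-family sizes follow the recycled pattern
  1, 1, 2, 4, 10, 18 (mean 6). This is the single most consequential choice
  in the generator: in real databases most redundancy lives in a minority of
  large families, whose members are exactly the queries with many reference
  homologs and therefore rich profiles. Homology reduction of a query source
  changes *which kinds of proteins get sampled* (large-family members versus
  singletons), and that composition shift — not any per-sequence change — is
  the mechanism behind the inner-homology and reference-size effects. With
  uniform family sizes those effects are structurally impossible, which we
  verified in pilots before fixing this design.
* **Secondary structure from a semi-Markov segment process.** Three macro
  states (helix, strand, coil) with geometric segment lengths (means 8/5/6,
  minima 4/2/1) and a fixed sub-label scheme (helix to H, strand to E, coil
  uniformly T/S/C). Residues are drawn from per-state propensity rows with
  four-fold enrichment of state-typical residues — discriminative enough for
  a windowed classifier to clearly beat the majority class (~40% coil), but
  far from separable.
* **Label noise.** Two sources: a 3% baseline chance per position that an
  ancestor's label flips to a coil sub-label (assignment ambiguity between
  8-state annotators is of this order), and a 10% chance that a *substituted*
  position flips (structure drifts where sequence drifts). The baseline term
  exists so that family ancestors are not systematically cleaner-labelled
  than deep mutants, which would otherwise bias low-homology layouts whose
  surviving representatives are ancestors.
* **Sequence lengths 110–130.** Deliberately narrow. Identity uses the
  CD-HIT convention (matches over the shorter sequence's length) on a global
  alignment; large length differences let unrelated pairs reach apparent
  identities above 0.2, which would make every 0.2 cutoff unsatisfiable.
  With the narrow band plus a gap penalty of −2 the unrelated background is
  ~0.12 (95th percentile ≈ 0.2).

What the generator does **not** emulate: indel evolution, real length and
composition distributions, phylogenetic correlation between families, and
any thermodynamic realism. Passing experiments therefore demonstrate the
*mechanisms* (leakage, redundancy, profile diversity), not the absolute
accuracy levels of real predictors on real data.

# Pairwise identity and homology reduction

Identity is computed from an optimal global alignment with linear gap
penalties (match +1, mismatch 0, gap −2 by default; all configurable on a
0.25 grid), taking — among equally optimal alignments — the one with the
most identical pairs, and dividing by the shorter sequence's length. The
gap default departs from the more common −1 deliberately: with gap −1 the
aligner can "gap-dance" unrelated sequences up to ~0.2 apparent identity,
and sub-25% cutoffs become unsatisfiable on *any* dataset. The engine is
compiled code (a packed-integer Needleman–Wunsch); an independent S4 aligner
with an equivalent scoring scheme is used as a cross-check in the test
suite, never as the engine.

Within-dataset reduction is greedy incremental clustering in the CD-HIT
style: longest first (ties by id), keep a sequence iff it is below the
cutoff against every kept sequence. Between-dataset reduction removes from
B what is ≥ cutoff to anything in A; the *two-way* procedure then removes
from A what is ≥ cutoff to the surviving B′, guaranteeing the symmetric
post-condition and idempotence. Every guarantee is re-checkable by an
exhaustive all-pairs scan (`max_inner_identity`, `max_cross_identity`),
which the experiment driver re-runs on every sampled layout before training
(reference sets inherit their inner guarantee from the reduced source they
are sampled from; the scan re-verifies it in the test suite).

# Profiles

`search_homologs` is the desk-scale stand-in for a database search tool:
exhaustive identity scan, hits at ≥ 0.25 identity, sorted by identity,
truncated to a cap (500 by default, the conventional hit-list size; the cap
mirrors the bounded hit lists of profile search tools). The identity floor
approximates the twilight zone below which alignment-based search loses
specificity. Note that at desk scale the cap essentially never binds:
typical hit lists here hold 0–5 sequences, so the saturation dynamics that
a bounded list shows against a large redundant database (where the cap
fills with near-duplicates) are out of reach — a limitation that matters
for the reference-redundancy experiment, discussed under Known
limitations. `build_pssm` accumulates the query plus aligned hit
residues per position and smooths with background pseudocounts
(`p = (c + beta*b)/(sum(c) + beta)`, uniform background, beta 1). There is no
iterated search and no sequence weighting — the major fidelity gap versus
PSI-BLAST, recorded here deliberately: with desk-scale references the
single-pass profile preserves the qualitative entropy/diversity behaviour
the experiments measure. Shannon entropy (`-sum p log2 p`, bits) is computed
per column and averaged; dataset-level entropy weights proteins by length.

# The predictor

Per-residue features concatenate, over a 5-residue window, the 20 profile
probabilities, the 20-letter one-hot encoding and a terminus-pad flag (205
features). The model is a bagged voting committee: each member trains on a
bootstrap resample of residues and a random 70% feature subset; prediction
is per-residue majority vote, ties resolved toward coil (the modal state).
Base learners are single-hidden-layer neural networks (default), decision
trees, or SVMs, all via their standard R implementations; committees of
different learners can be pooled.

The full-size configuration is 60 members with 30 hidden units. Ladder
experiments default to 10 members of 6 hidden units (decay 0.01, ≤50
iterations) — chosen, before any ladder was run, to reproduce the documented
baseline condition of the study design: at a conventional high-homology
layout the committee shows a clear apparent-vs-practical gap (~0.13 micro-Q)
while still finishing a multi-level multi-repeat design on one CPU. A
learner without that capacity (we measured pruned trees and tiny networks)
cannot exhibit the overfitting phenomena the experiments quantify; one with
much more (larger networks, RBF SVMs) is an order of magnitude slower
without changing directions.

# Layouts and experiments

A `layout_spec` fixes the sizes, all four homology levels (within query
sets, between train and test, query-to-reference, within reference), the
number of reference sets (1–3), repeats, and the seed. Sources are prepared
once per design point — the reduced reference and query pools and the
withheld independent set — and each repeat freshly samples reference/train/
test sets from them, mirroring the usual protocol in which non-redundant
source sets are fixed and repeats resample. The independent set is one
representative (the ancestor) from each withheld family; optionally (on by
default) the reference pool may contain *distant* relatives (identity
< 0.35) of independent proteins, the way real novel-protein test sets still
share remote homology with the reference database. Without such relatives
the independent group cannot respond to reference composition at all, and
the reference-redundancy and reference-size experiments would be blind.

Aggregation follows the random-sampling protocol: per-repeat micro-Q
(residue-level average) and length-weighted SOV per group, means and sample
standard deviations over repeats. Group differences use the
Shapiro–Wilk → F-test → Student/Welch cascade; when normality fails the
Wilcoxon rank-sum test is substituted (the source protocol leaves this case
unspecified). "No effect" is operationalised as a per-level range of means
below 2 percentage points *and* no significant difference between extreme
levels at alpha 0.05.

The experiment families (`run_ladder` designs) vary one relation at a time:
inter-query homology (`inter_query`), inner-query homology (`inner_query`), reference
isolation into 1–3 sets (`reference_isolation`), query–reference homology (`query_reference`),
reference inner homology (`reference_redundancy`), and reference size (`reference_size`).
`strategy_check` contrasts the proposed all-relations-at-0.3 layout with a
conventional high-homology layout. For `reference_redundancy` the query–reference relation
is left unreduced: an identity-thresholded search has no sub-cutoff weak
hits (unlike a profile search tool), so reducing query–reference identity
to 0.2 would empty every hit list and null the experiment; the reference
inner ladder then drives hit diversity directly.

# Numerical and scale choices

* Problem sizes for the shipped experiment drivers and the acceptance
  checks: universe of 300 families (~1800 sequences); reference 500, except
  300 for the isolation, query-reference and reference-redundancy designs
  (an all-pairs-reduced reference source at cutoff 0.3 retains only ~350
  sequences, the same wall that stops real reference reduction near 30%);
  train/test 30 each; independent 20; repeats 3 for the no-effect and
  entropy designs, 8 for the two drop-significance designs. These are the
  package's desk-scale study conditions; every size is configurable upward.
* Determinism: every sampling step derives from explicit seeds (layout seed
  + repeat index; training seeded per run). The same seeds reproduce results
  bit-for-bit; the caller's RNG state is never disturbed.
* Degenerate inputs: empty sequences, single-class training sets,
  non-normalised probability vectors and mismatched lengths raise immediate
  typed errors; unsatisfiable layout constraints raise a size-exhaustion
  error naming the first unsatisfiable constraint.
* The SOV variant is the 1999 revision (pair-counted normaliser with the
  boundary-shift allowance delta), pooled over states; the per-state
  averaged form and the 1994 variant are not implemented.

# Known limitations

Absolute accuracies and effect sizes on synthetic data do not transfer to
real benchmarks; only directions and null effects are claimed. The profile
stage is single-pass and unweighted, so entropy magnitudes are not
comparable to PSI-BLAST's. Significance with 3–8 repeats has limited power;
the shipped drivers accept that in exchange for single-CPU runtimes, and all
repeat counts scale up by configuration.

The reference-redundancy experiment (`reference_redundancy`) reproduces only part of the
phenomenon it emulates, and the package reports this honestly rather than
masking it. In a PSI-BLAST-scale pipeline, near-duplicate hits crowd a
bounded hit list and are *noise*: iterated, sequence-weighted profiles from
redundant references collapse toward the query, so reducing reference
redundancy raises both profile entropy and accuracy in every group. This
engine's profiles are single-pass and unweighted (a deliberate
simplification), every hit carries real propensity signal, and hit lists
hold 0–5 sequences — so pruning redundant reference members removes
information along with redundancy. The measured consequences on the desk
universe: independent-test accuracy does rise along the reference-reduction
ladder (the headline direction), and test-set profile entropy rises across
the ladder except for a statistically flat final step, but apparent (test)
accuracy falls slightly instead of rising, and the per-level
entropy-accuracy correlation is therefore negative rather than positive.
We verified this across unbounded and proportionally scaled hit-list caps
and several reference sizes before concluding it is structural at this
scale, and left the registered checks unweakened.
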