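---
title: "splicetree: model, splice rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{splicetree: model, splice rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

splicetree estimates, per small variant, the probability that it alters
pre-mRNA splicing. This vignette is the package's own account of the
method: the consensus model and its assumptions, the bespoke splice rules,
what the synthetic generator does and does not emulate, the numerical
conventions, and the places where the design was genuinely open.

## The consensus model

No single splice predictor performs well across all variant classes:
motif-based scorers need prior knowledge of degenerate binding sites,
precomputed resources only cover canonical splice regions, and
sequence-learned models mis-handle rarities such as AG-exclusion-zone
variants or minor-spliceosome introns. splicetree therefore treats the
external predictors as *features* and learns where each is trustworthy.

The learner is a single C4.5/C5.0-family decision tree, authored in the
package rather than wrapped from an existing implementation, because its
defining requirement — predicting through missing values without
imputation — must be explicit and testable:

* **Splits** maximise the information gain ratio. Gain is computed on the
  rows where the candidate feature is observed and scaled by the observed
  weight fraction; the split information includes the missing mass as an
  extra category. Numeric features use binary threshold splits with
  candidate thresholds at midpoints of consecutive distinct observed
  values; categorical features (the region class) split multiway, one
  branch per observed level.
* **Missing values** use fractional instance weighting: during training a
  row missing the split feature descends every branch with its weight
  multiplied by the observed branch mass fraction; at prediction time the
  same mixture is taken over branch predictions. With no missing values
  this reduces exactly to single-path traversal (tested as an identity).
* **Leaves** return Laplace-smoothed positive-class probabilities
  `(pos + 1)/(n + 2)`, so the classifier emits a continuous 0–1 score and
  no leaf is ever degenerate at 0 or 1.
* **Pruning** is pessimistic: a subtree is replaced by a leaf when the
  leaf's upper-bounded error (binomial upper confidence limit at
  `1 - prune_confidence`, default confidence 0.25, evaluated by `qbeta` on
  the possibly fractional counts) does not exceed the sum of its leaves'
  bounds. `prune_confidence = NA` disables pruning.
* **Determinism**: ties in gain ratio break toward the lowest
  feature-registry index, then the lowest threshold; training is invariant
  to row order. The registry order therefore matters and is stored (with a
  hash) in the serialised model.

Why a single tree rather than an ensemble: the consensus logic stays a
readable chain of if/else decisions, mirroring how an analyst consults the
constituent tools by region, and missing-value semantics remain exact. A
boosted mode was considered and left out; nothing in the architecture
precludes adding it, but none of the package's claims depend on it.

### Assumptions

The model assumes (i) training labels are binary and trustworthy, (ii)
feature missingness patterns at prediction time resemble those seen in
training (fractional weighting uses training branch masses), and (iii) the
external tools' score scales are stable across datasets — scores are used
raw, never re-normalised.

## Bespoke splice rules

* **Region classes.** Donor = last 3 exonic + first 6 intronic nt of a
  junction; acceptor = first 3 exonic + preceding 12 intronic nt; both in
  transcript sense, with minus-strand transcripts mirroring the
  plus-strand rule. Donor/acceptor take precedence over exon/intron; if a
  position falls in two site windows (possible only for very short exons
  or introns) the nearer splice site wins, ties to the donor. Window
  widths are configurable via `region_config()`.
* **ESE/ESS deltas.** For each motif, the delta is the best window score
  of the alternate haplotype minus the reference, over all windows
  overlapping the changed bases (log-odds sum convention). Deltas are
  computed only for exonic and near-exonic positions (within one motif
  width into the intron); deeper intronic positions carry a missing value
  rather than a fake 0, since the motifs are exonic elements. The shipped
  matrices are consensus-derived synthetic stand-ins (the experimentally
  derived matrices are not redistributable here); the text format and the
  published score thresholds are kept so they are drop-in replaceable.
* **AG/GT flags.** A variant creates (removes) AG or GT when the
  dinucleotide count of the changed window (changed bases ± 1 nt) rises
  (falls) between reference and alternate haplotypes, in transcript sense.
* **AG exclusion zone.** The zone runs from the branchpoint (exclusive)
  to the acceptor AG (exclusive). Branchpoint positions come from an
  external per-intron table when provided; otherwise the zone start
  defaults to 44 nt upstream of the 3' splice site (the outer edge of the
  canonical 18–44 nt branchpoint window). An AG created in the zone marks
  a candidate cryptic acceptor; if the new AG lies **closer than 15 nt to
  the branchpoint** the subcase is flagged exon-skipping-prone (the
  spliceosome cannot use an acceptor that close to the branchpoint, so the
  exon is skipped), otherwise new-splice-site use. The margin is
  configurable via `branchpoint_config(agez_bp_margin = ...)`.
* **Minimal introns.** An intronic deletion that leaves its intron
  shorter than 45 nt is flagged. 45 nt is the operative constant (a
  secondary figure source says 43); it is configurable via
  `branchpoint_config(min_intron_nt = ...)`.
* **U12 introns.** Membership is a lookup against a user-supplied BED of
  minor-spliceosome introns; with no file the feature is *missing*, not
  false.
* **Complex variants.** MNV and insdel variants are decomposed into a
  pure deletion plus a pure insertion at the same locus. External tools
  that can only score simple variants score the parts; per score category
  the complex variant receives the maximum over its scored parts. The max
  rule applies only here — the four SpliceAI-style delta categories enter
  the model as separate features, never collapsed.
* **Zero rule.** If both deep-learning score groups (the spliceai-style
  and mmsplice-style columns) are entirely missing, the final score is 0
  regardless of the tree output. Those tools carry hard region filters;
  absence of their scores is absence of evidence, and unguarded the tree
  would otherwise extrapolate from location features alone.

## Variant I/O conventions

Internal coordinates are 0-based half-open; VCF positions (1-based)
convert at the boundary. Alleles are parsimony-trimmed (shared suffix then
prefix, position advancing with the prefix, at least one base retained),
which makes score-table joins exact by construction; full left-alignment
against the reference is not performed — tests assert trimming never
changes the implied haplotype. The allele-frequency filter keeps variants
with popmax AF ≤ 0.01 and, by default, variants with no AF annotation
(absence from a population database is evidence of rarity). Output VCFs
format numbers canonically (6 significant digits, `.` for missing), so
re-reading a written file reproduces every value bit-exactly as formatted.

## The synthetic universe

`run_simulate()` builds everything the pipeline needs with no downloads:
a single-chromosome genome of 30 five-exon protein-coding genes
(alternating strands; exons 90–150 nt, introns 70–200 nt) in which every
intron has canonical GT/AG ends, a branchpoint adenosine 25 nt upstream
of the 3' splice site in a CTAAC context, an AG-free exclusion zone, and
a planted high-scoring enhancer motif in internal exons.

Variants are planted per region class (defaults 400 donor / 500 acceptor
/ 700 exon / 400 intron = 2000), mixing canonical-site SNVs, window
background, ESE-disrupting SNVs against the shipped matrices, exonic
MNVs, AG-creating SNVs inside the exclusion zone, minimal-intron
deletions, deep-intronic SNVs and intronic insdels. About two-thirds per
class are designated splice-disrupting (matching the positive fraction of
a realistic literature-curated truth set); each variant draws a latent
ΔPSI — |effect| ~ N(0.45, 0.15) for designated variants, N(0, 0.03) noise
otherwise — and the binary label is |ΔPSI| ≥ 0.10, the 10%
transcript-change rule. The null arm is truncated just below the
labelling threshold: the negatives emulate *validated* non-splice-altering
variants, which by that same curation rule cannot carry a supra-threshold
transcript change. Only the thresholded label is exported by default
(`export_dpsi = TRUE` adds the latent value for quantitative-extension
experiments).

Tool scores are class-conditional clipped Gaussians with equal spread in
both classes and a mean shift of `tool_separation` on each tool's own
scale, plus region-dependent missingness that mirrors real tool
behaviour: dbscSNV/SPIDEX only score canonical donor/acceptor variants,
CADD and Spliceogen only simple substitutions, the branchpoint tool only
intronic variants, and the deep-learning tools score complex variants
through their decomposition parts only (so the max rule is exercised
end-to-end). With `tool_separation = 0` the classes are
indistinguishable by construction (same mean *and* spread), and
`label_mode = "random"` detaches labels from the planted sequence
features — the matched null under which held-out auROC must sit at
chance.

What the generator does **not** emulate: real genome composition,
inter-tool score correlations (tools err independently here, which makes
consensus easier than in reality), realistic score distributions, or
curated-dataset ascertainment biases. Passing recovery tests therefore
demonstrates that the machinery is correct and calibratable, not that
real-data performance will match the synthetic numbers.

## Calibration conventions

PR curves sweep one point per distinct score, descending; a call is
`score >= threshold`, so tied scores share a point. auPRC uses step-wise
(rectangular) integration over recall with the precision at recall 0
anchored to the top-ranked point — PR interpolation conventions differ
between packages, so the convention is fixed, documented, and every
reported operating point is exactly recomputable from the raw scores.
auROC is the rank-based Mann–Whitney statistic (ties count 1/2).
Threshold selection searches both directions: lowest threshold at a
target precision or specificity, highest threshold at a target
sensitivity (whether a published high-specificity operating point was
found by specificity- or sensitivity-targeted search is ambiguous in
general, so both are provided). Region-stratified recall reports empty
strata as undefined (`NA`), never 0.

Cross-validation is stratified and deterministic per seed; per-fold
auROC/auPRC require both classes in every held-out fold, so leave-one-out
is rejected rather than reported with undefined fold metrics.

## Determinism and provenance

Every runner is pure with respect to its inputs: identical inputs and
seed give byte-identical outputs (tested at file level). Outputs embed
the package version and a config hash but never timestamps — run times go
to stderr logs. Models serialise to versioned JSON at 17 significant
digits, which round-trips doubles exactly; loading verifies the feature
registry hash.

## Problem sizes

The test suite trains on hundreds to two thousand synthetic variants and
the acceptance script on the 2000-variant reference conditions with
ten-fold cross-validation — sizes chosen so the full property suite
(including two complete pipeline runs for the determinism check) stays
comfortable on a single CPU while keeping every class of planted variant
populated.

## Known limitations

* The tree is a single learner; variance across retrainings is visible as
  threshold wobble near ties (mitigated by deterministic tie-breaking).
* ESE/ESS deltas use synthetic stand-in matrices until the user supplies
  experimentally derived ones.
* Intronic splicing enhancers/silencers are out of scope (an open problem
  field-wide), as is predicting the functional outcome (exon skipping vs
  intron retention) rather than the probability of impact.
* BED gene models carry no transcript structure, so splice-site features
  degrade to in/out-of-region subsetting.
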