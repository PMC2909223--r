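---
title: "Predicting PDZ domain-peptide interactions from reduced-alphabet n-grams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting PDZ domain-peptide interactions from reduced-alphabet n-grams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdzgram)
```

## The problem

PDZ domains are compact (80-90 residue) protein-interaction modules --- six
beta strands and two alpha helices --- that recognize the extreme C-terminus
of their partner proteins. The identity of the peptide's last residue
(position 0) and third-from-last residue (position -2) largely determines
recognition: Class I domains bind S/T-X-$\Phi$ tails, Class II bind
$\Phi$-X-$\Phi$, Class III bind D/E-X-$\Phi$ (with $\Phi$ hydrophobic and X
anything), and promiscuous "Class I-II" domains accept both Class I and
Class II ligands. `pdzgram` asks two questions from primary sequence alone:

1. **Interaction prediction** --- will this PDZ domain bind this peptide?
2. **Class prediction** --- is this domain Class I, II, or I-II?

## Sequence encoding

Sequences are mapped onto a seven-class reduced amino-acid alphabet defined
by side-chain volume and dipole moment (`reduced_alphabet()`): {A,G,V},
{I,L,F,P}, {Y,M,T,S}, {H,N,Q,W}, {R,K}, {D,E}, and {C} alone. A sequence of
length $L$ then yields $L-2$ trigrams (or $L-1$ bigrams) over the digits
1-7, and its feature vector is the normalized count of each possible gram:
$343 = 7^3$ trigram features or $49 = 7^2$ bigram features per sequence,
each vector summing to 1.

An interaction instance concatenates the domain's block and the (truncated)
peptide's block: 686 trigram or 98 bigram features. Peptides are truncated
to their 10 C-terminal residues before encoding, since PDZ recognition
extends at most to about position -10. A class instance uses the domain
block only (the peptide classes *are* the label). Feature columns are named
`pdz_tg_356`, `pep_bg_12`, ... in lexicographic gram order; this naming is
part of the on-disk contract so that saved models and selected-feature
tables are portable.

Non-standard residues (X, B, Z, U, gaps) are rejected with a positional
error rather than silently skipped: in a 10-residue peptide a single
mis-parsed residue moves 30% of the feature mass.

## The classifier

A Random Forest (`train_forest()`, backed by the `randomForest` package)
with two tunable parameters: `numTree` (default 200) and `numFeature`, the
number of candidate features per split (default 30). Parameters are chosen
by out-of-bag (OOB) error --- each tree is evaluated on the instances its
bootstrap left out --- via `grid_search_oob()`, whose default grids
(`numTree` 10-500, `numFeature` 5-100) bracket the defaults. Ties resolve
toward the smaller `numFeature`, then the smaller `numTree`, preferring the
cheaper model. On data sets whose informative features are few dozen
needles among hundreds of near-noise columns the OOB surface keeps
improving up to `numFeature` equal to a whole block (343); the synthetic
benchmark below therefore runs at `numFeature = 343`, `numTree = 500`,
while 200/30 remains the package default for real, diffusely informative
sequence data.

`predict_score()` reports the fraction of trees voting for each class
(rows sum to 1); the label is the argmax with ties broken toward the class
listed first in the model's class list, so binary predictions at a 0.5 vote
split default to the positive (binding) class deterministically.

Imbalanced tables can be stabilized by stratified resampling with
replacement (`resample_stratified()`): the output has exactly the input's
per-class counts, instances drawn with replacement. During cross-validation
this is applied *inside* each training fold by default; applying it before
the fold split (available as `resample = "before-cv"`) duplicates instances
across folds and leaks test information, so it is not the default even
though some pre-processing pipelines order it that way.

## Evaluation

`confusion_metrics()` implements TPR = TP/(TP+FN), FPR = FP/(FP+TN),
precision = TP/(TP+FP), accuracy = (TP+TN)/total; a zero-denominator ratio
is reported as `NA` (undefined), never 0. Worked example: a validation set
of 27 binding and 62 non-binding pairs with 25 and 46 classified correctly
gives accuracy $71/89 = 79.8\%$ and TPR $25/27 = 0.926$. For three classes,
accuracy pools per-class counts: $ (43+16+19)/(45+20+21) = 90.7\%$.

`roc_curve()` sweeps the decision threshold over distinct scores (ties
grouped), giving points monotone from (0,0) to (1,1); the trapezoidal AUC
equals the Mann-Whitney concordance probability with half credit for ties,
and the test suite checks this identity against a brute-force pairwise
count to 1e-12. `pr_curve()` reports (recall, precision) along the same
sweep. For the 3-class task the single reported AUC is the class-size
weighted mean of one-vs-rest AUCs, which reduces exactly to the binary AUC
when only two classes are present.

`cross_validate()` uses stratified fold assignment (each fold's class
proportions within one instance of the global ones), deterministic given
its seed; every instance is tested exactly once; confusion counts are
pooled across folds (micro aggregation) before metrics are computed, with
per-fold accuracies also returned. Stratification matters because an
unstratified split of a 1:2 imbalanced table can starve folds of positives.

## Feature selection (CFS)

Correlation-based feature subset selection scores a subset of $k$ features
by

$$\mathrm{merit} = \frac{k\,\bar r_{cf}}{\sqrt{k + k(k-1)\,\bar r_{ff}}}$$

where $\bar r_{cf}$ is the mean feature-class correlation of its members
and $\bar r_{ff}$ the mean absolute pairwise Pearson correlation among
them: good subsets correlate with the label but not with each other. The
feature-class correlation is the absolute point-biserial correlation for
binary labels and the one-hot multiple correlation
($\sqrt{SS_{between}/SS_{total}}$) for three classes; the two coincide for
two classes. Correlations are computed on the raw frequency columns with
no discretization --- a deliberate choice, stated so results are
reproducible, avoiding an arbitrary binning step. A zero-variance column
has correlation 0 by definition.

Two deterministic search strategies are provided: greedy forward selection,
and best-first search over add/remove-one-feature moves that stops after 5
consecutive non-improving expansions. Best-first explores a superset of the
greedy frontier and never returns a worse subset. `select_features()` runs
every configured strategy and combines the subsets (union by default,
intersection by flag), and for interaction tables searches the domain and
peptide blocks separately, mirroring how domain-side and peptide-side
features are reported downstream. Ties in merit resolve to the
lowest-index feature, so runs are reproducible.

A consequence worth knowing: CFS prunes *redundant* markers by design. If
two planted grams are perfectly penetrant in the same class, one of them is
enough to explain the label and the other is (correctly) dropped. Marker
recovery should therefore be assessed in the partial-penetrance regime
(below), where each marker carries complementary information.

## Motif mapping

`motif_report()` ties selection to sequence interpretation: selected
bigrams that occur inside selected trigrams (the consensus rule,
`consensus_features()`) are slid across a user-supplied multiple alignment;
at each start column a row counts only if its window is gap-free, and
occupancy is matching rows over gap-free rows. Hits above `min_occupancy`
(default 0.7 --- our operationalization of "most conserved", configurable)
are annotated with user-supplied secondary-structure column ranges and
ranked by maximum occupancy. On real PDZ alignments this surfaces the
carboxylate-binding-loop signature "12" (small hydrophobic followed by
large hydrophobic --- the GLGF motif), and motifs near the ligand-binding
alphaB helix such as "25". Computing the alignment itself and assigning
secondary structure are out of scope; both are consumed as inputs.

## The synthetic benchmark

`synth_config()` defines a fully synthetic PDZ study with recoverable
ground truth, at the scale of a realistic interaction screen: 85 domains
(80-90 residues), 181 peptides (10-mers), 500 sampled domain-peptide
pairs, 5% label noise. Domain classes I / II / I-II are drawn at
proportions 45:20:21; peptide classes I / II / III at 0.4/0.4/0.2. The
binding rule is class matching --- a peptide binds iff its class belongs to
the domain's accepted set, I-II accepting both --- and observed labels flip
independently with probability $\varepsilon$, so the Bayes-optimal accuracy
is $1-\varepsilon$ by construction.

Choices the generator makes, and why:

* **Concentrated peptide signal.** Generated peptides fix position -1 to a
  class-1 residue (A/G) and position 0 to V/I/L, and draw the Class II
  anchor from F/I/L rather than all hydrophobics, so each peptide class
  maps to a handful of C-terminal reduced trigrams. Real ligands diffuse
  this signal over many grams (and Y/M anchors would collide with the S/T
  reduced class); the benchmark plants it recoverably, which is the
  generator's job.
* **Class-conditional composition.** Each domain class enriches a small
  residue set (Class I: R,K,Y,M; Class II: D,E,I,L; I-II both sets) by a
  weight factor of 6 in its background draw, emulating the compositional
  differences real specificity classes show. Peptide bodies echo the
  composition of the class they target. This spreads class information
  over many weak features --- the regime Random Forests exploit --- rather
  than leaving it only in needle-in-haystack markers.
* **Promiscuous domains look like both classes.** Class I-II domains carry
  a Class I gram and a Class II gram plus their own marker ("147"), and
  both composition biases, so promiscuity is an overlay of the two
  specificities rather than an arbitrary third pattern.
* **Partial penetrance.** Each domain carries any given one of its class's
  planted trigrams with probability 0.7 (`gram_penetrance`), inserted 3
  times when present. Five distinct planted grams ("356", "335", "642",
  "624", "147") are each individually informative but none sufficient, so
  feature selection must retain several --- the regime in which marker
  recovery is a meaningful test.
* **Alignment.** `generate_alignment()` pads domains with terminal gaps and
  plants one gap-free conserved block (default motif "12" at column 20,
  carried by 95% of rows), giving motif mapping a known answer.

What the generator does **not** emulate: phylogenetic relatedness among
domains, realistic binding free energies or affinity gradations,
position-specific conservation outside the planted blocks, and alignment
uncertainty. Passing the recovery suite shows the pipeline recovers planted
structure at realistic scale and noise; it does not certify accuracy on
real screens.

## Problem sizes and seeds

The end-to-end checks run 10-fold cross-validation on the 500-pair
interaction benchmark with a 500-tree, 343-candidate-feature forest
(accuracy is compared against the 0.95 Bayes ceiling), a 90-domain 3-class
benchmark at the 200/30 defaults, CFS marker recovery on a 90-domain set
with composition bias disabled (so the five planted grams are the only
signal), and motif ranking on the planted alignment. All randomness flows
from explicit integer seeds; two runs with the same configuration and seed
produce identical reports.

## Known limitations

* Forest training cost grows with `numFeature`; the benchmark operating
  point (500 trees x 343 candidates) takes a few minutes of CPU at 500
  instances.
* The CFS implementation evaluates merits from a precomputed correlation
  matrix; for feature spaces far beyond 10^3 columns a sparse or cached
  strategy would be needed.
* `peptide_class()` requires at least 3 residues and treats any
  non-matching tail as `unclassified`; domains whose binding evidence is
  all Class III or unclassified are `unassigned` and excluded from the
  class task.
* The hydrophobic set $\Phi$ defaults to {A,C,F,I,L,M,V,W,Y}; no single
  published hydrophobicity scale is canonical, so it is a configurable
  knob, constrained to stay disjoint from S/T/D/E to keep the three class
  rules mutually exclusive.
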