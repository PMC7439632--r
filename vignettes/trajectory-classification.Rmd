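---
title: "Classifying disease trajectories from predicate paths: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying disease trajectories from predicate paths: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajpath)
```

## The problem

A *disease trajectory* is an ordered pair of diseases that tends to be
diagnosed in that temporal sequence (rheumatoid arthritis before heart
failure, say).  trajpath asks whether such temporal order can be read off a
*protein knowledge graph*: a collection of subject–predicate–object triples
between proteins ("A inhibits B", "A binds with B"), where the predicate's
direction runs from subject to object.  Each disease is represented by its
*disease proteins* — the proteins encoded by genes curated as associated with
it — and a candidate disease pair is described entirely by the paths that
connect the two protein sets.

The scientific question the package is built around: does the *directional*
information of predicates (which protein is subject, which object) add
anything over knowing merely that the proteins are connected?

## Path scenarios

Only paths of one or two triples are used; longer paths explode
combinatorially and dilute interpretability.  Between protein sets $A$ and
$B$ three scenarios arise:

* **overlap** — a protein in $A \cap B$, optionally with self-loop triples
  (e.g. homodimerization);
* **direct** — a single non-loop triple joining $a \in A$ and $b \in B$, in
  either orientation;
* **indirect** — a two-triple path $a - m - b$ through one intermediate
  protein $m$.

Conventions that the enumeration fixes (and that the test suite asserts):

* an edge is *forward* when its subject is the node nearer the first disease
  along the traversal; swapping the two sets mirrors every path and flips
  every orientation;
* the two legs of an indirect path must be distinct triples, so a degenerate
  $a - m - a$ walk that re-uses one triple in both directions is not a path;
  endpoints may coincide when a shared protein reaches itself through an
  intermediate via two different triples;
* the intermediate protein may itself be a disease protein of either set
  (there is no biological reason to exclude it; an
  `exclude_disease_intermediates` flag exists for sensitivity analysis);
* self-loop triples appear only in the overlap scenario;
* parallel edges (same protein pair, different predicate or direction) give
  distinct path instances, but provenance never multiplies paths.

## Feature sets

Paths are encoded as binary *signatures*, `scenario|component` strings; a
candidate's feature vector records which signatures occur at least once (all
features are presence-based — counts are deliberately not used).  Two choices
generate the four primary feature sets:

* **representation** — *metapath* encodes an indirect path's ordered
  predicate sequence as one feature (`indirect|p1->p2`); *split path* encodes
  each predicate separately (`indirect|p1`, `indirect|p2`).  Direct paths are
  length-1 metapaths, identical under both.
* **direction mode** — *undirected* strips all orientation; *mixed* keeps
  `:fwd`/`:rev` markers only on predicates categorized as directed by expert
  assessment; the supplementary *directed* mode orients everything, including
  self-loops (marked `:loop`).

In the undirected and mixed modes, self-loop predicates of the overlap
scenario never carry orientation (subject and object are the same protein, so
orientation is meaningless); a loop-free shared protein contributes the bare
`overlap` signature.  This decomposition of the overlap scenario — one
presence bit plus one bit per loop predicate — is this package's explicit
choice.  The `->` separator and the `fwd`/`rev`/`loop` markers are likewise
this package's stable conventions.

The predicate directionality table ships with the package: 47 predicates, 12
undirected and 35 directed.  The undirected entries follow a published expert
consensus; the directed names are a synthetic reconstruction of a typical
standardized biomedical predicate vocabulary (the fixture file name carries
the `synthetic` marker).  Negated predicates (`does not interact with`)
automatically inherit the category of their base predicate; the
implementation strips the negation prefix and re-conjugates the leading verb
to third person ("interact" → "interacts").  Predicates are compared
case-insensitively after whitespace normalization because source tables mix
capitalizations.  Unknown predicates raise an error by default — silently
guessing a direction category would corrupt the mixed variant — with an
opt-in flag to treat them as undirected.

## Evaluation protocol

Random forests (`ranger`, probability forests) classify candidate pairs.
Performance is the mean and standard deviation of per-fold test AUCs over 10
repeats of 10-fold cross-validation.  Design choices:

* **folds are stratified** so the rare positive class reaches every fold in
  small cohort-style designs; this is a deliberate choice and is exposed
  through `make_folds()`;
* **fold maps are shared across feature variants**: every variant of one
  paired run is trained and tested on identical partitions, so per-fold AUC
  differences can be tested with a two-sided paired t-test
  (`paired_fold_ttest()`, degrees of freedom = matched cells − 1).  Pairing
  all 100 repeat × fold cells is the default; per-repeat means are available
  behind the `granularity` argument, since either pairing granularity is
  defensible;
* comparing results with different fold maps is refused, not approximated;
* AUC is computed by the Mann–Whitney rank formula (ties counted half), and
  the Youden operating point (maximizing sensitivity + specificity − 1) by an
  exhaustive scan over observed cutoffs, ties broken towards higher
  sensitivity and then lower cutoff.  Both are cross-checked against pROC in
  the test suite;
* `undersample()` draws seeded uniform subsets to match a smaller reference
  design (e.g. 55 positives / 370 negatives);
* forest hyperparameters default to 500 trees and $\sqrt{p}$ candidate
  features per split, all exposed; the packaged simulation studies use
  200-tree forests, which at a few hundred candidates leave the AUC estimates
  essentially unchanged while keeping full 10×10 grids affordable;
* every stochastic step consumes one run-level seed, expanded
  deterministically per component, and never disturbs the caller's RNG state.

## The synthetic benchmark generator

No public corpus provides the paired inputs needed to test the pipeline end
to end (a proprietary knowledge platform and licensed terminology tables
stand behind the real data), so the generator produces all five inputs —
triples, directionality table, code→concept mapping, subclass hierarchy,
gene–disease associations, labelled pairs — with a *planted* association
between trajectory direction and predicate orientation:

> On paths sampled for a positive pair $(A, B)$, each edge carrying a
> directed predicate has its subject placed on the $A$ side with probability
> $\tfrac12 + \tfrac{\beta}{2}$.  For negatives and for undirected
> predicates, orientation is uniform.

Design decisions, and what they mean for interpreting results:

* **signal lives in orientation only.**  Edge *existence* is sampled
  identically for positive and negative pairs (same Poisson path counts, same
  predicate draws), so undirected feature sets form a proper baseline and any
  mixed-variant gain isolates directionality.  Orientation decisions consume
  a dedicated uniform draw per edge, so changing $\beta$ with a fixed seed
  changes orientations and nothing else — the test suite asserts that
  undirected feature matrices are bit-identical across $\beta$.
* **reversal negatives force temporal-order learning.**  With
  `negative_mode = "reversal"` each negative is the reversed positive and
  shares its edges; the two twins have identical undirected vectors and
  mirrored oriented vectors, so only orientation separates the classes.
* **disease set sizes are log-uniform** (default 5–60), emulating the
  strongly right-skewed set sizes of curated gene–disease catalogues without
  claiming their exact distribution; presets `jensen_like` (registry-scale,
  all-pairs negatives, sizes 7–94) and `vandenakker_like` (55 positives, 315
  random + 55 reversal negatives, sizes 17–167) approximate the two
  reference-set shapes at reduced scale.
* **predicate usage is Zipf-distributed** by default (weight $1/\mathrm{rank}$
  over a seeded permutation of the 47-predicate vocabulary), emulating the
  heavy-tailed predicate frequencies of real knowledge graphs.  Uniform usage
  is available but unrealistic: it makes every indirect metapath a
  near-unique column.
* **background noise** is parametrized as edges per protein
  (`background_degree`, default 0.5) plus per-protein self-loops (5%), so
  noise scales linearly with the universe.

### What the generator does and does not emulate

It reproduces the statistical *shape* of the task — skewed set sizes, skewed
predicate usage, scenario mix, reversal structure, class imbalance — but not
the topology of any real interactome: no hubs, no modules, no correlation
between a protein's degree and its disease associations, and gene–disease
associations are sampled independently per disease.  Passing tests therefore
demonstrate that the pipeline recovers an orientation signal when one exists
and reports chance when none does; they do not certify performance on real
knowledge graphs.

### Two subtleties found while validating the null

Both are properties of cross-validation on *dependent* candidates, worth
knowing before interpreting any run:

* **twin memorization.**  In a pure reversal design the undirected variants
  score systematically *below* 0.5: a candidate and its reversal have
  identical undirected vectors with opposite labels, and when one twin is in
  the training split the forest memorizes its label and inverts the
  prediction for the other.  The mixed-vs-undirected contrast remains valid
  (the paired comparison is what carries the claim), but the undirected
  baseline in reversal designs should not be read as "chance".
* **shared-disease coupling.**  When candidates share diseases, finite-sample
  fluctuations in a disease's protein-set size or class share leak through
  overall signature richness and can push a $\beta = 0$ run several AUC
  points off 0.5 in either direction.  The generator's `disjoint` mode —
  every candidate gets its own two diseases, making rows structurally
  independent — is therefore used for null calibration, and the
  `rewired` mode (degree-matched re-pairing) is available as a middle ground.

## Problem sizes of the packaged studies

The packaged validation experiments use: a null study at $\beta = 0$ with 300
positive and 300 negative disjoint pairs over 1200 diseases and 3000
proteins, and a signal study at $\beta = 0.8$ with 200 positives and their
200 reversals over 100 diseases and 1500 proteins; both evaluated with 10×10
cross-validation and 200-tree forests.  At these sizes the whole suite runs
on a single CPU in well under half an hour.  Larger universes sharpen the
contrast further (cross-talk paths between unrelated pairs shrink) but add
nothing qualitative.

## Known limitations

* Candidate pairs whose protein sets are identical are retained (they can
  only differ through orientation features); they are logged for audit.
* The negative space of real registry designs is constructed as "all ordered
  pairs minus positives"; its size is not independently validated against any
  published count.
* The t-test on 100 repeat × fold cells treats cells as exchangeable; cells
  within a repeat share training data, so the nominal degrees of freedom are
  optimistic — a caveat inherited from the protocol itself.
* No feature selection, weighting, calibration, or alternative learners: the
  package isolates one question (does predicate directionality help?) under
  one learner (random forests).
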