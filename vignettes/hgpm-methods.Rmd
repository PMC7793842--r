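---
title: "Hierarchical graphs of pharmacophore model ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical graphs of pharmacophore model ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgpm)
```

## The problem and the representation

A molecular dynamics trajectory of a protein–ligand complex yields one
structure-based pharmacophore model per frame: the set of chemical
interaction features (hydrophobic contacts, hydrogen-bond donors/acceptors,
aromatic, ionizable and halogen-bond features) present in that snapshot.
Over 10,000 frames this is far too much to inspect model by model, yet the
ensemble is highly redundant: most frames realize one of a modest number of
distinct interaction patterns.

`hgpm` represents each model as a binary feature vector over the catalog of
*unique features*. A unique feature is identified purely combinatorially by

* its interaction type (`H`, `AR`, `HBA`, `HBD`, `PI`, `NI`, `XBD`),
* the ligand atoms involved, and
* the interacting protein residues,

never by 3D position. Two hydrogen-bond acceptors on the same ligand
nitrogen count as different features if one reaches a serine and the other a
threonine. Identifier lists are sorted and deduplicated, so feature equality
is string equality of the canonical serial (`"HBA|N1|ARG63"`), which makes
deduplication, counting and hashing trivial. A *projected* mode drops the
ligand atoms (`"HBA|ARG63"`), trading ligand-side resolution for the ability
to pool ensembles obtained with different ligands of the same protein. We
interpret the ligand side of a feature as the set of ligand atom
identifiers: distinguishing features by the specific ligand atom (e.g. a
fluorine) is what makes the ligand-aware mode informative, and a
whole-ligand label would not support that. Hydrophobic environment sets are
kept verbatim — a feature whose residue set is a strict subset of another's
remains a distinct feature, mirroring how perception software emits them.

Identical vectors are merged; the number of frames carrying exactly a given
vector is its **appearance count**. Low-count vectors are noise and are
filtered: the threshold is either an absolute minimum (2 by default) or a
fraction of the initial frame count, `floor(fraction * n_frames)`, bounded
below by 2. Frames whose model is empty contribute no vector but still count
toward `n_frames`. Crystal-structure reference models are exempt from the
filter so that their nodes are always present for comparison.

## The hierarchy

The surviving unique vectors are ordered by strict subset inclusion of their
feature sets. Two additions make this a useful picture:

1. **Intersection closure.** If two nodes overlap without one containing
   the other, the node family is extended with their intersection, flagged
   *artificial* and carrying appearance count 0. The closure is run to
   fixpoint (intersections of artificial nodes included), implemented as
   incremental insertion — each incoming set is added together with its
   intersections against everything already present, which yields the full
   fixpoint because intersection is associative. Closure is what makes the
   graph *unique*: any two nodes with common features have exactly one meet
   node, and the node set does not depend on the order in which models are
   processed. Empty intersections create nothing; the graph deliberately has
   no universal root, so unrelated interaction patterns stay in separate
   components.
2. **Transitive reduction.** Of all subset/superset links only the cover
   relation is kept (no third node strictly between the endpoints). The
   reduction of a partial order is unique, so the edge set is canonical.
   Edges are directed subset → superset, i.e. from general to specialized.

The closure may create more artificial nodes than an implementation that
only intersects observed pairs once; we accept this, since only the fixpoint
is order-independent. If an intersection coincides with an observed vector,
no new node is created and observed status wins.

## Layout

The layout is deterministic and seedless:

* **x** is the feature count, so every cover edge points strictly
  rightward and columns group models of equal specificity;
* **y** is a one-dimensional classical (Torgerson) multidimensional scaling
  of the pairwise Manhattan distances between feature vectors (equal to
  Hamming distances on bits). The squared-distance matrix is double-centered
  and the leading eigenpair taken; coordinates are centered, and the sign is
  fixed so the node with the lexicographically smallest bit pattern sits at
  a non-positive coordinate, making output files byte-stable;
* the **variance of the projection**, reported with every layout, is the
  leading eigenvalue over the sum of the *positive* eigenvalues, as a
  percentage. Manhattan distances need not be Euclidean-embeddable, so
  negative eigenvalues can occur; they are excluded from the denominator. A
  configuration that is exactly 1-D embeddable gives 100 %; an equilateral
  triple gives 50 %. Values of 10–20 % are typical for real ensembles and
  simply mean the vertical axis is a coarse similarity cue, which is why it
  is reported rather than hidden.

We chose classical scaling over iterative stress majorization because it is
deterministic without a seed and its eigenvalue ratio gives the variance
diagnostic directly. Node display sizes map appearance counts affinely onto
`[size_min, size_max]` (defaults 4–20); artificial nodes always get the
minimum. Ties in y are left untouched; a seeded jitter is available at
render time for dense graphs.

Degenerate inputs are defined, not accidental: a single node (or all-zero
distance matrix) gets coordinate 0 and variance 100; equal positive counts
all map to the maximum size.

## Selection and screening metrics

Typical anchors are the highest-frequency node (ties broken by larger
feature count, then lexicographic bit pattern), the crystal-structure node,
or a node holding designated common features, found by exact vector lookup.
A *superset selection* collects every node whose set contains the anchor's;
artificial nodes are excluded by default because no screening model exists
for them. Each selected node is represented by the first model observed with
its vector — smallest `(run_id, frame_index)` in lexicographic run order
(runs are concatenated without a canonical order, so the lexicographic
convention is documented rather than inherited).

Consensus scoring is the plain common-hits count: a molecule's score is the
number of selected models that retrieve it, with deterministic tie handling.
Screening performance is summarized as **truncated ROC AUC** at a percentage
of the database: retrieved molecules (score > 0) are ranked by descending
score; tie blocks are traversed as straight segments; the curve ends at the
last retrieved molecule; it is cut after `ceil(percent/100 * N)` screened
molecules (interpolating inside a tie block) and the area is normalized by
the false-positive rate reached at the cutoff. No actives retrieved gives
0.0; a cutoff reached without screening any decoy gives 1.0. The exact
formula used by commercial screening software is unpublished; this
convention is fully documented, reproduces the qualitative behavior that a
selection retrieving nothing scores 0.00 at every level, and is checked
against an independent all-thresholds sweep oracle in the tests. One
consequence worth knowing: when very few decoys are retrieved, the rank of
each one carries enormous weight, so AUC values in that regime are volatile
by construction.

## The synthetic generator

Real ensembles require MD simulation and feature perception; the generator
provides matched stand-ins with known ground truth so that every stage of
the pipeline is testable end to end.

* **Trajectories.** Each feature follows an independent two-state Markov
  chain with `P(on→on) = p + ρ(1−p)`, `P(off→on) = p(1−ρ)` and initial state
  `Bernoulli(p)`, so its stationary marginal is exactly `p`; `ρ ∈ [0, 1)` is
  the frame-to-frame persistence (MD frames are autocorrelated; defaults
  0.3–0.6). Optional latent *binding modes* switch the per-feature `p`
  vector through a Markov mode sequence, producing ensembles whose graphs
  show multiple specialized branches. The default alphabet
  (`example_feature_table()`) is a realistic kinase activator site: three
  persistent polar anchors (p = 0.85–0.92, the "core"), plus hydrophobic,
  aromatic and halogen features of decreasing stability (p = 0.55 down to
  0.05). Default ensembles use 500 frames for statistical checks and 10,000
  frames for the scale run, matching the frame counts this kind of analysis
  is used at.
* **Libraries.** Actives contain the full core with probability 0.9 and
  each peripheral feature with probability 0.5 — binders are feature-rich
  and almost always satisfy the anchoring interactions. Decoys carry each
  feature independently with probability 0.1 — sparse, occasionally
  core-containing by chance. These values put the screen in the regime the
  method is meant for: consensus scores of actives are driven by many
  matching models, while the rare lucky decoy matches only a few.
* **Screening stub.** A molecule is a hit for a model iff the model's
  feature set is a subset of the molecule's and the model has at least three
  features; smaller models cannot be unambiguously aligned in 3D and return
  no hits.

What the generator does *not* emulate: correlated features beyond the latent
mode (real features co-occur through shared geometry), 3D alignment scores,
conformational multiplicity of library molecules, and chemically meaningful
decoys. Passing tests therefore demonstrate the correctness of the
combinatorial machinery and the qualitative enrichment behavior, not
screening performance on real libraries.

## Numerical and interface choices

* Catalog order is the lexicographic (byte-wise, locale-independent) order
  of canonical serials; every bit position, node id and output file is
  therefore reproducible across runs and platforms.
* Node ids are the bit pattern packed into hex — content-derived, injective
  and stable across file round-trips.
* Graph JSON stores patterns as hex plus the catalog and writes doubles
  with 17 significant digits, so `read_graph(write_graph(g))` is exact and
  repeated writes are byte-identical.
* Eigenvalues below `1e-9` (relative) are treated as zero in the MDS
  variance; the all-thresholds AUC agrees with its oracle to machine
  precision.
* Identifiers may not contain `|` or `,` (the serial separators); the
  constructors enforce this, which is what makes serialization injective.
* The PML importer is best-effort: it maps known feature-type names and the
  `ligandAtoms` / `targetResidues` annotations, and logs what it skips.

## Problem sizes used in the tests

Unit and property tests run on alphabets of 3–12 features with up to 60
observed sets, against brute-force oracles (fixpoint closure, cubic
transitive reduction, all-thresholds ROC sweep) over hundreds of random
instances; statistical checks use 20 × 500-frame trajectories and 10-seed
screening replicates; the scale check runs the full pipeline — simulate,
build, lay out, export JSON and HTML — on a 10,000-frame ensemble, which
completes in seconds.

## Known limitations

* Feature perception is out of scope: the package consumes tabular feature
  assignments and never reads coordinates, trajectories or structures.
* The subset hierarchy is exact, not approximate: near-duplicate vectors
  differing in one noisy feature remain distinct nodes (the appearance-count
  filter, not fuzzy matching, is the noise control).
* Artificial-node counts grow with ensemble heterogeneity; the fixpoint
  closure can add more intersections than a single observed-pair pass.
* The truncated-AUC convention is one of several defensible choices and
  absolute values should not be compared against numbers produced by other
  software; within-package comparisons are consistent.
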