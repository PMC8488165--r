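---
title: "Scoring and placing protein hydration sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and placing protein hydration sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Crystallographic water molecules mediate protein-ligand recognition,
bridge secondary structure and shape binding-site thermodynamics, yet most
deposited structures resolve only part of their hydration shell and
computationally predicted structures carry none at all.  `hydrosite`
predicts explicit water-oxygen positions for a heavy-atom protein
structure.  Its core is a learned, everywhere-differentiable score
function

$$\mathrm{Score}(\mathbf{p} \mid prot)\; \approx\; \mathrm{Norm}\big(d(\mathbf{p},
\text{nearest missing water})\big),$$

which estimates, for an arbitrary 3D position $\mathbf{p}$, the (squashed)
Euclidean distance to the nearest water molecule that is *not* present in
the input structure.  Because the function is differentiable in
$\mathbf{p}$, water positions are found by gradient descent rather than by
scanning a discrete grid of scores.

## The scoring model

Every atom within the 4.0 Å receptive field of $\mathbf{p}$ contributes an
*interaction embedding* built from two kinds of terms:

* a **distance term** — the atom-type embedding of atom $q$ concatenated
  with $|\mathbf{q}-\mathbf{p}|$, the analogue of an isotropic pair
  potential;
* an **angle term** per bonded neighbour $r$ of $q$ — both atom-type
  embeddings, the bond-type embedding and
  $\cos\angle(\vec{qp},\vec{qr})$, which captures the anisotropy (lone
  pairs, hydrogen-bond directionality) that isotropic terms miss.

Atom types are keyed by element, heavy-atom degree, hybridization and
aromaticity; the table enumerates the full cross product over C/N/O/S plus
an unknown fallback, so lookups are total.  Waters in the environment are
ordinary atoms with their own "water oxygen" type — this is what lets the
model express water-water stabilization.

All vector-to-vector blocks are **PolyNN** layers,

$$x_1 = \mathrm{Swish}(W_0 x_0 + b_0), \qquad
  x_2 = \exp(W_1 \log(1 + x_1)) - 1, \qquad
  x_3 = W_2 x_2,$$

whose log/exp middle layer models smooth algebraic interactions rather
than the step-like structures ordinary MLPs tend to learn.  Because
$\mathrm{Swish}(z) \ge -0.2785$, the argument of the log is bounded below
by $0.72$ and the layer is defined everywhere.  Sets of vectors (terms
within an atom, atoms within the field) are pooled by the **statistical
reduction**: concatenate component-wise sum, mean, maximum and population
standard deviation, then apply a PolyNN.  The reduction is permutation
invariant; summation order is canonicalized (protein atoms by serial, then
waters) so results are reproducible bit for bit.

An empty receptive field returns the worst score 1.0 with zero gradient,
so the placer never builds waters in a vacuum.

The forward pass and its exact backward pass (with respect to the probe
position, to environment water positions, and to every parameter) are
hand-derived and implemented in compiled code under `src/`; unit tests
verify the analytic gradients against central finite differences at
relative error below $10^{-4}$, and the forward pass against an
independent straight-line reimplementation at $10^{-10}$.

## Labels, weights and training

Distance labels are squashed by

$$\mathrm{Norm}(d) = \frac{2}{1 + 2^{-5d}} - 1,$$

which is steep below ~0.4 Å and nearly flat beyond 0.8 Å
($\mathrm{Norm}(0)=0$, $\mathrm{Norm}(0.2)=\tfrac13$,
$\mathrm{Norm}(\infty)=1$): errors of several Ångström matter no more than
errors of one.  Each instance is weighted
$1 + 1.5\,\mathrm{amino}_i + \mathrm{water}_i$, the counts of residues and
waters touching the probe's receptive field, prioritizing buried,
well-determined waters over bulk-exposed ones.

Four instance classes drive training:

1. **positives** — each crystal water against the structure minus itself
   (label 0);
2. **nearby negatives** — the water displaced uniformly within 0.8 Å
   (label = distance to the nearest crystal water), teaching local
   curvature;
3. **random negatives** — uniform positions in the padded bounding box,
   rejected within 1.6 Å of any water *and rejected when their receptive
   field is empty*: the score there is the hard-wired worst value, so such
   probes carry no gradient signal (label $\infty$, full environment);
4. **dynamic hard negatives** — *leave-one-out* (the current model
   gradient-descends each positive's position; the optimized position is
   labelled by its distance to ground truth) and *end-to-end* (all waters
   stripped, the full placement pipeline run, every prediction labelled by
   its nearest crystal water).

The loss is the weighted squared error against the normalized labels plus
an L2 penalty ($\lambda = 10^{-6}$), minimized by Adam at a constant
learning rate of $2\times10^{-3}$ with minibatches of 64.  The default
static mix is 1 : 2 : 4 (positives : nearby : random) per crystal water;
the mix is a free knob of the method and these values simply worked well
on the synthetic benchmark.  End-to-end negatives are regenerated every 8
epochs on 6 structures in rotation, using a cheapened placement
configuration (fewer descent iterations, tighter rescoring radius, capped
water count) — the mined labels stay valid, mining just converges less
finely than evaluation-grade placement.

**Checkpoint selection.**  At desk scale the end-to-end feedback loop can
occasionally destabilize a run late in training (the learned minima drift
above the placement threshold).  Every mining round therefore doubles as
an evaluation: its placements are scored against the training structures'
own crystal waters (mean F1 at 1.0 Å) and `train_scorer()` returns the
best-scoring checkpoint.  Selection sees training data only; held-out
structures are never touched.

## Placement

Placement runs in two alternating phases until a placement pass accepts no
new water (capped at 20 alternations):

* **Iterative best-first placement.**  A grid of 0.8 Å boxes covers the
  padded bounding box — small enough that a box holds at most one water.
  Boxes closer than 1.8 Å to a heavy atom or beyond the receptive field of
  every atom are inactive.  Each active box's water is optimized by
  backtracking gradient descent (steps capped at 0.3 Å, at most 60
  iterations, convergence at $10^{-3}$ Å, positions confined to 1.2 Å of
  the box center).  The best-scoring candidate is accepted if it is at
  least 2.2 Å (a minimal O-O contact) from every existing water and
  clash-free; it joins the environment and only boxes within 6.0 Å are
  re-optimized (a new water can influence a probe only within the 4.0 Å
  receptive field plus optimizer motion; full rescoring is available via
  `full_rescore = TRUE`).  The pass stops when the best score exceeds the
  threshold 0.5 — about 0.32 Å of predicted distance under the label
  squashing.  This iterative scheme is what reveals second-shell waters:
  their sites only score well once the first-shell partner exists.

* **Joint refinement with local resampling.**  All predicted waters are
  optimized simultaneously under the summed score, including the cross
  terms through each other's receptive fields.  Then waters are clustered
  (single linkage at 3.5 Å) and each cluster's add-back subsets are
  enumerated (exhaustively up to 6 members — 64 subsets — greedily
  beyond), re-optimized, and scored by $\sum_{i \in \text{kept}}
  (s_i - \text{threshold})$; the best subset is kept.  This objective is
  the package's own choice for "the subset with the best score": it makes
  removing a water profitable exactly when that water is worse than the
  stopping threshold.  A final pass enforces the 2.2 Å O-O exclusion by
  dropping the worse of any violating pair.

Box acceptance is monotone in score within a pass up to the optimizer's
convergence tolerance; with water-dependent score fields (the second-shell
scenario) later acceptances can legitimately be better than earlier ones,
which is the intended behaviour, not a defect.

## Evaluation

Predictions are compared with crystal waters by optimal one-to-one
bipartite matching (maximum cardinality, then minimum total distance; a
compact shortest-augmenting-path assignment solver in `src/`) at the three
conventional cutoffs 0.5 / 1.0 / 1.5 Å, yielding precision = TP/#predicted,
recall = TP/#crystal and their harmonic mean F1.  A greedy-nearest matcher
is exposed for sensitivity checks.  Both pooled (corpus-level counts) and
per-structure macro averages are reported, because aggregate F1 values in
the literature are frequently not the harmonic mean of the printed
aggregate precision and recall, which signals per-structure averaging of
unstated form.  Binding-site evaluation keeps only waters within 4.0 Å of
both the protein and the ligand, applied symmetrically to both sets before
matching.  `categorize_waters()` buckets crystal waters by polar-atom and
water contacts (3.5 Å default) for recall breakdowns.

## The synthetic fixtures

Real training data would be thousands of curated crystal structures.  The
package instead ships a generator of toy structures with a deterministic
water rule, sized so every stage trains and tests on one CPU in minutes:

* six three-atom fragments (carbonyl C-C=O, hydroxyl C-C-O, propane-like
  C-C-C) at random orientations, centers at least 9 Å apart in a cube;
* a carbonyl oxygen anchors one water at 2.8 Å, in the fragment plane, at
  120° to the C=O bond (a lone-pair direction);
* a hydroxyl oxygen anchors a water *pair*: the first at 2.8 Å at the
  tetrahedral angle, the second at 2.8 Å from both the oxygen and the
  first water (an equilateral O-w-w motif, i.e. two donors sharing an
  acceptor plus a water-water hydrogen bond).  The pair geometry was
  chosen so each site is pinned by features visible inside its own
  receptive field (distances to the oxygen and partner water plus the
  angle term at the oxygen) — a rule the model can actually recover;
* 0.05 Å Gaussian jitter and a 5° cone of angular tolerance mimic
  coordinate noise;
* `polar_fraction` (default 0.5) controls how many fragments anchor
  waters; `second_shell_prob` defaults to 1 so the rule is deterministic.

What the fixtures do **not** emulate: bulk solvent, crystal contacts and
symmetry mates, B-factor/occupancy uncertainty, ions and ligands
competing for sites, long hydrogen-bond chains extending beyond the
receptive field, or the atom-type diversity of real proteins.  Passing the
desk-scale benchmark therefore demonstrates that the architecture,
training scheme and placer can recover a hydrogen-bond-like geometric
rule from data — not that the shipped defaults reach publication-grade
accuracy on the PDB.  Training on real structures is the same code path:
parse, perceive bonds, type, train.

The companion `analytic_scorer()` is a closed-form oracle — the
Norm-squashed soft-min distance to hidden targets, with optional
conditional targets that activate only when a trigger water exists — used
to test the placer independently of any trained model, including the
water-network scenario.

## Numerical choices and edge cases

* Hydrogens are discarded on input; waters are represented by their oxygen.
* Alternate locations resolve to the highest occupancy, ties by altloc
  letter; receptive-field membership is a closed ball; ties in the
  reduction's max pick the first index.
* Probe-on-atom geometry (distance ~0) is guarded at $10^{-9}$ Å; the
  angle term raises an error when the probe coincides with the central
  atom.
* The score is unconstrained above/below $[0,1)$; thresholding clamps
  nothing.  Minima can score slightly below 0 — harmless, since only
  comparisons against the threshold matter.
* Optimization is plain backtracking gradient descent with a 0.3 Å step
  cap; stochasticity exists only in data generation and batch order, so a
  run is reproducible from its seed.
* Desk-scale problem sizes used throughout the package's own tests:
  hidden width 16, embeddings 8/4, 50 training and 10 held-out fixtures,
  150 epochs.  These are the package's defaults for the synthetic
  benchmark; `scorer_params()` alone defaults to the larger 32/8/64/64
  widths a real-data training would start from.

## Known limitations

* The receptive-field cutoff is hard at 4.0 Å, so the score is
  discontinuous when an atom crosses the boundary; the radius is part of
  the method's definition, and no switching function is applied.
* Protein atoms never move; refinement optimizes waters only.
* The asymmetric unit is taken as given — no symmetry-mate expansion, so
  waters coordinated by crystal contacts are unlearnable from the file
  alone.
* The atom/bond-type vocabulary is a reconstruction from stated criteria
  (element, degree, hybridization, aromaticity); template hybridization is
  deterministic rather than geometric.
* mmCIF is not parsed; PDB fixed-width only.
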