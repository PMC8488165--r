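# hydrosite

Prediction of explicit hydration sites — crystallographic water positions —
in protein structures, for structural biologists and computational chemists
who need water molecules in structures that lack them (unresolved shells,
NMR models, predicted structures) or who study water-mediated binding.

## Method

The core is a learned, differentiable score function

    Score(p | prot)  ≈  Norm(distance from p to the nearest missing water)

built from learnable atom- and bond-type embeddings.  Every atom `q` within
the 4.0 Å receptive field of a probe `p` contributes a distance term
(embedding of `q` + |q − p|) and one angle term per bonded neighbour `r`
(embeddings of `q`, `r`, the bond, and cos∠(qp, qr)).  All blocks are
PolyNN layers

    x1 = Swish(W0·x0 + b0),   x2 = exp(W1·log(1 + x1)) − 1,   x3 = W2·x2,

pooled by a permutation-invariant statistical reduction (sum ‖ mean ‖ max ‖
std → PolyNN).  Labels are squashed by `Norm(d) = 2/(1 + 2^(−5d)) − 1`,
steep near 0 and flat beyond 0.8 Å.  Training minimizes the weighted
squared error `Σ w_i (Score_i − Norm(label_i))² + λ|θ|²` over positives,
nearby/random negatives, and dynamically mined leave-one-out and
end-to-end hard negatives.

Waters are placed by gradient descent from a 0.8 Å grid: the best-scoring
optimized candidate is accepted, enters the environment (revealing
water-network sites), affected boxes are re-optimized, and the loop stops
at a score threshold; joint refinement with local resampling follows.
Predictions are evaluated against crystal waters by optimal one-to-one
matching at 0.5 / 1.0 / 1.5 Å cutoffs (precision / recall / F1).

The scorer's forward pass and its exact analytic backpropagation are
implemented in compiled code (`src/`); gradients are verified against
finite differences in the test suite.

## Worked example

Train on 50 synthetic fixtures (bonded mini-scaffolds whose waters follow a
deterministic hydrogen-bond-like rule), then predict the waters of a
held-out fixture from its dewatered structure:

```r
library(hydrosite)

train <- lapply(1:50, function(k) generate_structure(fixture_spec(seed = k)))
fit   <- train_scorer(train, training_config(seed = 1))

s    <- generate_structure(fixture_spec(seed = 101))     # held-out
pred <- place_waters(fit$params, strip_waters(s), placement_config())
pred$waters

evaluate_predictions(as.matrix(s$waters[, c("x", "y", "z")]),
                     as.matrix(pred$waters[, c("x", "y", "z")]))
```

The run above prints the four predicted waters with their scores —
predicted Norm-squashed distances, where 0 is a perfect water position and
values above the 0.5 threshold are never kept — and the match against the
four ground-truth sites:

```
          x         y         z     score iteration
1  9.252993 12.098729  8.296598 0.1038849         1
2 13.019016  3.416417  9.767311 0.4294598         2
3  9.366518 11.133910 11.895477 0.4410895         3
4  7.062991  2.052331  9.390919 0.4292306         4

  cutoff aggregation tp n_predicted n_crystal precision recall   f1
1    0.5      pooled  1           4         4      0.25   0.25 0.25
3    1.0      pooled  3           4         4      0.75   0.75 0.75
5    1.5      pooled  4           4         4      1.00   1.00 1.00
```

On this single structure one site lands between the 1.0 and 1.5 Å
cutoffs; over ten held-out fixtures the pipeline recovers the water rule
at recall and precision close to 1 at the 1.0 Å cutoff (see the
reproduction section below).  The same
functions run on real structures: `parse_pdb()` → `perceive_bonds()` →
`assign_types()` → `place_waters()`.

A command-line interface wraps the pipeline
(`inst/exec/hydrosite fixtures | train | place | evaluate`); every run
writes its resolved configuration next to its outputs.

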