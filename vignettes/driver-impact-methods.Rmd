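---
title: "Patient-specific driver scoring for prognosis prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-specific driver scoring for prognosis prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driverprog)
```

## The model

driverprog predicts binary cancer prognosis (good vs. bad, defined by
survival past a cancer-type-specific criterion year) from *patient-specific
cancer driver scores* rather than from expression directly. The chain for
one tumor sample is:

1. **Patient-specific network.** A shared directed gene network (a
   functional-interaction network plus regulatory networks, with every
   directed edge reversed so influence flows from a gene's targets back to
   the gene) is reweighted per patient as `W = A ⊗ Φ`. `A` is 1 on edges, 2
   on edges with a somatically mutated endpoint, 0 elsewhere. For an edge
   (i, j), `Φ_ij = (R_i + R_j) · min(R_i, R_j)`, where `R_g` is the absolute
   difference between the gene's expression rank in the tumor sample and the
   rank of its mean expression across normal samples (ascending midranks).
   The `min` factor rewards edges whose *both* endpoints are dysregulated:
   with R-values (6, 1) and (3, 4) the sums tie at 7 but the weights are 7
   and 21.
2. **Damped propagation.** Initial scores `f` (per-gene absolute expression
   difference from the normal mean) are spread over the column-normalised
   `W` by iterating `S ← (1 − d) f + d · W_norm S`, with per-gene damping
   `d = Asum / (Asum + 3)` driven by the gene's incoming-edge count. Genes
   with many in-edges rely on propagated evidence; isolated genes keep `f`.
3. **Penalty and win rate.** Genes without a somatic mutation in the
   patient are down-weighted by 0.85. Scores are then converted to win
   rates `V ∈ [0, 1]`: a mutated gene is compared against all other genes,
   a non-mutated gene against the patient's mutated genes only; ties count
   0.5.
4. **Selection and classification.** Genes are selected by Welch t-tests on
   *expression* between the good and bad training samples at a p-value
   threshold chosen from {0.1, 0.05, 0.01, 0.005} by stratified 5-fold
   cross-validated AUC; the classifier is then trained on the *win rates*
   of the selected genes: a feed-forward network with three ReLU hidden
   layers and a sigmoid output, binary cross-entropy, Adam at learning rate
   0.001, batch size 2, at most 200 epochs with early stopping once more
   than 20 epochs have seen a mean loss below 1e-4.
5. **Evaluation and prognostic genes.** The experiment repeats 10 random
   stratified 5:5 train/test splits; AUC, PR-AUC, balanced accuracy, F1 and
   Matthews correlation are reported per repeat. Genes ranking in the
   per-repeat top 30 by mean training-set win rate in at least 3 of the 10
   repeats form the prognostic gene set, summarised together with the edge
   density of their induced subgraph across patient networks.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `zero_fraction` | 0.8 | drop genes that are zero in more than 80% of pooled tumor+normal samples (a gene at exactly 80% is kept) |
| `penalty` | 0.85 | multiplicative down-weighting of non-mutated genes |
| damping offset | 3 | `d = Asum/(Asum+3)`; fixed by the model |
| `tol`, `max_iter` | 1e-6, 1000 | propagation stopping rule (max-abs change) |
| `grid` | 0.1, 0.05, 0.01, 0.005 | candidate selection thresholds |
| `cv_folds` | 5 | folds for threshold choice |
| `train_fraction` | 0.5 | stratified train share per repeat |
| `n_repeats` | 10 | repeated splits |
| `hidden` | p/2, p/4, p/8 floored at 64/32/16 | hidden widths; only the depth (3) is fixed by the protocol |
| `k`, `min_count` | 30, 3 | prognostic-gene rank cutoff and repeat count |

## Numerical and design choices

* **Rank ties** use midranks, which keeps `R` symmetric over tied blocks.
* **Column normalisation of W.** The propagation is applied to the
  column-stochastic `W_norm` (each source gene distributes unit influence
  over its out-edges). Without normalisation the iteration diverges for
  weights ≫ 1; with it, `ρ(diag(d) W_norm) < max(d) < 1`, so the iteration
  is a contraction with a unique fixed point
  `S = (I − diag(d) W_norm)^(−1) diag(1 − d) f` — the tests verify the
  power iteration against this direct solve to 1e-8.
* **Normalisation of f.** `f` is divided by its per-patient sum. The win
  rate is invariant to any increasing transform of the scores, so this
  changes nothing in the default feature path and only stabilises numerics.
  The `raw_score` and `score_no_winrate` ablations deliberately propagate
  `f` on the raw expression scale: feeding scores directly to the
  classifier is exactly what those ablations measure, and per-sample scale
  normalisation would change the method being ablated.
* **Censored samples.** Patients alive with follow-up shorter than the
  criterion year are excluded (their class is unknown); the literal
  died-before/not reading is available via `censored_policy = "good"`.
* **Welch t-test** rather than the pooled-variance form: prognosis groups
  are routinely unbalanced. No multiple-testing correction is applied —
  the threshold grid is calibrated by cross-validation instead. If the
  chosen threshold selects no gene on the full training half (possible on
  null data at 0.005), the single smallest-p gene is used so the classifier
  stays viable; folds where a threshold selects nothing score AUC 0.5.
* **Tie-break:** equal mean fold AUCs go to the smaller (stricter)
  threshold.
* **Hidden widths.** The protocol fixes depth (3), activations, learning
  rate, batch size and epochs, but not widths. Very narrow ReLU stacks die
  easily under small-batch Adam on few samples (we observed collapse to
  chance with ≤16-unit layers), so the default taper is floored at
  64/32/16 units.
* **Early stopping** counts low-loss epochs cumulatively
  (`early_stop_mode = "consecutive"` is available), on the mean per-epoch
  training loss. The optimiser is Adam, the standard choice at this
  learning-rate scale.
* **Determinism.** All classifier randomness (init, shuffling) flows from
  one integer seed through a dedicated generator; repeated runs are
  bit-identical, and ablation experiments sharing a seed use identical
  train/test splits (paired comparisons).
* **Isolated genes.** Genes present in expression data but absent from the
  network are kept as isolated nodes: degree 0, damping 0, score `f`. This
  keeps one consistent gene universe for the feature matrix.
* **Self-loops** are dropped at integration with a warning; they would
  distort both the damping counts and the propagation.

## What the synthetic generator emulates

`synthetic_spec()` defines a fully self-contained study: a sparse directed
network (1500 edges over 300 genes) with a densified module on 20 planted
driver genes; log-normal expression with per-gene baselines, floored at
0.5 so weakly expressed genes produce genuine zeros (exercising the
zero-expression filter); tumor samples shift the planted genes up by 0.3
log units (a shared tumor hallmark); bad-prognosis tumors add a 3-SD
(log-scale) shift on the planted genes; mutations are Bernoulli at 0.05
per gene with a 5-fold boost on planted genes (≈ 20 mutated genes per
patient, with drivers mutated in about a quarter of patients — the
scaled-down analogue of typical somatic mutation loads and driver
frequencies); and two real-data nuisances that motivate rank-based
scoring: a per-sample log-normal scale factor (SD 0.15, library size and
tumor purity) and sporadic heavy-tailed single-gene expression spikes
(probability 0.01, 7–50-fold). The default cohort is 30 good + 30 bad
tumors and 20 normals at seed 42; generation is a pure function of the
spec.

The choices interact deliberately with the model. A large shared tumor
shift would push planted genes to the top of *every* patient's ranking and
saturate the win rate identically in both prognosis groups; the moderate
default keeps the prognostic shift the dominant rank signal. The
scale-factor and spike nuisances barely move within-sample ranks but make
absolute expression differences incomparable across patients, which is why
the win-rate features outperform raw propagated scores here, mirroring the
motivation for the win-rate correction.

What the generator does **not** emulate: correlated co-expression modules
beyond the planted one, realistic marginal count distributions (it is not
a negative-binomial RNA-seq simulator), driver heterogeneity within the
bad-prognosis group, copy-number or methylation effects, and batch
structure. Passing the planted-recovery and ablation checks therefore
demonstrates internal correctness and the intended qualitative behaviour
of the method, not performance on real tumors.

## Problem sizes used in the checks

The shipped checks run the full pipeline on the 300-gene demo cohorts
(10 repeats each for the signal cohort, the null cohort with
`group_effect = 0`, and the unweighted-network and raw-score ablations),
verify the propagation against dense linear solves on 25 random networks
of 50–200 genes, and verify win rates against exhaustive pairwise
comparison on 100 random configurations of up to 50 genes. These sizes
were chosen so the entire suite exercises every stage end to end in a few
minutes on a laptop.

## Known limitations

* The integrated-network dedup rule across resources keeps both
  orientations of an undirected edge and collapses exact duplicates only;
  resources disagreeing on directedness therefore contribute both forms.
* Gene symbols are matched case-sensitively; no alias resolution.
* The edge-density statistic (nonzero patient-network edges within the
  induced subgraph per subset gene, averaged over patients) is one
  reasonable reading of "average edge density"; its absolute scale is not
  comparable across differently sized networks.
* `f` uses the absolute expression difference by default
  (`initial_score_mode = "rank"` switches to the rank difference); on
  unnormalised expression the two can rank genes differently.
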