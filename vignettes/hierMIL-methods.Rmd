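---
title: "Hierarchical attention MIL for patient phenotype prediction: models and methods"
author: "hierMIL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical attention MIL: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierMIL)
```

## The problem

Single-cell RNA-sequencing resolves a patient sample into hundreds to tens of
thousands of cells, but clinical labels — disease status, treatment response —
attach to the *sample*, not to individual cells. This is a multiple instance
learning (MIL) problem: each sample is a *bag* of cell-level *instances*, and
only bag labels are observed. Attention-based MIL predicts the bag label from
a weighted sum of instance representations, with softmax-normalized weights
that double as per-cell relevance scores.

Flat attention over cells, however, ignores a structure every single-cell
analyst starts from: cells come annotated with types, and cells of a type are
far more alike than cells across types. hierMIL builds this grouping into the
pooling path. Aggregation happens in two steps — cells within a type are
pooled into a type representation, and type representations are pooled into
the sample representation — so the model can learn which *cell types* matter
for the phenotype, and its predictions decompose exactly into per-type
contributions.

## Model

For a sample with cells $x_{ij} \in \mathbb{R}^m$ (cell $j$ of type $i$,
$n_i$ cells of type $i$, $N = \sum_i n_i$), a feed-forward encoder with one
or two hidden layers maps each cell to $h_{ij} = \varphi(W_x x_{ij} + b_x)
\in \mathbb{R}^d$, $\varphi$ = ReLU by default.

Two aggregation strategies are provided:

* **CTA (cell-type attention).** Cells are mean-pooled within their type,
  $h_i = \frac{1}{n_i} \sum_j h_{ij}$, and attention acts on types only.
* **HA (hierarchical attention).** Attention acts within each type:
  $e_{ij} = w^\top h_{ij} + b$, $\alpha_{ij} = \mathrm{softmax}_j(e_{ij})$
  within type $i$, and $h_i = \sum_j \alpha_{ij} h_{ij}$.

In both, a second attention level weighs the present types:
$e_i = v^\top h_i + b'$, $\beta_i = \mathrm{softmax}_i(e_i)$, and the sample
representation is

$$h \;=\; \sum_i \beta_i h_i \;=\; \sum_{i,j} \gamma_{ij} h_{ij},
\qquad \gamma_{ij} = \beta_i \alpha_{ij},$$

so the combined cell weights are automatically normalized:
$\sum_{ij}\gamma_{ij} = \sum_i \beta_i \sum_j \alpha_{ij} = 1$. A linear
head maps $h$ to class probabilities — a sigmoid on
$\bar w^\top h + \bar b$ for binary tasks, a softmax on $W h + b$ otherwise —
and training minimizes the cross-entropy over samples.

Two ablation architectures isolate the value of the type hierarchy:
**meanPool** averages all $N$ cell representations (a pseudo-bulk profile),
and **cellAtt** applies one flat softmax attention over all cells, ignoring
types. Useful identities, all enforced by tests: HA with $w = 0$ equals CTA;
cellAtt with $w = 0$ equals meanPool; and cellAtt equals HA on a bag with a
single cell type.

### Assumptions

The model assumes cell-type annotations are given (from any annotation tool
or manual curation) and treats them as part of the input; noisy annotations
degrade performance (see the robustness experiments). Absent cell types are
expected and handled: a type with zero cells in a bag has no representation
and is excluded from the type softmax — it is never imputed and receives
exactly zero attention. Features are assumed to be roughly continuous
(log-normalized expression or embeddings); raw counts should first pass
through `preprocessCounts()` (scale each cell to a total of $10^4$, then
`log1p`, optionally dropping genes seen in fewer than 5 cells).

## Interpretability

Because pooling and the head are linear, the pre-activation logit
decomposes exactly (binary case shown; the multi-class case replaces
$\bar w^\top$ by the head matrix):

$$z = \bar w^\top h = \sum_{i,j} \gamma_{ij}\, \bar w^\top h_{ij}
    = \sum_i \beta_i\, \bar w^\top h_i,$$

giving per-cell and per-type contributions that sum to the forward-pass
logit (minus the bias) — `decompose()` returns both and the package asserts
the identity to 1e-5 on random models. The **importance score** of type $i$
contrasts its mean contribution across classes:

$$\kappa_i = \frac{1}{|S_1|} \sum_{s \in S_1} \ell_{si}
           - \frac{1}{|S_0|} \sum_{s \in S_0} \ell_{si},
\qquad \ell_{si} = \beta_{si}\, \bar w^\top h_{si}.$$

When sample $s$ lacks type $i$ we take $\ell_{si} = 0$ while keeping the
full class sizes in the denominators; this is the only convention under
which $\sum_i \ell_{si}$ still reproduces the sample logit, and it treats
"type absent" as "type contributed nothing", which is what the forward pass
actually computes.

### Permutation test

`permutationTest()` decides which $\kappa_i$ are significant by refitting
the model on label-permuted cohorts from fresh seeded initializations and
using the null draws to compute empirical p-values. Design choices, each
genuinely open:

* **Two-sided by default** (`sided = "two.sided"`, on $|\kappa|$): a type
  can drive either class; a one-sided variant is a flag away.
* **Add-one estimator**: $p_i = (1 + \#\{|\kappa^{perm}_i| \ge
  |\kappa^{obs}_i|\}) / (n_{perm} + 1)$, so p-values are never zero and are
  exactly uniform on $\{1/(n+1), \dots, 1\}$ under exchangeability.
* **Benjamini–Hochberg** correction by default ($I$ tests, one per type);
  Holm and Bonferroni are selectable.
* **Fixed hyperparameters across permutations**: refits reuse the
  architecture and optimizer settings of the observed fit rather than
  re-tuning per permutation. Re-tuning inside every permutation would
  multiply cost by the grid size for a null that is rarely sharper; the
  fixed-hyperparameter null is the common approximation and is stated in
  the report metadata.
* **Default $n_{perm} = 99$**, the smallest round count whose add-one
  p-values resolve 0.01; increase it when $\alpha/I$ is small.

For $C > 2$ classes the package provides a one-vs-rest generalization
(`importanceScoresMulticlass()`): the target class's logit component is
contrasted between that class and all others. This construction is the
package's own (reported as such in the output metadata); with $C = 2$ and
the positive class as target it reduces exactly to $\kappa_i$ above.

## Training and evaluation

Optimization is mini-batch Adam (rate 1e-3 by default, batch of 8 samples,
optional L2 weight decay on weight matrices) on the cross-entropy loss;
any gradient-descent variant fits the objective, and Adam is the standard
choice for small attention networks. Attention vectors $w, v$
initialize at small scale so early training is near mean pooling — the
least-committal start; encoder and head weights use fan-in scaling. Bags
are processed as ragged per-sample units, never padded, so no mask can leak
into a softmax. All randomness (initialization, batch shuffling, folds,
permutations, simulation) flows from explicit integer seeds; every fit is
bit-reproducible.

`nestedCV()` implements repeated nested cross-validation: stratified outer
folds estimate generalization; within each outer-training split, every
hyperparameter grid point is scored by the AUC of its stacked inner-fold
predictions, the best point is refit on the full outer-training split, and
metrics (AUC, F1, accuracy, precision, recall) are computed once per repeat
on the stacked out-of-fold predictions. Conventions chosen where the
protocol is silent: folds are stratified by class (cohorts of 40–60 samples
otherwise produce degenerate folds); the inner loop uses 5 folds (10-fold
inner CV at these sizes leaves 3-sample inner test sets); binary
F1/precision/recall refer to the positive class at a 0.5 threshold while
multi-class metrics are macro-averaged with one-vs-rest AUC; a grid point
that fails to train scores AUC 0.5 and is logged. The default grid crosses
hidden width {32, 64}, depth {1, 2}, learning rate {1e-3, 1e-4} and weight
decay {0, 1e-4}, and is entirely caller-configurable.

Three robustness experiments mirror common data-quality failure modes:
shrinking the training set (`experimentTrainSize()`), subsampling cells per
bag (`experimentCellSubsample()`), and randomizing a fraction of cell-type
annotations (`experimentAnnotationNoise()`). Noise injection and CV
splitting consume separate derived seed streams, so the zero-noise arm of
the annotation experiment reproduces the baseline CV bitwise under a shared
master seed — a contract the tests assert.

## Synthetic cohorts

`simulateCohort()` generates the data the models assume: per-sample cell
counts uniform on a range, type proportions from a Dirichlet with optional
whole-type dropout (absent types), multinomial cell assignment, and
Gaussian features around per-type mean profiles. Class signal enters
through two independently switchable channels — an expression shift on
driver-type cells of positive samples, and a composition tilt of the driver
types' proportions — so interpretability attribution can be studied under
each. Defaults, chosen once as a realistic desk-scale study: 30 + 30
samples, 5 types at ~20% expected abundance (concentration 5), 50 features,
50–100 cells per sample, unit within-type noise, dropout 0.05, one driver
type with a shift of 2 applied to the 10 leading features (a minority of
the feature space, as differential signatures usually are).

Three named scenarios recur in the tests and the acceptance script:

* **Reference signal cohort** (the defaults, shift 2): strong, learnable
  signal; nested-CV AUC should exceed 0.9 and the driver type should be
  recovered as critical.
* **Null cohort** (shift 0): labels independent of data; CV AUC should sit
  near 0.5 and permutation p-values should be uniform.
* **Hierarchical-signal cohort** (shift 0.5): per-cell signal is weak
  (half the within-type standard deviation) but averaging the ~15 driver
  cells per bag makes the type-level signal strong. This is the regime the
  hierarchy exists for: type-aware pooling (CTA, HA) denoises before
  attending, while flat cell attention must find weak individual cells, so
  CTA and HA should dominate cellAtt here.

`simulateRareDriver()` concentrates the shift in a fraction (default 10%,
shift 4) of driver-type cells, emulating phenotypes carried by a small
subpopulation — the regime where HA's within-type attention has room to beat
CTA's mean pooling. The comparison is exploratory; the generator makes no
claim about how often that advantage materializes at desk scale.

What the generator does **not** emulate: library-size variation, batch and
donor effects, count overdispersion (beyond the optional negative-binomial
count mode used for I/O testing), doublets, or hierarchically related cell
types. Passing tests on these cohorts therefore demonstrate correctness of
the machinery and sane statistical behaviour under the stated model — not
performance on any real dataset.

## Numerical choices

* Softmaxes subtract the maximum logit before exponentiation; shift
  invariance is a tested property (1e-7).
* The biases $b$ (cell attention) and $b'$ (type attention) cancel inside
  their softmaxes and are unidentifiable; they are retained for fidelity to
  the model definition but excluded from equivalence tests.
* Probabilities are clamped at 1e-12 before logs; ReLU uses the
  left-continuous derivative (0 at 0).
* A bag with a single present type gets $\beta = 1$ exactly; a type with
  one cell gets $\alpha = 1$ exactly (its attention logit is inert — no
  special handling).
* Ties in hyperparameter selection resolve to the first grid row; ties in
  `rankCellTypes()` resolve alphabetically.
* Training aborts with diagnostics on a non-finite loss; inside
  `permutationTest()` such a fit is retried once with a fresh seed, and
  inside `nestedCV()` the grid point is scored 0.5.

## Problem sizes in the test suite

The acceptance-level checks run at sizes chosen to make their statistical
claims sharp yet quick on one CPU: identity checks use 25–100 random
models on bags of up to 10 cells; permutation-null calibration uses 50
cohorts of 20 samples (99 permutations each, 250 p-values total, binomial
95% band around 0.05); driver recovery uses 20 runs of the reference
cohort; CV power, ablation ordering and annotation-noise checks use 5 (or
3) repeats of 10-fold nested CV with a 1–2-point grid and a 30-epoch
budget. These sizes are the package's own simulation design and are stated
here so they can be scaled up deliberately.

## Limitations

The models require cell-type annotations and currently error on cell types
unseen at training time; generalization to novel types is out of scope.
There is no cell-cell interaction modeling (no transformer-style
self-attention), no mixed-model robustness layer, no prototype learning,
and no prior-knowledge modulation of attention weights. Gene-level
attributions and enrichment analyses on critical types are deliberately not
provided — the package reports scores and criticality calls only. H5AD
files are not read directly; cohorts arrive via the CSV/MTX directory
layout or an in-memory `SingleCellExperiment` (`cohortFromSCE()`).
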