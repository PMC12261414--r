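# hierMIL

Hierarchical attention multiple instance learning (MIL) for predicting
patient-level phenotype labels from annotated single-cell expression data —
with exact, cell-type-level interpretability.

## The problem

In single-cell studies the clinical label (disease status, treatment
response) belongs to the *sample*, while the data are thousands of per-cell
expression profiles or embeddings. hierMIL treats each sample as a MIL bag
of cells and predicts its label, but unlike flat attention-MIL it uses the
cell-type annotations that every single-cell workflow already produces:
aggregation happens hierarchically, first over cells within a type, then
over types.

For a sample with cells $x_{ij}$ (cell $j$ of type $i$), an encoder gives
$h_{ij} = \varphi(W_x x_{ij} + b_x)$; within-type attention (HA model) or
mean pooling (CTA model) gives type representations $h_i$; type-level
attention $\beta_i = \mathrm{softmax}_i(v^\top h_i + b')$ gives the sample
representation

$$h = \sum_i \beta_i h_i = \sum_{i,j} \gamma_{ij} h_{ij},
\qquad \gamma_{ij} = \beta_i \alpha_{ij},$$

followed by a linear sigmoid/softmax head. Because pooling and head are
linear, the prediction logit decomposes **exactly** into per-cell and
per-type contributions $\ell_{si} = \beta_{si}\bar w^\top h_{si}$. The
**importance score** of cell type $i$,

$$\kappa_i = \tfrac{1}{|S_1|}\textstyle\sum_{s \in S_1} \ell_{si}
           - \tfrac{1}{|S_0|}\sum_{s \in S_0} \ell_{si},$$

contrasts its mean contribution between positive and negative samples, and
a label-permutation test (model refit per permutation, add-one empirical
p-values, Benjamini–Hochberg correction) calls the *critical* cell types.
Mean-pooling and flat cell-attention ablations, repeated nested 10-fold
cross-validation with inner-loop hyperparameter selection, data-quality
robustness experiments, and a seeded synthetic-cohort generator round out
the package.

## Worked example

```r
library(hierMIL)

co <- simulateCohort(seed = 7)   # 30+30 samples, 5 types, driver = type1
co
#> MILCohort: 60 samples, 5 cell types, 50 features
#>   classes: class1 (30), class2 (30)
#>   cells per sample: 52 - 99 (median 73)

mod <- fitMIL(co, mode = "HA", hiddenDim = 16,
              config = trainConfig(nEpochs = 30, batchSize = 8, seed = 1),
              seed = 1)
round(evaluateMetrics(predictProba(mod, co), sampleLabels(co)), 3)
#>       auc        f1  accuracy precision    recall
#>         1         1         1         1         1

tr <- milTrainer(mode = "HA", hiddenDim = 16,
                 config = trainConfig(nEpochs = 30, batchSize = 8))
permutationTest(co, tr, nPerm = 99, seed = 2)
#> ImportanceReport: 5 cell types, 99 permutations, two.sided p-values, BH correction, alpha = 0.05
#>   critical: 1 of 5
#>   cellType      kappa pRaw      pAdj critical
#> 1    type1 7.75770160 0.01 0.0500000     TRUE
#> 2    type4 0.07072087 0.24 0.6000000    FALSE
#> 3    type5 0.05947308 0.37 0.6166667    FALSE
#> 4    type2 0.01862508 0.89 0.9800000    FALSE
#> 5    type3 0.01004395 0.98 0.9800000    FALSE
```

The generator planted the class signal in `type1`; the fitted model
separates the classes (in-sample AUC 1 here — use `nestedCV()` for honest
out-of-fold estimates), and the permutation test singles out `type1` as the
only critical type: its importance score 7.76 dwarfs the others and no
label permutation produced a larger one (p = 1/100, BH-adjusted 0.05).

Real data enter via `loadCohort()` (CSV/MTX directory: `matrix.mtx`,
`cells.tsv`, `samples.tsv`) or `cohortFromSCE()` from a
`SingleCellExperiment`; raw counts can be normalized with
`preprocessCounts()`. A thin command-line wrapper with `simulate`, `cv`,
`experiment`, `permtest` and `explain` subcommands lives at
`inst/scripts/hiermil-cli.R`.

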