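# milstage

Weakly supervised lymph-node metastasis staging from rectal MRI, in R.

## The problem

Preoperative N staging of rectal cancer requires judging, node by node,
which MRI-visible pelvic lymph nodes are metastatic — but retrospective
series have no node-level ground truth, because nodes resected at surgery
cannot be matched one-to-one with nodes seen at imaging. The pathology
report does give two patient-level quantities: the binary metastasis
status $y$ and the metastatic proportion $\rho = k/m$ (k metastatic among
m resected nodes).

`milstage` trains node-level classifiers from exactly that weak
supervision. Each patient is a *bag* of node patches; a small residual
convolutional network scores every node with a metastatic probability
$p_i$, and the bag is coupled to the patient labels through two pooled
heads:

$$L = \lambda_{\mathrm{mil}}\,\mathrm{BCE}(\max_i p_i,\; y)
    + \lambda_{\mathrm{llp}}\,\mathrm{BCE}(\tfrac1n\textstyle\sum_i p_i,\; \rho)$$

— a multiple-instance learning (MIL) term on the max-pooled probability
and a learning-from-label-proportions (LLP) term on the average-pooled
probability. Three variants fuse successively richer per-node features:
`M_I` (patch intensity only), `M_IS` (+ long/short axis diameters and
their ratio), `M_ISA` (+ mean apparent diffusion coefficient). Predicted
metastatic counts (nodes with $p_i \ge \tau$, threshold fitted on
training bags) yield the ternary N stage (N0: 0, N1: 1–3, N2: ≥ 4).

The package is aimed at methodologists who want a fully testable,
self-contained implementation of this weak-supervision recipe: it ships a
synthetic cohort generator with matched population statistics (≈14 ± 5
nodes/patient, 39% patient positivity, heavy-tailed metastatic counts),
per-node morphometry, Grad-CAM heatmaps with intranodal/perinodal hotspot
classification, and a complete staging evaluation suite (bootstrap AUC,
DeLong comparison, count MAE, ordinal concordance index, kappa/F1,
calibration and decision curves). No external data are needed.

## Worked example

```r
library(milstage)

train <- simulateCohort(cohortParams(nPatients = 120, textureEffect = 1.2,
                                     seed = 11))
test  <- simulateCohort(cohortParams(nPatients = 60, textureEffect = 1.2,
                                     seed = 22))
train
#> LNCohort: 120 patients ( 42 LN-positive ), 1685 visible nodes

model <- trainIntensityModel(train, modelConfig(seed = 1, epochs = 16L))
model
#> NodeModel variant M_I ; tau = 0.2264
#>   trained 16 epochs; final val loss 0.84

pred <- predictCohort(model, test)
report <- evaluateStaging(pred, nBoot = 500, seed = 1)
report
#> Staging evaluation
#>   binary AUC 0.859 (95% CI 0.734-0.941); sens 0.632 spec 0.854
#>   count MAE 1.483 (0.825-2.159); ternary C index 0.764 (0.642-0.879)
#>   kappa 0.346; macro F1 0.505; accuracy 0.683
```

The binary AUC ranks patients by their most suspicious node; the count
MAE says the predicted number of metastatic nodes is off by about one and
a half nodes on average at this moderate texture signal; the C index is
the probability that two patients with different true N stages are
ordered correctly by the predicted count. Per-node explanations locate
what drove a positive call:

```r
b  <- bags(test)[[which(pred$k_hat > 0)[1]]]
pr <- predictPatient(model, b)
explainNode(model, nodes(b)[[which.max(pr$probs)]])
#> NodeHeatmap 32x32 ; hotspot: intranodal
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/milstage` (subcommands `simulate`, `extract`, `train`,
`predict`, `explain`, `evaluate`).

See `vignettes/weak-node-staging.Rmd` for the model, the simulator's
assumptions, and the reasoning behind the numerical design choices.

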