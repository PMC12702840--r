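# mafldcl

Two-stage contrastive learning for predicting metabolic
dysfunction–associated fatty liver disease (MAFLD) phenotypes from
multi-source tabular patient data.

## The problem

MAFLD subtypes carry different prognoses: the diabetic phenotype has the
highest mortality risk, while the obese and lean phenotypes are both
BMI-defined and are merged here into a single *nondiabetic MAFLD* class.
Given demographics `D`, clinical measurements `C`, and two incomplete
self-reported survey views — lifestyle `S_lif` and genetic family history
`S_gen` — the task is to predict the 3-class outcome
`Y ∈ {non-MAFLD, nondiabetic MAFLD, diabetic MAFLD}` under heavy class
imbalance (≈ 85% / 11.5% / 3.5%). The package is aimed at biostatisticians
and ML-for-health researchers who need a tested reference implementation
of this architecture plus an evaluation harness for imbalanced multiclass
risk prediction.

## The method

Three components, composed end to end:

1. **Person–feature bipartite graphs** per survey view: person nodes vs
   coded-value nodes `F_ij` (feature *i*, level *j*); an observed value is
   an edge, a missing cell is simply no edge. A 2-layer mean-aggregation
   neighbourhood encoder is trained with the triplet margin loss

   `L = max(0, d(f(a), f(p)) − d(f(a), f(n)) + α)`

   (anchor *a*, positive *p* = a neighbour or the node itself if
   isolated, negative *n* = a non-neighbour, Euclidean *d*), giving
   per-person embeddings `A^Lif`, `A^Gen` from raw, non-imputed surveys.

2. **Multiview contrastive pretraining**: a clinical autoencoder
   bottleneck `z_b` is the frozen teacher; two 3-layer MLP learners map
   the graph embeddings to `z_a`, `z_c` and minimise the one-directional
   InfoNCE loss

   `L(z_x, z_b) = −log [ exp(sim(z_x(i), z_b(i))/τ) / Σ_k exp(sim(z_x(i), z_b(k))/τ) ]`

   with cosine `sim` and a *batch-adaptive* temperature
   `τ = softplus(W · ReLU(mean(z_b))) + τ_min` produced by a small
   temperature network trained jointly.

3. **Two-stage risk estimation**: stage 1 estimates `p = P(any MAFLD)`,
   stage 2 a phenotype distribution `(q₁, q₂)`; the composed 3-class
   distribution is `(1 − p, p·q₁, p·q₂)`. Training minimises a
   class-weighted sum: NLL of the composed distribution
   + γ · binary CE (stage 1) + λ · phenotype CE on true-MAFLD rows
   (stage 2).

A synthetic cohort generator plants the structure the method assumes
(latent metabolic/behavioural factors, intraphenotype subclusters,
cross-view coupling `ρ`, survey-only missingness including whole-view
nonresponse), so every stage is testable without any external data. The
evaluation harness provides repeated stratified splits, stratified k-fold
CV, macro precision/recall/F1, one-vs-rest AUC, a four-mode ablation
(MLP / Graph / Graph+CL / Full) on paired splits, and paired t-tests.

## Worked example

```r
library(mafldcl)

sim <- generate_cohort(synthetic_config(n = 1000, rho = 0.8, seed = 7))
print(sim$table)
#> <cohort_table> n=1000, 112 features, missing 31.73% of cells
#>
#>         non_MAFLD nondiabetic_MAFLD    diabetic_MAFLD
#>               854               107                39

cfg   <- pipeline_config()
split <- trial_split(1000, seed = 1, f = 0.8, y = sim$table$y)
feats <- prepare_trial(sim$table, split, cfg, seed = 1000)
labels <- as.integer(sim$table$y) - 1L
fit   <- classify_mode(feats, "Full", labels, split, cfg, seed = 1000)

auc <- ovr_auc(labels[split$test], fit$scores)
round(auc$per_class, 3)
#> [1] 0.732 0.658 0.947
round(auc$macro, 3)
#> [1] 0.779

threshold_report(fit$p, labels[split$test] > 0, c(0.3, 0.5, 0.6, 0.7))
#>   threshold flagged precision    recall
#> 1       0.3      65 0.3076923 0.6896552
#> 2       0.5      40 0.3750000 0.5172414
#> 3       0.6      27 0.3703704 0.3448276
#> 4       0.7      20 0.4500000 0.3103448
```

The per-class AUCs say the model ranks diabetic MAFLD almost perfectly
(0.947 — the definitive clinical markers do their job), non-MAFLD well
(0.732), and nondiabetic MAFLD hardest (0.658), the familiar pattern for
the minority class that lacks definitive markers. The threshold sweep
shows the stage-1 precision/recall trade-off a clinician would navigate:
raising the flagging threshold from 0.3 to 0.7 cuts the flagged count
from 65 to 20, raises precision from 0.31 to 0.45 and drops recall from
0.69 to 0.31.

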