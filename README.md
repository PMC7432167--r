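# reactAD

Applicability domains for quantitative reaction–property models.

## The problem

Regression models that predict numeric characteristics of chemical reactions —
rate constants, equilibrium constants — are only reliable near their training
data. An **applicability domain** (AD) definition turns that intuition into a
binary decision per reaction: *X-inlier* (within AD, trust the prediction) or
*X-outlier* (outside AD). Reactions make this harder than ordinary QSAR:
conditions (solvent, temperature, mixture composition) co-determine the
property, and a model trained on one reaction type cannot be expected to
transfer to another.

`reactAD` is for computational chemists who build such models and need to
decide which predictions to trust. It provides:

* **Reaction representation** — atom-mapped reaction SMILES parsed into a
  Condensed Graph of Reaction (CGR): one graph whose atoms and bonds carry
  `before>>after` attributes, with *dynamic* bonds/atoms marking the change.
  Reaction centres are connected components of the dynamic subgraph; each
  centre plus its radius-*R* neighbourhood is encoded as a canonical
  **signature** string whose equality defines "same reaction type".
* **Descriptors** — ISIDA-style counts of 2–4-atom linear CGR fragments,
  concatenated with 15 solvent descriptors, 1/T and the organic-solvent molar
  ratio, standardized to zero mean and unit variance.
* **Eleven AD definitions** behind one `ad_fit()`/`predict()` contract:
  leverage (h = xᵀ(XᵀX)⁻x, default threshold h\* = 3(M+1)/N), nearest-neighbour
  distance (Dc = Zσ + ⟨y⟩), one-class SVM, a two-class Y-inlier/Y-outlier
  classifier (2CC), bounding box, fragment control (FC), reaction type control
  (RTC), random-forest ensemble variance (RFR_VAR), Gaussian-process
  predictive variance (GPR-AD), and the zero/perfect baselines.
* **Four metrics** — coverage; OIR = RMSE_out − RMSE_in; ΔR²_AD = R²_in −
  R²_all; OD = (TO/(TO+FI) + TI/(TI+FO))/2, the balanced accuracy of Y-outlier
  detection (a *Y-outlier* is a reaction whose absolute prediction error
  exceeds 3·RMSE); plus AUC_AD as a diagnostic.
* **A nested-CV benchmark** that tunes QRPR and AD hyperparameters in the
  inner loop (objectives OIR or OD), evaluates on merged outer folds, forms
  composites with RTC1 (written `BB*`, `2CC*`, …), and ranks methods by a
  top-50% penalty scheme.
* **A seeded synthetic reaction generator** (`builtin_suites()`) with distinct
  reaction types, condition-dependent linear property models, planted gross
  Y-outliers, a zwitterion-tautomer suite whose CGRs have charge changes but
  no dynamic bonds (the designed blind spot of fragment control), and a
  novel-leaving-group suite for external-validation scenarios.

## Worked example

Benchmark AD definitions on a synthetic substitution dataset of 150 reactions
(5% planted gross outliers), nested 5×5 cross-validation:

```r
library(reactAD)
suites <- builtin_suites()
train  <- generate_reactions(suites$substitution, n = 150, seed = 1)

cfg <- ad_config(outer = 5, inner = 5, ntree = 300,
                 max_features_grid = c(0.3, 1.0),
                 nu_grid = c(0.05, 0.2), gamma_grid = 10^c(-3, -1),
                 alpha_grid = c(0.01, 0.1))
bm <- run_benchmark(train,
                    methods = c("BB", "FC", "RTC1", "RFR_VAR", "2CC",
                                "OZ", "PZ", "Perfect"),
                    objectives = "OIR", config = cfg, seed = 7)
bm
#> <ad_benchmark> 150 reactions, 5x5 nested CV, seed 7
#>         model coverage  oir delta_r2_ad   od auc_ad
#>      2CC*/OIR     0.91 0.14        0.02 0.45   0.80
#>       2CC/OIR     0.91 0.14        0.02 0.45   0.80
#>            BB     0.97 0.80       -0.01 0.49   0.92
#>           BB*     0.97 0.80       -0.01 0.49   0.92
#>            FC     1.00 0.00        0.00 0.50     NA
#>           FC*     1.00 0.00        0.00 0.50     NA
#>            OZ     1.00 0.00        0.00 0.50     NA
#>       Perfect     0.96 4.45        0.15 1.00   1.00
#>            PZ     0.00 0.00       -0.68 0.50     NA
#>  RFR_VAR*/OIR     0.83 1.44        0.01 0.59   0.91
#>   RFR_VAR/OIR     0.83 1.44        0.01 0.59   0.91
#>          RTC1     1.00 0.00        0.00 0.50     NA
```

Reading the table: the optimistic zero model (`OZ`, everything inside AD) has
coverage 1 and, by definition, OIR = ΔR²_AD = 0 and OD = 0.5; the pessimistic
zero model (`PZ`) has coverage 0 and ΔR²_AD = −R²_all. The Perfect baseline
(X-inlier ⇔ Y-inlier) has OD = 1 by construction and the largest OIR: its
excluded reactions are exactly the gross errors. Among real methods,
`RFR_VAR*/OIR` (per-tree variance threshold tuned by OIR, ANDed with RTC1)
keeps 83% of reactions while the reactions it rejects are predicted 1.44
property units worse (RMSE) than those it keeps — it isolates the planted
outliers. On a training suite of a single reaction type RTC1 accepts
everything; its value shows on foreign types:

```r
foreign <- generate_reactions(suites$elimination, n = 60, seed = 1)
detect_nonnative(train, foreign, "rtc")
#> [1] 1
```

— 100% of the elimination-type reactions are excluded from the AD of the
substitution-trained model.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/reaction-ad simulate  --suite substitution --n 100 --seed 1 --out data.csv
Rscript inst/cli/reaction-ad signatures --data data.csv --radius 1
Rscript inst/cli/reaction-ad benchmark  --data data.csv --seed 1 --out results/
```

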