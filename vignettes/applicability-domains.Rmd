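---
title: "Applicability domains for reaction-property models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Applicability domains for reaction-property models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reactAD)
```

## The problem

A quantitative reaction–property relationship (QRPR) model predicts a numeric
characteristic of a chemical reaction — typically a rate or equilibrium
constant — from the structures of reactants and products and from the
experimental conditions (solvent, temperature, mixture composition). Like any
empirical model, a QRPR model is only trustworthy near its training data. An
*applicability domain* (AD) definition operationalizes "near": it is a binary
classifier that marks each test reaction as an X-inlier (within AD, prediction
trusted) or X-outlier (outside AD). The quality of an AD definition is judged
by four abilities: rejecting reactions of a *type* absent from the training
set, improving prediction quality inside the domain, detecting *Y-outliers*
(reactions whose absolute prediction error exceeds three times the RMSE), and
keeping coverage — the fraction of reactions retained — as high as possible.

Reactions are harder objects than molecules: the same pair of molecules can
react at different centres, conditions modulate the property by orders of
magnitude, and a model trained on one reaction type (its *native* type) has no
business predicting another. The package therefore works on the Condensed
Graph of Reaction and treats reaction-type membership as a first-class AD
signal.

## Reaction representation

**Condensed Graph of Reaction (CGR).** An atom-mapped reaction is superposed
into a single graph: each atom (keyed by its map number) carries its formal
charge, heavy-neighbour count and hybridization *before and after* the
transformation; each bond carries its order before and after, `none` standing
for a bond present on one side only. A bond whose two orders differ is
*dynamic*; an atom is *dynamic* if any of its three attributes changes or if
it touches a dynamic bond. Atom maps are taken as given — the package never
invents an atom-to-atom mapping, it raises an error instead, and aromaticity
is read from the input SMILES notation (with a ring-validity check) rather
than re-perceived. Hydrogens are implicit throughout; neighbour counts are
heavy-atom counts. Hybridization is assigned per side as `aromatic` for atoms
in aromatic notation, `sp` for atoms with a triple bond or two double bonds,
`sp2` for one double bond and `sp3` otherwise; the dedicated aromatic label
lets a signature distinguish an aromatic ring at the reaction centre from an
aliphatic environment.

Because charge changes count as dynamic even without any bond-order change,
zwitterion-type tautomerism — where a proton moves between heteroatoms and
only formal charges change — still produces a nonempty reaction centre. This
is deliberate: it is exactly the case where fragment-based control fails (see
below), so type-based control must catch it.

**Reaction centres and signatures.** A reaction centre is a connected
component of the dynamic subgraph. The centre plus all atoms within graph
distance *R* is serialized into a canonical string: atom tokens carry element,
neighbour counts, hybridizations and charges (all as `before>>after` pairs),
bond tokens carry `order_before>>order_after`. Canonical numbering uses
iterative extended-connectivity refinement seeded with the atom labels;
remaining ties are resolved by individualization branching, taking the
lexicographically smallest serialization, so two isomorphic labelled
neighbourhoods always give byte-identical strings. The serialized form is a
rank-ordered atom list plus a sorted edge list rather than a SMILES-like
depth-first string: only string *equality* is ever consumed, so any
deterministic injective canonical form is equivalent, and the flat form is
simpler to reason about and to test against a brute-force isomorphism oracle.

**Fragment descriptors.** Structural descriptors are counts of linear paths
of 2–4 atoms on the CGR (a path and its reverse are one occurrence; the
canonical key is the lexicographic minimum of the two serializations). Atom
tokens in *fragments* are bare element symbols and bond tokens are
`before>>after` order pairs — deliberately poorer than the signature grammar.
Fragments thus see dynamic *bonds* but not charge or hybridization changes.
This reproduces the behaviour of sequence-fragment descriptors on CGRs: a
zwitterion-type tautomerization, having no dynamic bonds, generates only
ordinary static fragments, and fragment control will accept such a reaction
whenever its static fragments are covered by the training set — the
documented failure mode that motivates reaction type control.

**Condition descriptors.** Each reaction carries 17 condition values: 15
solvent descriptors (Catalan SPP/SA/SB, Kamlet–Taft alpha/beta/pi*, four
dielectric-constant functions, three refractive-index functions, and two
user-definable slots, zero by default, reserved because published solvent
schemes of this kind list 15 slots while naming 13), the inverse absolute
temperature 1/T in K⁻¹, and the organic-solvent molar ratio in percent (100
for a pure solvent). The dielectric functions are the standard
Kirkwood/Onsager-type forms ε, (ε−1)/(2ε+1), (ε−1)/(ε+2), (ε−1)/(ε+1) and the
refractive functions n², (n²−1)/(n²+2), (n²−1)/(2n²+1); no result in the
package depends on this specific choice. A bundled table covers 14 common
solvents with typical literature values of the empirical scales and is
user-extensible.

All descriptor columns are standardized to zero mean and unit variance on the
training block (population standard deviation, so the training block is
exactly centred and scaled); constant columns map to zero. For
Gaussian-process models the property is standardized too and predictions are
rescaled before any metric is computed.

## AD definition methods

All methods share one contract (`ad_fit()` / `predict()`): a mandatory
boolean decision per reaction and, for score-based methods, a continuous
score of which the decision is a pure threshold function.

| method | score | inlier when | tunables |
|---|---|---|---|
| Leverage | h = xᵀ(XᵀX)⁻x | h ≤ h* | h* (default 3(M+1)/N) |
| Z-1NN | distance to nearest training row | d ≤ Dc | Dc = Zσ + ⟨y⟩, Z = 0.5 |
| 1-SVM | one-class SVM decision value | value ≥ 0 | nu, gamma |
| 2CC | P(Y-inlier) from a 500-tree classifier | p > p* | max_features, p* |
| BB | — | every column within training [min, max] | — |
| FC | — | no unseen fragment | — |
| RTC | — | signature set nonempty and ⊆ training set | radius R (default 1) |
| RFR_VAR | variance of 500 per-tree predictions | v ≤ σ* | σ* |
| GPR-AD | GP posterior predictive variance | v ≤ σ* | alpha, gamma, σ* |
| OZ / PZ / Perfect | — | all / none / Y-inliers | — |

Numerical conventions worth stating:

* **Pseudo-inverse for leverage.** Fragment matrices are routinely
  rank-deficient, so XᵀX is inverted by SVD pseudo-inverse, and the M in the
  default threshold h* = 3(M+1)/N counts only non-constant columns. Since
  descriptors are standardized, X is centred and h measures distance from the
  descriptor centroid; the sum of training leverages equals rank(X) (tested
  against the hat-matrix trace identity at 1e−8).
* **Boundary conventions.** Inlier at h = h*, d = Dc, v = σ*, and error
  exactly 3·RMSE (inclusive on the inlier side); the 2CC probability rule is
  strict (p > p*), matching its usual statement. A consequence: p* = 0 does
  not guarantee full coverage if the classifier assigns an exact zero
  probability.
* **Z-1NN.** Euclidean distances on standardized descriptors; training
  nearest-neighbour distances exclude self-matches; only the minimum distance
  is used, so ties are immaterial.
* **2CC degeneracy.** Y-outliers are training reactions whose cross-validated
  absolute error exceeds 3·RMSE (strict). If the labels are single-class the
  classifier is inapplicable: the fitted object decides all-inlier and a
  warning is recorded — the benchmark keeps running.
* **Ensemble variance** is the population variance of the per-tree
  predictions. The GPR is fitted through `kernlab::gausspr` with an RBF
  kernel; its reported predictive variance is the latent posterior variance
  in standardized-property units (verified in the tests against a closed-form
  implementation at 1e−6).
* **Composites.** A composite AD (`name*`) is the logical AND with RTC at
  radius 1 (RTC1). AND with the optimistic zero model is the identity; AND
  with the pessimistic one is the pessimistic model.
* **Degenerate metric inputs.** OIR is 0 when either side of the AD split is
  empty; OD is 0.5 when either Y-class is absent; ΔR²_AD uses R²_in = 0 for an
  empty inlier set (so the pessimistic zero model scores −R²_all) and is NA —
  excluded from ranking — for inlier sets of one reaction or constant observed
  property; AUC_AD is NA when only one decision class is present. AUC_AD is
  computed as the normalized rank-sum (ties counted one half) and is reported
  as a diagnostic only: it is not offered as a tuning objective because it
  cannot distinguish a tiny accurate domain from a huge inaccurate one.

## Tuning and benchmarking

The benchmark is a nested cross-validation (default 5×5, seeded, unstratified
uniform fold assignment). In each outer fold, the descriptor model — fragment
vocabulary, standardization, solvent lookup — is refit on the outer-training
set only, so no test reaction influences any fitted statistic of its own fold.
The QRPR regressors are tuned on the inner folds by mean RMSE (random forest:
max_features over {0.1, 0.3, 0.5, 0.7, 1}; GPR: alpha over 10^[−3,1] × gamma
over 10^[−4,0], log-spaced). AD hyperparameters are tuned on the pooled
inner-fold predictions by maximizing OIR or OD; both objectives are offered
and each produces its own model row (`RFR_VAR*/OIR` and so on). Ties are
broken toward larger coverage, then first grid point.

Decision thresholds (h*, Dc, σ*, p*) are searched over the 20 quantile levels
of the pooled inner-fold score distribution. For the refit on the full
outer-training set, the *chosen quantile level* is mapped onto the refit
model's own training-score distribution rather than reusing the absolute
inner-fold value: a model refit on more data produces systematically smaller
ensemble variances, and an absolute σ* carried over from the inner folds can
artifactually collapse coverage. The 2CC probability threshold is kept
absolute, since class probabilities are already on a fixed scale.

Predictions and decisions from the outer test folds are merged before any
metric is computed; Y-outlier labels for evaluation come from the merged
predictions (GPR-based rows are evaluated against the GPR predictions, all
other rows against the random forest). The Perfect AD model is constructed
from the same merged errors, which makes OD = 1 for it by construction — a
consistency check more than a method.

**Ranking.** For each dataset and each of coverage, ΔR²_AD (the
practical-utility measure) and OD, a model receives penalty 0 when its value
is strictly above the median across models, else 1 (NA values are penalized);
when non-native detection rates are supplied, accepting even one non-native
reaction adds a penalty. Models are ordered by ascending penalty sum, ties
alphabetical. With the strict-median rule, an odd method count penalizes the
median itself — the stricter of the two readings of "top half".

**External application.** `external_validate()` trains the full pipeline on
one dataset, applies it to an external set, and reports coverage and the
prediction quality computed on the decided X-inliers only, next to the no-AD
baseline — the workflow for the practically interesting question "which
predictions of my deployed model should I trust".

## The synthetic data generator

No experimental reaction data ships with the package; every test and the
acceptance script run on seeded synthetic suites (`builtin_suites()`):

* **substitution** — an S\(_N\)2-like scaffold (C–Cl breaks, C–O forms, with
  charge transfer to the leaving group) with substituent slots on the carbon
  and on the nucleophile;
* **elimination** — an E2-like scaffold (C=C forms, C–Br breaks, base
  protonation) whose substituent alphabet includes a glycine-like chain, so
  the suite's CGRs contain the static amino-acid fragments;
* **cycloaddition** — a Diels–Alder-like scaffold with six dynamic bonds;
* **zwitterion** — amino-acid tautomerism whose CGRs have charge changes but
  *no* dynamic bonds: the designed blind spot of fragment control;
* **leaving_group_shift** — substitution-scaffold reactions with a novel
  first-shell substituent at the centre plus a constant property shift of 3:
  a native-type cluster a structure-blind model mispredicts but RTC1 catches.

The property is a linear model over a handful of automatically selected,
linearly independent fragment counts (weights N(0, 0.8²)), plus condition
terms (weight −1200 on 1/T, an Arrhenius-like slope; 0.01 per percent molar
ratio), one identifiable two-feature interaction of weight 0.6, an intercept
of 2, and Gaussian noise of sd 0.3 — property values behave like log-scale
rate constants. Substituents are sampled with geometrically decaying
frequencies (ratio 0.5), mimicking the skew of real reaction databases, and
5% of reactions are planted as gross Y-outliers: an offset of ±5 (about 17
noise standard deviations), assigned preferentially to rare substituent
combinations. The rarity preference and the interaction term are deliberate:
prediction-variance ADs presuppose that ensemble variance tracks local data
support and that gross errors concentrate in sparsely characterized
chemistry. Cross-validated variance at a row is mathematically independent of
that row's own property value, so uniformly placed label errors would be
undetectable *in principle* by any X-side method — a generator without this
structure could not exhibit the behaviours the benchmark is meant to measure.
Hidden per-reaction flags (suite, template, planted-outlier) live in a sidecar
attribute/file and are never visible to fitted models.

What the generator does *not* emulate: chemically realistic kinetics or real
property distributions, stereochemistry, condition–structure correlations,
measurement-error heteroscedasticity beyond the planted outliers, and
vocabulary sizes beyond a few hundred fragments. Passing tests therefore
demonstrate the correctness of the machinery and the qualitative behaviours
designed into the suites, not performance on experimental reaction data.

```{r example}
suites <- builtin_suites()
train <- generate_reactions(suites$substitution, n = 100, seed = 1)
rtc <- ad_fit("rtc", reactions = train$reaction, radius = 1)
foreign <- generate_reactions(suites$elimination, n = 50, seed = 1)
mean(!predict(rtc, foreign$reaction))   # non-native exclusion rate
```

## Problem sizes used by the shipped checks

The test suite and the acceptance script run at desk scale: datasets of
60–150 reactions, 3–5 outer and 3–5 inner folds, forests of 100–500 trees,
and two-point hyperparameter grids where tuning behaviour rather than grid
resolution is under test. Statistical-tendency checks (the coverage ordering
of OIR- versus OD-tuned variance thresholds, planted-outlier recall) are
averaged over ten fixed seeds at n = 100–150 with five inner folds — the fold
structure at which the pooled inner-fold OIR curve is stable enough for the
tendency to emerge; identities (zero/perfect models, composite algebra,
oracle equivalences) hold exactly at any size.

## Known limitations

* The SMILES dialect is the subset needed for mapped reaction data: organic
  subset and bracket atoms, branches, ring closures, aromatic notation,
  charges and maps; no stereochemistry, isotopes are ignored, and there is no
  aromatizer — input aromatic flags are trusted after a ring-validity check.
* Signature strings are canonical within this package; they are not
  exchangeable with other CGR toolkits at string level, only equality
  semantics are guaranteed.
* Exhaustive enumeration in the canonical-form tie-break is exponential in
  the worst case; reaction-centre neighbourhoods are small (tens of atoms)
  and highly labelled, so refinement almost always terminates before
  branching matters.
* 1-SVM tuning selects (nu, gamma) pairs directly by the objective; with very
  small inner folds the decision can be unstable, which is the documented
  reason its coverage varies more than other methods'.
* The 2CC method is unavailable when a training split has fewer than two
  reactions in either Y-class; it then falls back to all-inlier with a
  warning rather than failing the benchmark.
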