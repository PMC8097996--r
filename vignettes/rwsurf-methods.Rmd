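---
title: "Methods: weighted survival forests for biomarker-variability cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted survival forests for biomarker-variability cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwsurf)
```

# The problem

In longitudinal diabetes care a patient's serial laboratory record —
HbA1c, total cholesterol, HDL-C, LDL-C, triglyceride measured over years
of visits — carries information beyond its level: its *visit-to-visit
variability*. `rwsurf` models a right-censored outcome (e.g. all-cause
mortality over an eleven-year follow-up) from per-patient engineered
covariates in which the temporal SD and CV of each analyte are
first-class predictors, using a random survival forest whose trees are
combined with learned, regularized weights.

# The model

## Base learner: a log-rank survival tree

Records are triples $(t_i, \delta_i, x_i)$: follow-up time in days,
event indicator, and a fixed-length feature vector (missing values
padded with $-1$; see below). A tree is grown by recursive binary
splitting: at each node `mtry` features are drawn without replacement;
for each, up to `nSplitCandidates` thresholds are drawn from the
observed in-node values; the split maximizing the standardized absolute
two-sample log-rank statistic $|O - E|/\sqrt{V}$ is taken, with
$x \le \text{threshold}$ routed left (ties at the threshold go left).
A split is admissible only if both children retain at least
`minLeafEvents` events; recursion also stops at `maxDepth` or when no
candidate separates the node ($V = 0$ or statistic $0$). Each leaf
stores the Nelson–Aalen cumulative hazard of its members,
$\hat H(t) = \sum_{s \le t} d(s)/Y(s)$, evaluated on the tree's shared
grid — the distinct event times of the sample the tree was grown on.
Censorings at $s$ count as at risk for events at $s$ (the standard
convention).

## Ensemble and weights

`fitForest()` grows $B$ trees on n-out-of-n bootstrap samples and
records in-bag indices. The ensemble cumulative hazard is the convex
combination $H_w(t|x) = \sum_b w_b H_b(t|x)$ on the global grid (the
distinct event times of the training data); the scalar risk score
("mortality") is $\sum_k H_w(t_k|x)$ over the grid. Uniform weights
$w_b = 1/B$ give the plain random survival forest.

The weights are then learned by minimizing, over the probability
simplex, the mean discrete-hazard negative log-likelihood plus an L2
penalty:

$$\mathcal L(w) = \frac1n \sum_i \Big[ -\delta_i \log\big(\Delta
H_w(t_i|x_i) + \varepsilon\big) + H_w(t_i|x_i)\Big] + \lambda \sum_b
w_b^2 ,$$

where $\Delta H_w(t_i|x_i)$ is the weighted hazard increment at the grid
time nearest $\le t_i$. Three design choices deserve comment, because
the underlying method statement leaves them open:

* **Likelihood definition.** "Log-likelihood" admits several readings
  for an ensemble of hazard estimators. We adopt the discrete-hazard
  form above (event term = log hazard increment, survivor term =
  $-H$) because it is computable from exactly what the trees store and
  is convex in $w$. A Cox partial likelihood over the mortality score is
  available via `loss = "cox_partial"` as an alternative.
* **Weight constraints.** Non-negativity and sum-to-one are imposed so
  that $H_w$ remains a valid (non-decreasing) cumulative hazard; the
  uniform-weight and single-tree models are then interior/vertex points
  of the feasible set, and the large-$\lambda$ limit is exactly uniform
  (the penalty's simplex minimizer).
* **What is tuned vs optimized.** Weights are *optimized* (projected
  gradient); $\lambda$ is *grid-searched* by five-fold cross-validation
  on the training records, held-out folds scored by the unpenalized
  loss, ties resolved toward the larger (more regularized) $\lambda$.
  Weight learning uses the training records; out-of-bag data are
  reserved for importance and evaluation.

## Optimization

Projected gradient descent from the uniform start: each iterate
projects a gradient step onto the simplex (Euclidean projection, the
sorting algorithm) and is accepted under backtracking only if the
penalized objective does not increase, so the iterate sequence is
monotone by construction. Stopping: projected-step norm below $10^{-6}$
relative to the step size, or 500 iterations. $\varepsilon = 10^{-12}$
floors the logarithm; without it a record whose event time precedes its
leaf's first event time (a zero increment) would make the loss
infinite. Away from zero increments the loss is insensitive to
$\varepsilon$ (doubling it moves the loss by far less than $10^{-6}$).

# Feature engineering

For each variability analyte inside the measurement window:
`baseline` = earliest in-window value, `mean`, `sd` (sample SD, $n-1$
denominator), `cv` = $100\,\text{SD}/\text{mean}$. A patient
contributes variability values for a parameter only with **three or
more** in-window measurements; below that, mean/SD/CV are missing
(the baseline value is still reported when any measurement exists).
Choices the data definitions leave open, fixed here:

* *Sample SD* ($n-1$): the convention of the variability literature;
  the denominator is otherwise unstated.
* *Baseline = earliest in-window measurement*: "baseline" is otherwise
  undefined; window endpoints are configurable since lab baselines may
  predate or coincide with the index date.
* *CV at zero mean is missing* (cannot occur for physiological values
  but must be defined); negative analyte values are excluded upstream
  by range validation, so CV is non-negative.
* *Hypoglycemia* (glucose strictly $< 3.9$ mmol/L per episode): counting
  over the entire follow-up leaks future information into a predictor,
  so the default counts only measurements dated up to the window end;
  `leakFreeHypoglycemia = FALSE` restores whole-follow-up counting.
* Anemia (Hb $< 13$/$12$ g/dL by sex) and iron deficiency (ferritin
  $< 67.4$ pmol/L) are strict; a flag that cannot be determined is
  *missing*, not false.

`padMissing()` replaces every missing cell by $-1$ (the padding the
forest is trained under — trees treat $-1$ as an ordinary value, which
implicitly lets splits separate "missing" from observed ranges); the
logical missing-mask is retained alongside for diagnostics.

# The synthetic cohort generator

`simulateCohort()` emulates the kind of registry the method targets:
per patient $i$ and analyte $a$ a latent mean $\mu_{ia} \sim
N(\text{popMean}, \text{betweenSD}^2)$ and latent volatility
$\sigma_{ia}$ from a log-normal with stated natural-scale mean and SD;
visit counts negative-binomial (mean 10, size 5, truncated at 1), visit
dates uniform over a five-year lookback window; measurements $y =
\mu_{ia} + \sigma_{ia}\varepsilon$. Event times are Weibull proportional
hazards, $H(t|x) = (t/b)^k e^{\eta}$, drawn by inverse transform, with
$\eta$ the centred linear predictor of the **latent** features named in
`effectSizes` — the hazard is driven by the true $\sigma$, not its noisy
estimate, which is what makes parameter-recovery tests meaningful.
Censoring is administrative at the follow-up horizon (mirroring a fixed
study end date), with optional exponential dropout behind
`dropoutRate`.

Default magnitudes follow the biochemical profile of a large type-2
diabetes registry: HbA1c population mean 8.56 % with between-patient SD
1.36 and within-patient SD averaging 1.28 (SD 0.851); lipids, glucose,
hemoglobin, ferritin and differential counts analogously; baseline
hazard $k = 1.4$, $b = 5334$ days, chosen so roughly half the cohort
has an event by the eleven-year horizon; default effects (log of
typical multivariate hazard ratios) for age, male sex, HbA1c mean,
HDL-C mean, NLR, plus $+0.35$ per unit of HbA1c within-patient SD so
variability genuinely carries signal. One published triglyceride
summary (SD 6.90 at mean 1.86 with CV 30.8) is internally inconsistent;
the generator calibrates the TG volatility to the CV row (SD ≈ 0.57).

What the generator does **not** emulate: informative visit processes
(sicker patients visiting more often), correlated analyte trajectories,
measurement-unit drift, ICD-coded comorbidity onset, or drug-dose
dynamics. Tests passing on this generator therefore demonstrate
correctness of the machinery and recoverability of a planted signal —
not clinical performance on registry data.

# Interpretation

* **Permutation importance**: prediction error is a fixed-horizon
  squared loss between $1 - S_w(h|x)$ and the observed status at
  horizon $h$ (default: median follow-up), restricted to records whose
  status at $h$ is determinable — event by $h$, or followed past $h$;
  censored-earlier records are excluded, which avoids biasing the null.
  An IPCW variant (inverse probability of censoring weights from the
  reversed-role Kaplan–Meier) is available via `ipcw = TRUE`. Each
  record is predicted only by trees for which it is out-of-bag, with
  the forest weights renormalized over those trees. VIMP = permuted
  error − baseline error; zero or negative marks a non-predictive
  variable. The permutation is seeded, so reports are reproducible.
* **Minimal depth**: per tree, the depth of the feature's first split
  (root = 0); a feature unused in a tree contributes that tree's
  maximum depth + 1 (the standard convention); averaged over trees.
  Structure-only: invariant to the weights.
* **Decision rules**: the "main tree" is taken to be the
  highest-weight tree — the weighting itself supplies a natural choice
  that uniform forests lack. Root-to-leaf paths are consolidated to one
  interval per feature, ranked by leaf mortality score, and annotated
  with out-of-bag membership and event counts.

# Evaluation harness

`crossValidate()` uses event-stratified folds (small folds otherwise
risk event-free test sets); per fold one bootstrap ensemble is grown
and scored both with learned weights (rwrsf; $\lambda$ tuned by inner
CV on the fold-training data) and uniform weights (rsf), beside a Cox
baseline (`survival::coxph`, Breslow ties by default for oracle
simplicity, Efron behind a flag; risk = linear predictor). Metrics:
Harrell's C (comparable pairs $t_i < t_j$, $\delta_i = 1$; risk ties
credit 0.5), rank-based AUC, and precision/recall at an explicit
operating point — predicted positive means risk at or above the cohort
median risk, a rule chosen because survival-model precision/recall is
meaningless without a stated threshold; the binary status is
event-during-follow-up (a horizon-restricted mode exists).

# Numerical and degenerate-case conventions

* Step functions: $H(t)$ = value at the largest grid time $\le t$; 0
  below the grid; an empty grid encodes $H \equiv 0$ (all-censored).
* Log-rank with zero variance (no events, or a degenerate group
  pattern) is defined as 0; such splits are never chosen.
* Unsplittable nodes (constant features, too few events) become leaves;
  a fully degenerate dataset yields a single-leaf tree, never an error.
* Simplex checks use tolerance $10^{-8}$; the optimizer's monotonicity
  is asserted to $10^{-9}$.
* `selectLambda` fold ties are broken toward larger $\lambda$
  (equality tolerance $10^{-12}$).
* All randomness flows through explicit seeds (bootstrap, tree
  candidate draws, folds, permutations); fixed seed ⇒ byte-identical
  artifacts.

# Problem sizes used by the test-suite and the acceptance script

The packaged checks run on simulated cohorts of 300–500 patients with
forests of up to 100 trees, ten recovery seeds, and five evaluation
seeds; oracle checks (Nelson–Aalen, log-rank, concordance, Cox
coefficient, two-tree weight learning) use exhaustive or brute-force
references on fixtures of up to 20 records. These sizes give stable
Monte-Carlo margins for every property asserted while keeping a full
run in the minutes range on a single CPU.

# Known limitations

* The discrete-hazard likelihood concentrates information at observed
  grid increments; cohorts with very sparse event grids make the
  event term noisy (the $\varepsilon$ floor then dominates for records
  below the grid).
* Weight learning is performed on training (in-bag-aggregate) records;
  an out-of-bag weight-learning mode would reduce optimism but shrinks
  the effective sample per tree.
* On data generated by a proportional-hazards linear model the Cox
  baseline is the correctly specified competitor and can outperform
  both forests; the weighted forest's advantage is expected where
  nonlinearities and interactions matter.
* Competing risks, time-varying covariates and informative censoring
  are out of scope.
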