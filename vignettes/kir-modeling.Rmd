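---
title: "Kinase inhibitor regression for cytokine secretion screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinase inhibitor regression for cytokine secretion screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Cytokines and chemokines are regulated by intracellular kinase signaling, but
which kinases control which secreted factor is rarely known. A
polypharmacology screen gets at this indirectly: a panel of n kinase
inhibitors, each with a known quantitative target profile against p kinases,
is applied to stimulated macrophages (LPS, 500 nM drug, 24 h), and the level
of each secreted factor is measured relative to the LPS-only control. Because
every drug inhibits many kinases at once, the inhibition profiles act as a
designed multivariate perturbation, and regression can deconvolve the
responsible kinases.

For one cytokine with response vector `y` (fraction of control, one value per
drug) and the drug-by-kinase residual-activity matrix `X` (percent of
uninhibited activity, 0--100), the model is penalized linear regression:

    minimize  (1/2n) * sum_i (y_i - b0 - x_i'b)^2
              + lambda * [ (1-alpha)/2 * ||b||_2^2 + alpha * ||b||_1 ]

with predictors standardized internally to zero mean and unit variance and
coefficients reported back on the original scale. A *positive* coefficient
means that higher residual kinase activity goes with higher secretion -
equivalently, that inhibiting the kinase suppresses the factor - so positive
coefficients nominate regulating kinases.

The full per-cytokine procedure (`fit_kir_model()`):

1. **Alpha sweep.** Models are fitted for 11 evenly spaced values of the
   mixing parameter, alpha = 0, 0.1, ..., 1.0.
2. **Penalty selection.** For each alpha, lambda is chosen by leave-one-out
   cross-validation, the folds being the n drugs in their given order (no
   shuffling: the procedure is deterministic). The grid is 100 log-spaced
   penalties from the smallest all-zero penalty (lambda_max, computed on the
   full data so fold errors are comparable) down by a factor 1e-3; for
   alpha < 0.05 the lambda_max formula uses 0.05 to stay finite. Ties in the
   cross-validated error break toward the larger penalty, i.e. the sparser
   model.
3. **Quality gate.** Using the best solution's held-out predictions:
   `nRMSE = RMSE / range(y)` and the Pearson correlation between observed and
   held-out predicted responses. A model is accepted when nRMSE < 0.1 *and*
   r > 0.85 (both strict). Held-out predictions, not in-sample fits, feed the
   gate: in-sample statistics of regularized fits would flatter every model.
   Range normalization of the RMSE is the default and configurable.
4. **Hit calling.** A kinase is *informative* for a cytokine when its
   coefficient exceeds 1e-8 in the selected solution for at least one
   alpha > 0. The pure-ridge member (alpha = 0) never produces exact zeros
   and is always excluded; the 1e-8 tolerance guards against float noise at
   the sparsity boundary.
5. **Prediction.** Accepted models predict unscreened inhibitors from their
   target profiles, `level = b0 + x'b`, using the best-alpha solution (lowest
   LOOCV MSE across the whole grid - the ridge exclusion applies to hit
   calling, not prediction). A pseudo-drug with all residual activities at
   100 predicts the fitted control level.

Downstream surfaces translate the models into the three result tables:
a binary kinase-by-cytokine matrix with per-kinase counts
(`build_kinase_cytokine_matrix()`); percent efficacy
`100 * (1 - level)` and drug rankings by average efficacy over the cytokines
of interest (`compute_efficacy()`, `rank_drugs()`); and cytokine-centric
subnetworks on a reference interaction graph (`extract_cytokine_network()`).

## The solver

The elastic-net core is solved on the Gram parameterisation
(`G = X'X/n`, `c = X'y/n`) by cyclic coordinate descent combined with an
active-set polish: a sweep activates penalty violators, the sign-restricted
penalized normal equations are then solved exactly on the active set (with a
line search to the first zero crossing when the solve would flip a sign,
which strictly decreases the objective), and a full KKT check certifies the
solution to the requested tolerance (default 1e-10 on the largest
stationarity violation). Plain coordinate descent converges slowly when
p > n and the penalty is small - precisely the screen's regime (34 drugs,
hundreds of kinases) - while the active-set solve removes that tail. The
alpha = 0 member has a closed form and is computed by one eigendecomposition
of the Gram matrix for the whole penalty path. Solutions are tested against
the ridge closed form, an independently written coordinate-descent solver,
and glmnet (by penalized-objective value; coefficient-level agreement with
glmnet is exact at the lasso end, while for intermediate alpha glmnet's
internal response scaling shifts its effective L1/L2 balance slightly away
from the documented objective).

Numerical conventions worth knowing:

* Standardization uses the population (1/n) variance; constant predictor
  columns are dropped with a warning and report coefficient 0.
* LOOCV refits the standardization within every fold; the left-out drug is
  scaled by the training fold's statistics.
* Support size along the penalty path is non-increasing in lambda for
  orthogonal designs (where it is a theorem); on correlated designs lasso
  variables can leave and re-enter the path, so no such invariant is
  enforced.
* Cytokines with zero response variance are skipped with a recorded reason,
  never fitted; constant responses or constant held-out predictions are
  rejected by the quality gate with an explanatory flag.

## The synthetic screen generator

Every stage is tested against screens with known ground truth
(`simulate_screen()`). The generative model mirrors the regression being
fitted:

    y_ic = b0_c + sum_j (X_ij / 100) * beta_jc + eps,   eps ~ N(0, noise_sd^2)

with responses clipped at 0. Defaults are the screen conditions this package
models: 34 screened inhibitors, a 427-inhibitor prediction panel, 298
kinases, 37 secreted factors. Per cytokine, `k_planted` kinases (default 5)
carry coefficients drawn Uniform(0.05, 0.3) on the fraction-of-control
scale - large enough to recover at n = 34, small enough to keep responses
positive - and the intercept is `1 - sum(beta)` so the uninhibited (LPS-only)
control level is exactly 1. Each drug strongly inhibits a random kinase
subset (residual activity Uniform(0, 50)) of expected fraction `selectivity`
(default 0.15: broadly selective tool compounds at 500 nM typically hit on
the order of 10-20% of profiled kinases); all other entries sit at
Normal(100, 2) truncated to [0, 100], emulating assay jitter. Response noise
defaults to sd 0.02 on the fraction-of-control scale.

The benchmark suite runs this generator at a reduced, desk-run scale
(34 drugs, 50 kinases, 10 cytokines, 25 seeds for the recovery and null
benchmarks; a 100-drug held-out panel), which keeps the regression problem in
the screen's n < p regime while the whole suite stays runnable on one CPU.

What the generator does *not* emulate - and therefore what passing tests do
not establish about real screens: secretion responses are exactly linear in
residual kinase activity (no saturation, synergy or pathway rewiring); noise
is additive Gaussian rather than the multiplexed immunoassay's
intensity-dependent error; kinase inhibition profiles are independent across
drugs, whereas real inhibitor panels share chemotypes and hit correlated
kinase families; and off-target effects outside the profiled kinome do not
exist. Planted-recovery rates on synthetic screens are accordingly an upper
bound on what the method can do with real data.

The secretome generator (`simulate_secretome()`) emulates the
control-versus-LPS comparison: 191 factors with log-normal baselines, a
subset shifted by a known fold change, log-normal replicate noise (sd 0.1 on
the log scale) and 4 replicates per condition - a realistic replicate count
for a differential comparison; the drug screen itself was run in duplicate,
but the package does not model that pairing.

## Screen statistics

`differential_secretion()` uses a two-sided Welch (unequal-variance) t-test
on `log2(value + 1)` readouts with Benjamini-Hochberg adjustment across
tested factors (significant at q < fdr, default 0.05). The offset-log
transform tolerates zero readouts and is configurable. The underlying screen
publication states significance without naming a test; Welch-on-logs with BH
is this package's choice, made for robustness to the strong mean-variance
coupling of immunoassay readouts. Factors with fewer than two replicates in
a condition are excluded with a recorded reason. `normalize_to_control()`
divides by the mean stimulated-control level, so the control maps to 1.0 and
factors with a zero control mean are excluded as unquantifiable.

## Drug ranking conventions

Efficacy is percent suppression relative to the stimulated control,
`100 * (1 - level)`; negative predicted levels clip to 0 before conversion. A
cytokine counts as *affected* at efficacy >= 50% by default - the screen
publication never defines "affected", so the threshold is explicit,
configurable and recorded in the output metadata. Ranking sorts by average
efficacy over the selected cytokines, ties broken by percent affected and
then drug id, making the output invariant to input row order. *Specificity*
(1 - normalized Shannon entropy of a drug's positive efficacy profile) is a
declared stand-in for an undefined quantity in the source material: 1 means
all predicted suppression concentrates on one factor, 0 means it spreads
evenly. *Selectivity* is the fraction of profiled kinases a drug inhibits
below 50% residual activity. Efficacies from rejected models are excluded by
default (`accepted_only = TRUE`) rather than silently mixed with
high-confidence predictions.

## Networks

The reference interaction graph is user-supplied (three-column edge list or
SIF; KEGG-derived in the original application) with the convention that
*higher weight means less likely interaction* - confidence-scored inputs can
be inverted on load. For each cytokine, the subnetwork is the union of all
minimum-total-weight paths of at most `max_hops` edges (default 2) from each
informative kinase to the cytokine's anchor node; all tied minimal paths are
kept, for determinism, and kinases without a qualifying path are reported as
disconnected rather than dropped. This is a deliberately small, exactly
testable variant of network construction - the full network-scoring
algorithm published alongside the original screen is out of scope here.
Pruning retains edges at or below a weight threshold and then drops nodes
disconnected from the anchor; it is idempotent and monotone in the
threshold.

## Known limitations

* Single-dose screens only: no dose-response modeling, no interaction or
  nonlinear terms.
* The quality gate's thresholds (nRMSE < 0.1, r > 0.85) are taken as given;
  they are conventions of the modeled screen, not optimized quantities.
* Hit calling is sign-restricted: kinases whose inhibition *increases*
  secretion (negative coefficients) are never called, by design.
* The LOOCV error surface over lambda can be flat near its minimum; the
  sparser-model tie-break makes selection deterministic but two nearly
  identical screens can still select different penalties.
* With 34 drugs and hundreds of kinases, correlated inhibition profiles make
  individual coefficients unstable; the informative-kinase union over the
  alpha grid trades precision for recall deliberately.
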