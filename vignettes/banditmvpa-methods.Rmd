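---
title: "Models and methods behind banditmvpa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind banditmvpa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package computes

`banditmvpa` implements, end to end and against synthetic data, an analysis
chain used in model-based neuroimaging studies of reward learning in
adolescents: behavior on a three-arm social bandit is fit with a family of
Rescorla–Wagner models; reward outcomes are decoded from multivariate
neural activation patterns across subjects; the decoder is applied at
choice time to measure how strongly the reward pattern is *re-activated*
in proportion to the chooser's expected value; and trial-level
mixed-effects, moderation and mediation models link that coupling to
internalizing symptoms and to the exploitation/exploration strategy
expressed in the softmax inverse temperature.

No human data ship with the package. A generator (`generate_cohort()`)
produces cohorts with exactly the statistical structure the analysis
assumes, so every downstream stage is testable offline, and the tests say
precisely what has been established: that the pipeline recovers planted
structure, not that any empirical claim about brains is reproduced.

# The task and the learning models

The environment (`task_config()`, `make_schedule()`) is a 90-trial
three-arm bandit. Arm reward probabilities are {0.8, 0.5, 0.2}; every 30
trials the assignment of probabilities to arms is redrawn uniformly from
the permutations that differ from the current one, so each block
transition is a detectable change. A win nets +$10 and a loss −$10; for
learning, outcomes are coded r ∈ {+1, −1}, which makes the initial value
V = 0 a neutral prior (an alternative {1, 0} coding is configurable).

Learning follows the Rescorla–Wagner rule V ← V + α·δ with prediction
error δ = r − V, in a 2×2 factorial of variants (`model_spec()`):

* **A+ (counterfactual / anticorrelated updating):** each unchosen arm u
  is updated toward the *inverse* outcome, δ_u = (−r) − V_u, with no extra
  free parameter. In a setting where one arm's gain is typically another's
  loss, this captures the anticorrelation a learner can exploit.
* **RS+ (risk sensitivity):** separate learning rates α⁺ and α⁻ apply to
  positive and negative prediction errors (δ = 0 triggers no update under
  either rate), inducing asymmetric valuation of risky arms.

Choices are softmax in the values, p_i ∝ exp(βV_i), computed with
max-subtraction; β ≥ 0 is the inverse temperature, the package's
"exploitation" parameter. β = 0 is the uniform policy, giving the exact
identity NLL = n·ln 3 used as a test oracle.

One update implementation (`rw_update()`) serves both simulation and
likelihood; the compiled likelihood used in fitting is tested to 1e−10
against a deliberately naive straight-line transcription of the equations
and against `negloglik(..., engine = "r")`.

# Hierarchical fitting and model comparison

Subjects are fit per model variant with empirical-Bayes Laplace-EM
(`fit_hierarchical_em()`), approximating full hierarchical Bayesian
inference: the E step computes each subject's MAP estimate (multi-start
BFGS in the unconstrained space logit α, log β) and a Laplace covariance
from a central-difference Hessian (step 1e−4, eigenvalues floored at
1e−6); the M step re-estimates a diagonal Gaussian population prior from
the approximate posteriors. Stochastic multi-start is used on the first
pass only; later passes warm-start deterministically from the previous
MAP and the prior mean so the EM map is a fixed function of the prior and
can converge. Convergence is declared when prior means and standard
deviations move less than `tol` (default 5e−3; default `max_iter` 40).

Because AIC is defined for maximum-likelihood fits, each subject is refit
after convergence under the converged prior with variance inflated ×100
(effectively flat, warm-started), and AIC = 2k + 2·NLL with k = 2 (RS−)
or 3 (RS+). Model comparison sums AIC over subjects; ties break toward
fewer parameters.

Numerical notes: the EM-monitoring objective is the summed Laplace
approximation to the marginal likelihood; Laplace-EM is not exactly
monotone, so the test asserts monotonicity within a slack of 0.05 rather
than machine tolerance. The β estimates entering downstream analyses are
the hierarchical MAP estimates (not responsibility-weighted ones).

# The synthetic cohort: what is planted, and why these defaults

`cohort_config()` states the world once:

* **60 subjects, 2 balanced sites, 8 networks × 200 voxels, 90 trials** —
  a mid-sized two-site adolescent cohort at the task's stated length.
* **Latent internalizing factor S ~ N(0,1)** drives the CBCL internalizing
  total (loading 0.9) and depression/anxiety/somatic subscales (0.7);
  log CTQ correlates 0.4 with S but has *no* direct path to any neural
  quantity, mirroring the null for trauma severity that the analysis is
  meant to be able to find. Age, IQ and head motion are pure nuisance;
  motion scales a subject's voxel noise (`exp(0.1·z)`), so the covariate
  has a real job.
* **log β = 1.5 − 0.5·z(S) + ε (ε sd 0.3)** — higher internalizing means
  more random exploration. Learning rates are Gaussian in logit space,
  independent of S, with means α⁺ = 0.5 and α⁻ = 0.1 (sd 0.4).
* **Neural patterns:** each network has one centered unit-norm direction w
  shared across subjects (cross-subject decoding presupposes a common
  code). Outcome rows are snr·(±1)·w + N(0,1) noise with snr = 2; choice
  rows are κ_i·V_chosen(t)·w + noise with κ_i = 1 − 0.4·z(S_i) + η
  (η sd 0.25) in the designated striatum network and κ_i = 1 + η
  elsewhere.

Two defaults deserve justification. First, snr = 2 puts single-trial
outcome decodability at roughly Φ(2) ≈ 0.98 along w, which after
estimation loss lands leave-one-subject-out accuracy in the mid-0.9s —
the regime the analysis assumes (decoders must work before reactivation
can be measured). Second, the learning-rate asymmetry (0.5 vs 0.1) is
deliberately strong: identifiability analysis during development showed
that at 90 trials the expected per-subject likelihood advantage of the
risk-sensitive model over its 2-parameter nested alternative equals the
AIC penalty when the means are 0.4/0.15, making the generating model
unrecoverable. Since recoverability of planted structure is a stated
requirement of the generator, the asymmetry was set (once) to the point
where the generating variant is identifiable, and not revisited.

What the generator does **not** emulate: hemodynamics, volumetric
geometry, fMRI noise autocorrelation, session/run structure, missing
data. A green decoding test therefore establishes correctness of the
pipeline's statistics, not robustness to fMRI artifacts.

Note one structural choice with visible consequences: β and κ are both
children of S (a common-cause fork), not links in a chain. The full
pipeline's mediation test on default data is accordingly weak — the
mediator carries little information about β beyond the exposure — and
the mediation *recovery* acceptance runs on the module-level planted-path
design instead. This is the stated world, not a defect.

# Decoding

Per network, all subjects' outcome-phase trial×voxel matrices are
row-centered (each trial's mean removed) and stacked; a soft-margin SVM
with Gaussian kernel is trained on the N−1 remaining subjects for each
held-out subject, evaluated on the held-out outcome trials (balanced
accuracy = mean of sensitivity and specificity), and applied to the
held-out row-centered choice-phase trials to give signed hyperplane
distances, positive = reward side by the labeling convention.

Implementation: no SVM library is available in the deployment
environment, so `src/svm.cpp` implements the C-SVC dual with a
libsvm-style SMO solver (maximal-violating-pair selection, precomputed
kernel); it is validated against scikit-learn's libsvm on a frozen
fixture to 1e−3. The kernel width is the conventional "scale" heuristic
1/(p·Var), computed once per network from the pooled outcome data and not
tuned per fold; cost C = 1. The cross-subject kernel matrix is computed
once per network and shared by all folds (the fold's training set indexes
into it), which is what makes the default cohort decodable in ~20 s per
network on one CPU. No class rebalancing is applied (win rates are ≈53%
under the default schedule and balanced accuracy already corrects base
rates); no per-subject standardization beyond row-centering.

# Coupling and moderation

`assemble_trial_table()` joins, per network and trial, the hyperplane
distance with the expected value V of the chosen arm *replayed from the
fitted parameters* over the subject's actual choices and outcomes (never
the generating truth), plus covariates (age, IQ, motion, the subject's
own decoding accuracy) and moderators. Continuous predictors are
standardized cohort-wide; distances stay on their native scale (the
coupling test is equivariant under rescaling).

The coupling model per network is

    distance ~ V + age + iq + motion + decode_acc + (1 | site/subject)

fit by REML (lme4), fixed effects tested with the large-sample normal
approximation, Bonferroni-corrected across the 8 networks
(0.05/8 = 0.00625, conventionally printed 0.0063). On convergence
failure the random structure simplifies to subject-only and the fit is
flagged.

Moderation adds the subject-level moderator and its V× interaction, and —
deliberately deviating from an intercepts-only default — an uncorrelated
per-subject random V slope. The reason is calibration, not taste: the
stated world contains true slope heterogeneity (η sd 0.25), and a
moderator of a trial-level slope tested at trial-level degrees of freedom
treats chance correlation between that heterogeneity and the moderator as
signal; in development this flagged planted-null networks at the
corrected alpha. With the random slope the interaction is tested against
between-subject slope variance and the null networks are clean while the
planted striatum effect remains unambiguous. `random_slope = FALSE`
restores the literal intercepts-only model. When the moderator is a
clinical scale, log CTQ stays in the model as the trauma-severity
covariate.

# Mediation

The subject-level mediator is the per-subject OLS slope of striatum
distances on the fitted V series (`subject_coupling_slopes()`); subjects
with a degenerate V series get a missing slope. `mediation_bootstrap()`
tests X → M → Y (X standardized internalizing, Y fitted log β, log CTQ as
covariate) with subject resampling: paths a and b are refit per resample,
the indirect effect ab gets a percentile CI (default 95%, 50,000
iterations in the pipeline; BCa is not implemented) and a two-sided
bootstrap p = 2·min(Pr(ab ≤ 0), Pr(ab ≥ 0)), point mass at zero counted
on both sides. For the linear point estimates c = c′ + ab holds exactly
and is asserted.

Calibration of the indirect-effect test is composite: under the joint
null (both paths zero) the product test is intrinsically conservative
(measured 0 rejections in 200 null replicates) — a well-known property,
not a bug — while at the boundary null (a ≠ 0, b = 0) rejection runs at
the nominal rate (measured 9/200 at α = 0.05). The acceptance tests
assert both behaviors separately.

# Orchestration and reproducibility

`run_pipeline()` chains simulate → fit → decode → couple → mediate →
report, writing CSV/JSON per stage plus a manifest with the config
snapshot, named per-stage seeds derived from the master seed, and MD5
checksums of every output; re-running with the same config reproduces the
checksums bit for bit. A CLI front end with cumulative subcommands lives
in `inst/cli/banditmvpa.R`. The default full-size run completes in about
2.5–3 minutes on a single CPU; the test suite uses reduced cohorts where
the full size adds nothing (decoding accuracy at 12 subjects, end-to-end
reproducibility at 20 subjects × 2 networks), while model recovery,
parameter recovery and moderation run at the full 60 × 90 scale.

# Known limitations

* The empirical-Bayes EM is a point approximation to hierarchical Bayes:
  no responsibility weighting across models, no posterior uncertainty in
  the group prior, diagonal prior only.
* Fixed-effect p-values use the normal approximation; with 60 subjects
  the moderation tests (effective df ≈ subjects) are mildly
  anti-conservative relative to a t reference.
* The SMO solver implements first-order working-set selection without
  shrinking; adequate at this scale, slower than libsvm on much larger
  problems.
* Percentile (not BCa) bootstrap CIs; the known slight undercoverage at
  n = 60 is visible in the calibration tests' tolerance bands.
* The generator's fork structure means pipeline-level mediation is weak
  by construction (see above); only the module-level recovery is a power
  claim.
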