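---
title: "Models and methods behind twosteptask"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind twosteptask}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The task

The two-step task dissociates habitual (model-free, MF) from goal-directed
(model-based, MB) control. On every trial a first-stage choice between two
actions leads probabilistically to one of two second-stage states: action
$k$ reaches state $k$ on a fixed 70% of trials (*common* transition) and the
other state otherwise (*uncommon*). Each second-stage option pays a unit
reward with a probability that drifts across trials as an independent
Gaussian random walk (step SD 0.025) reflected into $[0.25, 0.75]$. A
purely MF learner repeats rewarded first-stage choices regardless of the
transition that produced the reward, predicting a main effect of previous
reward on the probability of staying; an MB planner inverts the effect of
reward after uncommon transitions, predicting a reward-by-transition
interaction.

`task_config()` holds the generative settings (201 trials per session, the
70/30 scheme, walk SD and boundaries, an optional miss rate for trials
without a response). The defaults are the study conditions this package
emulates: 20 subjects times 5 sessions of 201 trials. Design choices worth
stating explicitly:

* **Second stage has a genuine two-option choice** in each of two states
  (four independent reward walks). The stage-2 inverse temperature and
  learning rate of the agent imply stage-2 decisions, so the standard
  two-state/two-action layout is used.
* **Common mapping is the identity** (action $k$ commonly reaches state
  $k$); arbitrary but fixed.
* **Boundary reflection is single**: $x > h \mapsto 2h - x$ and
  $x < l \mapsto 2l - x$. At the default step SD (0.025, 2.5% of the walk
  range per step versus a 50-point band) a step can never overshoot far
  enough to require a second reflection.
* **Missed trials** are generated by an independent Bernoulli draw,
  carry no choices, produce no learning update, and are excluded from all
  analyses; the perseveration indicator keeps referring to the last valid
  choice.

# The hybrid agent

The agent family follows the hybrid SARSA($\lambda$)/model-based
architecture. Stage-2 values $Q_2(s,a)$ are learned by temporal difference
with rate $\alpha_2$ from the 0/1 reward. Stage-1 MF values update with
rate $\alpha_1$ from the (pre-update) visited stage-2 value, plus the
stage-2 prediction error weighted by the eligibility $\lambda$. MB values
are computed prospectively from the instructed transition scheme,

$$Q_{MB}(a) = P(\text{common}) \max_{a'} Q_2(s_a, a')
            + (1 - P(\text{common})) \max_{a'} Q_2(s_{\bar a}, a'),$$

with the transition probabilities fixed at their instructed values rather
than learned (participants are told the scheme; an incremental
transition learner was considered and rejected as out of scope for the
reference analyses). Stage-1 choice is a softmax over

$$b_{MB}\, Q_{MB}(a) + b_{MF}\, Q_{MF}(a) + p\, \mathbf{1}[a = a_{t-1}],$$

and stage-2 choice a softmax with inverse temperature $\beta_2$. The seven
free parameters are $b_{MB}, b_{MF}, \beta_2 \ge 0$ (exponential transform
from the unconstrained fitting scale), $\alpha_1, \alpha_2, \lambda \in
(0,1)$ (logistic sigmoid), and the unbounded perseveration $p$ (identity).
The perseveration term multiplies a $\{0,1\}$ repeat indicator of the
previous valid stage-1 action; the alternative $\pm 1$ coding only rescales
$p$ by 2 and shifts the intercept, so the choice is a convention, stated
here once.

Two conventions the literature leaves implicit are fixed as follows: the
stage-1 backup uses the *pre-update* stage-2 value (the classic ordering),
and Q values restart at zero at the beginning of every subject-by-session
unit (units are fitted exchangeably under one group prior, with no
carry-over between sessions).

`model_variant()` exposes eight variants built from four toggles: separate
versus shared learning rates, two separate stage-1 weights ($b_{MB}$,
$b_{MF}$) versus an explicit mixture ($\beta_1$, $\omega$ with weights
$\beta_1\omega$ and $\beta_1(1-\omega)$), eligibility trace present or
fixed at 0, perseveration present or fixed at 0. The two named anchors are
`ll2bmfbmb2alr` (full two-beta model) and `llm2b2alr` (the classic
$\omega$-weighted hybrid). The remaining six compositions are this
package's own registry choices. Note that the two stage-1
parameterizations span exactly the same likelihood surface
($w_{MB} = \beta_1\omega$, $w_{MF} = \beta_1(1-\omega)$ is a bijection
onto the positive quadrant), which the test suite verifies numerically;
differences between them in a hierarchical comparison can only come from
how Gaussian the population looks in each coordinate system, not from the
data likelihood. Model "recovery" between these two variants is therefore
intrinsically a coin flip, and iBIC differences between them are a few
points in tens of thousands.

# Hierarchical empirical-Bayes fitting

`em_fit()` treats every subject-by-session unit as a draw from one
Gaussian prior on the unconstrained parameter scale and alternates:

* **E step** — per unit, a multi-start BFGS maximization of
  log-likelihood plus log prior (MAP), with posterior moments from the
  Laplace approximation (inverse Hessian of the negative log posterior,
  eigenvalues clipped to $[10^{-8}, 4\max(\sigma^2)]$ so flat directions
  cannot derail the update). The first EM iteration uses the prior mean
  plus 4 prior draws as starts; later iterations warm-start from the
  previous MAP with one fresh restart.
* **M step** — prior mean as the average of unit means; prior covariance
  as the average of Laplace covariances plus squared deviations.

The default prior covariance is **full** rather than diagonal. The unit
likelihood has a pronounced ridge linking $b_{MF}$, $\alpha_1$ and
$\lambda$ (raising the weight while lowering the rate leaves short
sessions almost equally likely); a diagonal prior cannot represent that
population correlation, over-shrinks the rate, and inflates the group mean
of $b_{MF}$ noticeably at 201 trials per unit. With the full covariance
the residual group-mean bias roughly halves. `covariance = "diagonal"`
restores the independent prior. EM starts from a weakly informative prior
(mean 0, variance 6.25 per unconstrained parameter — covering learning
rates in roughly (0.01, 0.99) and weights over two orders of magnitude),
runs at most 30 iterations by default and reports `converged = FALSE`
(never silently) when the hyperparameters still move by more than `tol`.

A known limitation, quantified in the package's own recovery runs and
deliberately not hidden: with 201 trials per unit the MAP/Laplace
machinery recovers the group means of well-identified parameters
($\beta_2$, $\alpha_2$, $p$) essentially without bias, but whichever
parameters sit on the ridge at a given realization ($b_{MF}$, $\alpha_1$
or $\lambda$) can retain a finite-sample bias of 0.1-0.4 on the
unconstrained scale — two to seven draw standard errors at 100 units —
that does not vanish even at 1005 trials per unit. Rank-order recovery is
much safer: true-versus-MAP Spearman correlations for the stage-1 weights
are 0.5-0.8 at study scale. Conclusions should therefore rest on
within-design comparisons and correlations, not on absolute group means of
the ridge parameters.

Model comparison uses the integrated BIC: per unit, the marginal
likelihood of its choices under the fitted prior is estimated by
Monte-Carlo integration (2000 prior samples by default, log-sum-exp
accumulation, fixed seed), and $-2\sum_i \log \hat m_i$ is penalized by
$h \log N$ where $h$ counts prior hyperparameters (two per free parameter)
and $N$ counts both stage choices of all valid trials. The per-unit BIC at
the MAP uses the same $N$ convention; the field does not standardize
whether one or both stages count as "choices", so this is documented here
as the package's convention.

# Stay/switch regression

`build_stay_design()` produces one row per analyzable trial with the
outcome *stay* (current stage-1 choice repeats the previous one) and
$\pm 1$ codings of the previous trial's reward, transition, and
correctness. The first valid trial of a session and any pair interrupted
by a missed trial are excluded. The *correct* regressor guards against
value differences at trial start masquerading as a transition-by-reward
interaction: with the generative walks available (always, for synthetic
data) the correct action is the one whose common state has the higher
attainable reward probability on that trial; without walks a decayed
(rate 0.9) empirical reward average per state stands in.

`fit_mixed_logistic()` fits
`stay ~ reward * transition (* session) + correct` with by-subject random
intercept and slopes via `lme4::glmer` (Laplace), treatment-coding
sessions against the first. On singular fits the random structure falls
back from correlated to uncorrelated slopes to a random intercept, with a
warning — simulated cohorts with identical agents have no between-subject
variance, so the fallback is routine there. Per-term Wald statistics come
from `car::Anova`; the linear analogue (`fit_mixed_linear()`, for
continuous per-trial responses such as hemodynamic amplitudes, z-scored
within subject by default) uses REML via `lmerTest` with Satterthwaite
F tests. A pooled plain-logistic mode exists for large homogeneous
simulation sweeps, where subject random effects are zero by construction
and `glmer` adds only runtime.

One caveat the simulations make visible: even a *pure* MF agent
($\lambda = 1$, no MB weight) shows a small negative reward-by-transition
interaction (about $-0.08$ next to a reward effect of $+1.0$ at 100 agents
x 201 trials) through reward-history correlations that the correct
regressor only partly absorbs. At large simulated cohorts this bias is
statistically significant, so "no interaction" should be read as "small
relative to the reward effect", not "exactly zero".

# Mapping parameters onto regression coefficients

`run_sweep()` varies one model parameter over a five-point grid while
clamping the six others at reference medians, simulates 200 agents x 201
trials per grid value (1000 per swept parameter), and fits the stay
regression per grid value. `correlation_indices()` then correlates grid
values with the induced `reward` coefficients (MF index) and
`reward x transition` coefficients (MB index). The packaged grid —
weights and temperatures $\{0.25, 0.5, 1, 2, 4\}$, rates and eligibility
$\{0.1, \ldots, 0.9\}$, perseveration $\{-0.5, \ldots, 0.5\}$, medians at
the centers — is a documented stand-in for percentile grids estimated
from data, and is fully configurable; sweeps run on the natural scale
(an unconstrained-scale sweep is a trivial reparameterization of the grid).
`reconstruct_lme()` projects session means of the parameters through the
indices ($b_{MF}, \alpha_1, \lambda$ for the MF coefficient; $b_{MB},
\beta_2, \alpha_2$ for the MB one, summed, first-session-relative). The
projection is descriptive and deliberately has no inverse: several
parameter changes map onto the same coefficient change.

# Reliability, repeatability and power

`icc_2k()` implements the two-way random-effects, absolute-agreement,
mean-of-$k$-ratings intraclass correlation from the ANOVA mean squares,
with the $F = MS_{rows}/MS_{error}$ test of ICC $= 0$ and confidence
bounds from the single-rating interval (Satterthwaite denominator)
stepped up by Spearman-Brown. Labels: below 0.4 poor, 0.4-0.75 moderate,
above 0.75 excellent. `cv_percent()` reports the mean across subjects of
the per-subject SD over sessions divided by the absolute subject mean, in
percent, with a subject-level bootstrap interval (the aggregation and CI
method are package conventions; reported CVs elsewhere rarely state
theirs). `rm_anova()` is the one-way within-subject ANOVA with Bonferroni
paired post-hocs and orthogonal polynomial contrasts evaluated as
one-sample t tests on per-subject contrast scores; no sphericity
correction is applied by default, matching the reference analyses.

`power_simulation()` asks: if training changed a parameter's mean
linearly across five sessions by a given fraction, how often would the
linear-contrast test detect it at $\alpha = 0.05$ with 20 subjects? The
per-subject trajectories split the reference variance into a stable
between-subject part and session noise according to an assumed
test-retest correlation; power rises with that correlation because the
linear contrast cancels the stable component. The reference natural-scale
distributions (bMF mean 0.8 SD 0.6; bMB mean 1.0 SD 0.9) are the
package's synthetic defaults — published power statements for this design
rest on an external empirical distribution, so absolute power numbers are
not claimed, only the orderings (monotone in effect size, cohort size and
reliability), which the test suite checks. `detectable_effect()` inverts
the curve by bisection. The exact trend test behind published power
numbers for this design is not stated anywhere; the linear polynomial
contrast is the natural choice and is the package's documented assumption.

# Hemodynamics

The fNIRS chain is minimal but numerically complete. `mbll_convert()`
solves the two-wavelength (760/850 nm) modified Beer-Lambert system per
sample with the instrument constants as shipped defaults (extinction
1486/2526 for O2Hb, 3843/1798 for HHb; DPF 7.25/6.38; 30 mm
source-detector distance), treating them verbatim as dimensionless, so
concentrations are in arbitrary units; total hemoglobin is the sum of the
oxy and deoxy changes. `preprocess()` baseline-corrects, linearly
detrends and band-pass filters (zero-phase third-order Butterworth,
default 0.01-0.2 Hz — cutoffs are a package default, configurable, since
reference analyses rarely print theirs). `glm_trial_amplitudes()`
estimates one amplitude per trial by least squares on stick functions at
choice onsets convolved with a double-gamma response kernel (peak 5 s, a
NIRS-appropriate default, configurable) plus polynomial drift; onsets
packed tighter than the kernel make the design rank-deficient and raise
an error pointing at the inter-trial spacing. `synth_nirs()` runs the
forward model (amplitudes -> concentrations -> optical densities +
physiological sinusoids + white noise) so the whole chain can be tested
end to end, including feeding recovered amplitudes into
`fit_mixed_linear()`. Short-channel regression and motion-artifact
handling are out of scope.

# Problem sizes, seeds and numerics

All stochastic functions accept explicit seeds; cohort simulation derives
one stream per subject-by-session unit from the master seed and the unit
labels, so unit data are invariant to row order. The compiled likelihood
and the pure-R reference implementation agree to 1e-10 and both are kept.
Optimizer tolerance is 1e-10 relative on the objective with 4 restarts
(first EM sweep); iBIC uses 2000 Monte-Carlo samples per unit. The test
suite exercises the full study scale where the checks demand it (100
units x 201 trials for recovery and model comparison, 1000 agents per
swept parameter, 500 null replicates for calibration) and smaller
fixtures everywhere else; the synthetic generator reproduces the design's
sample sizes, transition scheme, walk and deadline-miss mechanics, but
not response-time distributions, motivational drift, or any within-session
non-stationarity of real participants — results on synthetic cohorts
validate the machinery, not human behavior.
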