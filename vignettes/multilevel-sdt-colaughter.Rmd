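---
title: "Multilevel Bayesian signal detection for colaughter and cospeech affiliation judgements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel Bayesian signal detection for colaughter and cospeech affiliation judgements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Listeners hear a short clip (1–3 s) of two people either laughing at the
same time (colaughter) or talking over one another (cospeech), and judge
whether the pair are friends or strangers. The scientific questions are
about *bias* and *discriminability*: do listeners lean towards "friends"
regardless of the truth (criterion), how well do they separate friend from
stranger dyads (sensitivity, d′), and how are both moved by the
vocalization mode and by time-compressing the clips (a proxy for speaker
arousal)?

`laughsdt` implements this analysis as a fully testable pipeline. Because
the behavioural responses from the original study are not publicly
deposited, the package pairs the analysis code with a generative simulator
of the complete experiment, so every stage — model fitting, model
comparison, condition summaries, ROC/AUC — can be validated by parameter
recovery against known ground truth.

## The design generator

`design_spec()` encodes the experiment's structure: 108 participants, 24
conversations (12 friend dyads, 12 stranger dyads), the first and last
qualifying clip per conversation and mode (96 stimuli), and two
counterbalanced lists. Each mode × familiarity cell of clips is split
evenly (and, when possible, evenly over first/last occurrence) between the
lists; a participant on list *l* hears that list's share sped-up and the
rest at original speed, so every participant hears each clip exactly once,
12 trials in each familiarity × mode × speed cell. Two choices the design
description leaves open are made here and exposed as seeded options:
participants alternate lists by index (balance), and presentation order is
an independent random permutation per participant.

```{r, eval = FALSE}
library(laughsdt)
design <- build_design(design_spec(seed = 1))
nrow(design)    # 10368 trials
```

## The generative model and its ground truth

Responses are simulated from the probit model the analysis assumes
(the "all terms" model, level 4):

$$\Pr(\text{"friends"}_{ij}) = \Phi\!\big(x_{ij}'(\beta + u_j) + s_i\big)$$

with reference-coded indicators (familiarity = 1 for friends, talk = 1 for
colaughter, speed = 1 for sped-up; reference levels strangers, cospeech,
original), participant effect vectors $u_j \sim N(0, DCD)$ over all eight
terms, and stimulus intercepts $s_i \sim N(0, \sigma_s^2)$. The two speed
versions of a clip share one stimulus intercept: the stimulus is the clip,
and heterogeneity between its speed versions is exactly what the speed
terms describe. Multivariate normality of the random effects is the
conventional reading of a multilevel model statement and is adopted here.

The default fixed effects are not hand-picked numbers: they are solved at
run time from the published condition-level table (criterion and
sensitivity z per mode × speed condition) through the invertible cell map
described below, giving
$\beta = (-0.22, 0.33, 0.19, 0.21, -0.11, 0.37, -0.02, 0.10)$.
The random-effect scales are chosen once as realistic for this kind of
judgement task: participant intercept sd 0.4 (listeners differ noticeably
in overall bias), slope sds 0.2 (modest individual differences in the
experimental effects), no default correlation, and stimulus sd 0.5 — in
speeded judgements of natural clips, stimulus heterogeneity is typically
the largest variance component.

What the simulator deliberately does *not* emulate: sequential effects
(habituation, feedback-free drift), response omissions, listening-side
acoustic confounds, and any dependence of the liking rating on anything
but $\Phi(\eta)$. Passing recovery tests therefore demonstrates that the
*inference machinery* is correct under the assumed model, not that the
model is true of real listeners.

## The model ladder

`make_model(0:4)` builds the five nested probit models: intercept only;
+ familiarity; + talk and familiarity:talk; the speed analogue; and all
eight terms. Main effects move the criterion, interactions with
familiarity move sensitivity. Every fixed term varies by participant
(correlated), and the intercept varies by stimulus, in all models.

## Priors

Fixed effects get normal(0, 0.3) priors by default — the value selected by
prior-predictive checking over the candidate grid {1, 0.5, 0.3, 0.1}
(`prior_predictive()`): the 0.3 prior still generates a broad distribution
of overall "friends" rates while making extreme rates (outside
[0.05, 0.95]) improbable, and the package's tests verify that the
extreme-rate probability is monotone in the prior sd. Three priors the
analysis description leaves unstated are set here and exposed in
`prior_spec()`:

* intercept: normal(0, 1). The overall bias is less constrained a priori
  than the manipulation effects; a wider prior avoids dragging the
  criterion to zero.
* random-effect sds: half-normal(0, 0.3), weakly regularizing on the
  z scale.
* participant correlations: LKJ with concentration 2, mildly favouring
  near-identity matrices.

The prior-sensitivity property (posterior means under sd 0.3 vs 0.5 differ
by less than a posterior sd on the same data) is part of the test suite.

## Posterior sampling

The sampler is a latent-utility Gibbs sampler: augmenting each binary
response with a truncated-normal utility makes the conditional draws of
the fixed effects, the participant effect vectors and the stimulus
intercepts exact multivariate-normal updates (no tuning, no divergences by
construction — a property that suits the probit link specifically). The
variance components use two complementary updates per sweep:

* adaptive random-walk Metropolis on log sds and atanh correlations under
  the half-normal/LKJ priors (proposal scales adapted in warmup batches),
  and
* an interweaved non-centered rescaling step: conditioned on the scaled
  effects, each sd enters the latent-Gaussian likelihood linearly and has
  a conjugate truncated-normal draw. This ancillarity–sufficiency
  interweaving breaks the slow random walk between effects and their
  scales that a purely centered sampler exhibits.

`fit_config()` defaults to two chains of 3000 iterations, half warmup,
mirroring the published sampler settings; `target_accept` (0.99) and
`max_trajectory_depth` (20) are recorded for provenance and for plugging
in gradient-based backends, but do not steer the Gibbs sampler. Whether
the published "3000 iterations" included warmup is not stated; both
readings are available through `warmup_fraction`.

Quality checks (`check_diagnostics()`) follow the published criteria:
no divergences, split-Rhat ≈ 1.00 (flagged outside [0.99, 1.01]),
effective samples above 200, and prior-vs-posterior learning (posterior
IQR narrower than the prior IQR). A known limitation: the 28 participant
correlation parameters are weakly identified at reduced scale and mix
slowly under random-walk updates; when they are themselves of interest,
run long chains and expect the LKJ prior to dominate. Fixed effects — the
quantities all summaries use — mix well (Rhat < 1.02 at 1000 iterations in
the reduced profile).

Degenerate inputs: data with only one response value are rejected before
sampling; trials referencing units absent from a fit raise an error in
prediction rather than silently marginalizing.

## Model comparison

PSIS-LOO is implemented from first principles: per-trial importance
ratios $1/p(y_n\mid\theta_s)$, a generalized Pareto fit to the largest
min(20% of draws, $3\sqrt S$) ratios by the profile-posterior
(Zhang–Stephens) method with a method-of-moments cross-check, tail
replacement by expected GPD order statistics truncated at the raw maximum,
and the usual elpd/LOOIC bookkeeping with Pareto-k warnings above 0.7.
All-equal ratios return untouched weights with a $-\infty$ sentinel k.
The implementation is validated against analytic leave-one-out refits of
a conjugate toy model (agreement within 0.1 elpd) and against simulated
tails of known index.

One caveat worth knowing: with trial-level (conditional) likelihoods,
stimulus random intercepts can absorb stimulus-level predictors
(familiarity and mode are properties of the clip), so leave-one-trial-out
differences between the intercept-only and full models are driven mostly
by the within-stimulus speed effects and by shrinkage. The package's
ranking test therefore simulates substantial within-stimulus effects.

## Condition summaries

Under the reference coding, every condition's criterion and sensitivity is
a documented linear combination of the eight coefficients
(`cell_combination()`): e.g. the sped-up colaughter criterion is
$\alpha + \beta_{talk} + \beta_{speed} + \beta_{talk:speed}$ and its
sensitivity $\beta_{fam} + \beta_{fam:speed} + \beta_{fam:talk} +
\beta_{fam:talk:speed}$. Contrasts (e.g. the colaughter − cospeech
sensitivity difference) are evaluated draw by draw and summarized with
means, central 95% intervals, and sign-credibility (the share of draws on
the mean's side of zero, reported as 100 when all draws agree).

Percentage-scale summaries can be computed two ways; both are returned.
The published table is reproduced exactly by transforming the posterior
mean ($100\,\Phi(\bar z)$), so that convention is the headline column;
the mean of the transformed draws is also provided, and the two agree
within a point for $|z| \le 1$.

## ROC and AUC

Predictions use the posterior mean of $\Phi(\eta_s)$ for plotted curves
and per-draw scores for AUC intervals, mirroring the published
construction. The threshold sweep classifies score ≥ t as "friends" over a
1001-point grid (or exhaustive observed-score thresholds for exactness);
curves are stored in conventional (FPR, TPR) orientation — the published
figure's specificity axis is a display option, not the internal
representation. AUC itself uses the rank-statistic identity with half
credit for ties, tested exactly against brute-force pair enumeration and
against `pROC` as an independent reference, and calibrated against the
closed-form equal-variance result $AUC = \Phi(d'/\sqrt 2)$. Condition-wise
AUC supports both all-trials and balanced subsetting (the published choice
is not stated; all-trials is the default).

## Problem sizes and numerical choices

The package's own validation runs use a reduced profile chosen as the
smallest scale at which recovery is informative: 24 participants × 48
stimuli (1152 trials), one or two chains of 600–1000 iterations, and 20
simulate-and-refit replicates for the coverage study; the full published
scale (108 × 96, 2 × 3000 iterations) is a configuration preset, not a
different code path. Other numerical choices: truncated-normal draws by
inverse-CDF with probabilities clamped to [1e-16, 1 − 1e-16]; a 1e-10
ridge before inverting the participant covariance; correlation proposals
rejected outright if the proposed matrix fails its Cholesky; LOO requires
at least 100 draws and at least 5 tail points before attempting a GPD fit.

## Known limitations

* Correlation parameters mix slowly (above); their posteriors at reduced
  scale are prior-dominated.
* Conditional-likelihood LOO limits sensitivity to stimulus-level
  predictors (above).
* The simulator's liking ratings are a placeholder for I/O testing; no
  ordinal model is provided.
* Numeric LOOIC values and AUC of the original behavioural data cannot be
  reproduced without the undeposited responses; the pipeline's correctness
  is instead established by the recovery, oracle-agreement and
  transform-reproduction tests.
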