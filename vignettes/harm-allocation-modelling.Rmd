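---
title: "Modelling harm allocation between one person and a group"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling harm allocation between one person and a group}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task and the scientific question

`harmalloc` models a moral-dilemma paradigm in which a decision maker
repeatedly allocates harm — operationalised as seconds of a painful
cold-pressor test — either to a single individual ("the one") or to each
member of a group of three or four people ("the group").  Harm levels live on
a grid from 30 to 180 s in 10-s steps, and every choice pair satisfies

$$C_{group} \le C_{one} \le C_{group} \cdot N_{group},$$

so the one option always minimises *total* harm (the utilitarian choice)
while the group option always minimises the *largest individual* harm (the
Rawlsian maximin choice).  Fifty unique pairs are each shown under three
default conditions — no default, one-default, group-default — giving 150
trials; the defaults probe Kantian (inaction) preferences, since letting a
default happen avoids an active harmful choice.

The scientific question is how people trade off these normative strategies,
and whether Rawlsian preference decomposes into separable psychological
dimensions: a *maximin weight* and an *agreeability threshold*.

## The choice model

The winning model scores the utility difference between choosing the one and
choosing the group as

$$U(one)   = -(1-\alpha) C_{one} - \alpha (C_{one} + \varphi)$$
$$U(group) = -(1-\alpha) C_{group} N_{group} - \alpha C_{group}$$
$$\Delta U = U(one) - U(group)
           = (1-\alpha)\,\Delta_{total} - \alpha\,(\Delta_{single} + \varphi)$$

with $\Delta_{total} = C_{group} N_{group} - C_{one}$ and
$\Delta_{single} = C_{one} - C_{group}$, and a softmax choice rule
$P(\text{one}) = 1/(1 + e^{-\tau \Delta U})$.

* $\alpha \in [0, 1]$ is the maximin weight: $\alpha = 0$ is a pure
  utilitarian who only tracks total harm; $\alpha = 1$ a pure maximin chooser
  who only tracks the worst-off individual's harm.
* $\varphi$ (seconds) is the agreeability threshold: the extra harm to a
  single person that the decision maker still deems mutually acceptable.
  Under $\alpha = 1$ the one option is preferred exactly when
  $\Delta_{single} < -\varphi$, which makes the threshold reading exact.
* $\tau > 0$ is the softmax inverse temperature on the seconds utility
  scale.  Because utilities span tens to hundreds of seconds, $\tau$ of
  order 0.1–0.5 already produces strongly value-driven choice.

A note on direction conventions: $\Delta U$ is defined algebraically as
$U(one) - U(group)$ and feeds $P(\text{one})$; the package adopts these
equations literally (the identity is asserted in the test suite), even
though informal descriptions sometimes label $\Delta U$ from the Rawlsian
side.  Ties ($\Delta U = 0$) get probability exactly one half; there is no
deterministic tie rule.

### Model variants

`harm_model()` exposes the family used for model comparison: the winning
three-parameter model (`"full"`), the boundary constraints `"alpha0"` and
`"alpha1"`, a no-threshold model (`"nophi"`), a multiplicative threshold
(`"ratio_phi"`), and an exploratory `"default_bias"` extension.  The
functional form of the ratio variant is not uniquely pinned down by the
published description; we reconstruct it as
$\Delta U = (1-\alpha)\Delta_{total} - \alpha(C_{one} - \varphi C_{group})$,
i.e. the acceptable harm to the one is a multiple of each group member's
harm.  With $\varphi_{ratio} = 1$ it coincides with the constant variant at
$\varphi_{const} = 0$, which the tests exploit.  The default-bias variant
adds a stickiness parameter for the default option and is clearly an
extension beyond the winning model, motivated by the observed default
effects.

## Hierarchical estimation

`fit_harmalloc()` treats subject parameters as draws from group-level
distributions and estimates both levels jointly by MCMC (JAGS), with a
noncentered subject-level parameterization
($\theta_s = \mu + \sigma z_s$, $z_s \sim N(0,1)$) to improve sampling
geometry.  The default profile is 4 chains of 1,000 kept iterations after
1,000 warm-up; `fast_profile()` (2 chains, 500 + 500) is used for
simulation studies and continuous testing.

Exact priors for this model family are a design choice; we centralise them
in `fit_settings()` and follow common hierarchical-decision-model
conventions:

* latent group locations: standard normal for the probit-scale $\alpha$
  and $\tau$ locations, $N(0, 20^2)$ for $\varphi$ (seconds);
* group scales: half-normal (SD 1 for $\alpha$ and $\tau$, 10 for
  $\varphi$);
* subject transforms: $\alpha_s = \Phi(\cdot)$,
  $\tau_s = \Phi(\cdot)\cdot\tau_{max}$, $\varphi_s$ untransformed.

$\tau_{max}$ defaults to 2: given the seconds scale of the utilities, that
bound already spans effectively deterministic choice, and a much larger
bound would concentrate prior mass on degenerate likelihood regions where
saturated probabilities make sampling fragile.  Choice probabilities are
clamped to $[10^{-9}, 1 - 10^{-9}]$ inside the sampler for the same reason.

Convergence is summarised by split-chain R-hat and effective sample size;
any monitored parameter with R-hat $\ge 1.1$ raises a warning (never
silently).  Fixing a group scale to zero (`fix_scale`) collapses the model
to complete pooling, which the tests use as a sanity check, and
`centered = TRUE` provides the centered parameterization for cross-checks.
A subtlety worth recording: a printed "group-level SD" can refer either to
the posterior SD of the group mean or to the between-subject spread.
`summary()` therefore reports both (`group_sd` and `between_sd`).

Trials on which a default was implemented through inaction are treated as
choices of the default option; the task makes inaction implement the
default, and all 150 trials enter the likelihood.

## Model comparison

`psis_loo()` implements Pareto-smoothed importance-sampling approximate
leave-one-out cross-validation from the stored pointwise log-likelihood
matrix: importance ratios are inverse pointwise likelihoods, the top 20 %
(at most $3\sqrt{S}$) are replaced by expected order statistics of a
generalized Pareto distribution fitted to the tail with the Zhang–Stephens
estimator (with the usual weak-prior regularisation of the shape), and
smoothed weights are truncated at the raw maximum.  Observations with tail
shape $k > 0.7$ are flagged.  The pointwise unit is one *trial*: that is
the granularity at which the hierarchical likelihood factorises, and it is
the scale on which the large expected-predictive-accuracy differences
between variants arise.  `compare_models()` reports ordered pairs
explicitly — the printed difference is always row model minus reference
model — with $SE = sd(\text{pointwise diff}) \cdot \sqrt{n}$, sidestepping
any sign-convention ambiguity.

`posterior_predictive()` simulates choice data from posterior draws and
correlates predicted with observed per-subject Rawlsian choice proportions;
with fewer than three subjects or zero observed variance the correlation is
reported as undefined rather than fabricated.

## The synthetic cohort generator

`generate_cohort()` draws subject parameters from

* $\alpha_s = \Phi(z_s)$, $z_s \sim N(\Phi^{-1}(0.95),\, 0.8)$,
* $\varphi_s \sim N(-10.03,\, 10)$,
* $\tau_s \sim \mathrm{LogNormal}(\log 0.2,\, 0.5)$,

and simulates choices from the winning model on the 150-trial design.  The
locations are the reported group-level estimates ($\alpha = 0.95$,
$\varphi = -10.03$).  The spreads are not reported at the subject level
anywhere we can read them off, so they were fixed once by calibration
against cohort-level behavioural anchors: the mean per-subject Rawlsian
choice proportion near 0.59 with a between-subject SD near 0.20, subject
agreeability thresholds spanning negative to positive values, and
near-deterministic per-subject choice behaviour.  A probit-scale SD of 0.8
for $\alpha$, 10 s for $\varphi$ and a log-normal $\tau$ centred at 0.2
jointly reproduce those anchors; narrower spreads (e.g. a $\varphi$ SD
below ~3 s) cannot, because they leave essentially no recoverable
between-subject signal and keep every subject's threshold strictly
negative.  These defaults are the package's study conditions and are not
adjusted per analysis.

What the generator does *not* emulate: response times, learning or
fatigue across trials, non-response, and any within-subject correlation
structure beyond the model itself.  Passing tests on synthetic cohorts
therefore demonstrate correctness of the machinery and identifiability
under the model, not validity of the model for any particular empirical
population.

## Parameter recovery

`parameter_recovery()` simulates a cohort with known truths, refits, and
correlates posterior-mean estimates with the truths.  Truths default to the
same group distributions the generator uses; the sampler is exposed because
the truth distribution materially affects the recovery correlation — a
wider spread of true $\varphi$ yields a higher $r$ at fixed estimation
noise.  With 150 trials and moderate $\tau$, the per-subject likelihood is
a three-coefficient logistic regression ($\Delta_{total}$, $\Delta_{single}$,
intercept), and $\hat\varphi$ is an intercept-to-slope ratio; its standard
error of roughly 4–6 s is the binding constraint on the $\varphi$ recovery
correlation at these study conditions.  The recovery report documents
non-identifiability (e.g. in the deterministic $\tau \to \infty$ limit,
parameters are only recoverable up to the decision boundary) rather than
failing.

Problem sizes: the full recovery profile is 68 subjects x 150 trials with
2 chains x (1,000 warm-up + 1,000 kept), which the acceptance script runs;
in-test recovery uses 20 subjects with shorter chains.

## IS-RSA

The intersubject representational similarity analysis relates
between-subject similarity in the agreeability parameter to between-subject
similarity in voxelwise neural responses to the worst-off harm.  All
similarities use

$$s_{ij} = \frac{1}{1 + d(S_i, S_j)}$$

with $d$ the Euclidean distance (absolute difference for scalars), mapping
every variable onto $(0, 1]$.  Parameters enter on their raw scale by
default, matching the formula as printed; `scale = TRUE` z-scores them
first for users who want scale-free distances.

Per voxel, the $n(n-1)/2$ dyads are modelled as

$$y_{(i,j)} = \beta_0 + \beta_\varphi\, s^{\varphi}_{ij}
  + \beta_\alpha\, s^{\alpha}_{ij} + u_i + u_j + e_{(i,j)},$$

where the subject random intercepts $u$ share a single variance component
and each dyad loads on *both* members' intercepts (multi-membership) —
the standard correction for the repeated occurrence of each subject across
dyads.  Because the fixed- and random-effect design is identical at every
voxel, the model is estimated by a one-time eigendecomposition of the dyad
membership Gram matrix $ZZ'$, after which each voxel costs one
one-dimensional REML optimisation of the variance ratio.  The test suite
checks this estimator against a dense brute-force REML oracle and against
lme4 with a hand-built multi-membership incidence matrix.  Voxels with zero
variance in neural similarity are flagged undefined rather than fatal.

Inference on $\beta_\varphi$ uses a Wald normal approximation (empirically
close to nominal: type-I error ~0.046 at the 0.05 level on null
simulations); a subject-level permutation test (`n_perm`) is available for
small cohorts — labels are permuted at the *subject* level and the
similarity matrix rebuilt, since permuting dyads directly would break
exchangeability.  Voxelwise p-values are thresholded at FDR $q < 0.05$
(Benjamini–Hochberg) and surviving voxels are reported as connected
clusters of at least five voxels.  Cluster connectivity defaults to
6-neighbourhood (face adjacency), the most conservative common convention;
18 and 26 are available.

Synthetic beta maps (`generate_beta_maps()`) plant a region (default a
$5^3$ cube in a $20^3$ grid) where the voxel response is a unit-slope
linear function of the subject's $\varphi$ plus Gaussian noise, so
$\varphi$-similar subjects have similar planted responses by construction;
everywhere else is independent noise.  This supports planted-recovery and
null-calibration tests, which is also how the anatomical claims of the
original fMRI analysis are out of reach here: we validate the *procedure*
(detection inside the plant, calibration outside), not any brain anatomy.
Per-voxel scalar similarity is used, as the analysis is voxelwise on beta
estimates; neighbourhood (searchlight) pattern similarity would be a
natural extension.

## Numerical and degenerate-input choices

* Softmax saturation is handled by computing log-probabilities via
  `plogis(log.p = TRUE)` and clamping inside the sampler.
* $\Delta U = 0$ gives probability exactly 0.5.
* Behavioural t statistics with zero between-subject variance are reported
  as `NaN` with an explanatory note, never silently dropped.
* The repeated-measures ANOVA applies the Greenhouse–Geisser correction
  (epsilon from the double-centered condition covariance, floored at
  $1/(k-1)$ and capped at 1); fractional corrected dfs are reported, and
  the implementation is cross-checked against `car`'s multivariate route.
* PSIS tail fits fall back to unsmoothed importance weights (with an NA
  shape) when the tail is too tied or degenerate to fit.

## Known limitations

* JAGS slice sampling mixes more slowly than gradient-based samplers on
  this posterior; the fast profile can show R-hat above 1.1 on group-scale
  parameters, which the fit surfaces as a warning.  Decisions that matter
  should use the default profile.
* The agreeability threshold's recovery correlation is bounded by the
  truth spread and the per-subject information in 150 binary choices; see
  the parameter-recovery section.
* The exact 50 predetermined choice pairs of the deployed task are not
  bundled; the design module samples a reproducible stand-in from the
  valid set (an explicit pair list can be supplied).
* No response-time modelling, no learning across trials, no real-BOLD GLM
  estimation.
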