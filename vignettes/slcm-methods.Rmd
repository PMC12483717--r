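---
title: "Modelling longitudinal counts with a structured latent curve model"
author: "slcmcount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling longitudinal counts with a structured latent curve model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slcmcount)
```

## The modelling problem

Repeated-measures count outcomes with varying opportunity are common in
developmental research: the motivating setting is the number of times a
young child produces a particular grammatical form in an oral language
sample, observed at a handful of ages between 1.5 and 6 years, with the
number of sampled utterances (the *exposure*) varying widely across
assessments.  Three features drive the model:

* **Exposure.**  The expected count must be proportional to opportunity.
  The natural log of the exposure enters the linear predictor as an offset
  with coefficient fixed at one, so the model describes a *rate* per
  sampled unit.
* **Overdispersion that changes with age.**  Conditional on age and
  exposure, counts across children are more variable than Poisson, and the
  excess variability is largest at the youngest ages and fades as skills
  consolidate.  The measurement model is therefore NB2 — negative binomial
  with quadratic variance $\mathrm{Var}(Y) = \mu + \phi\mu^2$ — with an
  occasion-specific dispersion $\phi_w$ shared by all individuals at an
  occasion.  Poisson is recovered as $\phi \to 0$.
* **Phase-change growth.**  On the log-rate scale the developmental
  trajectory is well described by two lines: a steep early phase and a
  flatter later phase, joined continuously at an age (the *changepoint*)
  that is itself estimated and varies across children.

## The model

Ages are binned into 3-month windows and coded by the window's lower bound
minus the 18-month origin, so assessment times are $t \in \{0, 3, \dots,
51\}$ months.  Each individual contributes at most one assessment per
window.  For individual $i$ at occasion $w$ with exposure $u_{iw}$,

$$y_{iw} \mid b_i \sim \mathrm{NB2}(\mu_{iw}, \phi_w), \qquad
\log \mu_{iw} = \log u_{iw} + f(t_{iw};\, \beta) + \Lambda(t_{iw})\, b_i,$$

where the population trajectory is the continuity-constrained
linear–linear function

$$f(t) = \beta_0 + \beta_1 \min(t, \gamma) + \beta_2 \max(0, t - \gamma),$$

with intercept $\beta_0$ (log rate per sampled unit at the origin), phase
slopes $\beta_1, \beta_2$, and changepoint $\gamma \ge 0$.  Zero-order
continuity eliminates the phase-2 intercept, which is recoverable as
$\beta_0 + \beta_1\gamma$; the unconstrained two-phase model has five free
individual growth parameters (four entering linearly, one — the
changepoint — nonlinearly), the constrained model four.

The individual deviations $b_i \sim N(0, T)$ enter through the first-order
Taylor basis of $f$ in its parameters, evaluated at the population values —
the structured-latent-curve device that lets the nonlinear changepoint
carry a linearly entering random effect with zero population mean:

$$\Lambda(t) = \Big(1,\; \min(t,\gamma),\; \max(0, t-\gamma),\;
(\beta_1 - \beta_2)\,\mathbf{1}[t > \gamma]\Big).$$

At $t = \gamma$ exactly the indicator takes its left value (zero),
consistent with $\max(0, t - \gamma) = 0$ there; this tie-break is covered
by a unit test.  Because the times are binned, the marginal likelihood is
smooth in $\gamma$ between bin boundaries and kinked at them.

The occasion dispersions can be left free (one per occasion) or constrained
to a trajectory: log-linear, $\phi(t) = \exp(\delta_0 + \delta_1 t)$, or —
the form that matches a steep early decline levelling off at a strictly
positive floor — exponential decay with a nonzero asymptote,

$$\phi(t) = \delta_3 + (\delta_1 - \delta_3)\,\delta_2^{\,t},
\qquad \delta_1 > \delta_3 > 0,\; 0 < \delta_2 < 1,$$

so that $\delta_1$ is exactly the dispersion at the origin and $\delta_3$
the asymptote.  The percent-per-month reading of $\delta_2$ is ambiguous
between proportional decay of $\phi$ and of $\phi - \delta_3$ (it is the
latter that decays exactly geometrically), so reports state the fitted
coefficients rather than a percentage.  Regression disturbances are not
represented separately: in this single-indicator first-order formulation
unexplained variability is carried entirely by $\phi_w$.

## Estimation

The marginal likelihood integrates the NB2 likelihood over $b_i$:

$$\ell_i(\theta) = \log \int \prod_w
\mathrm{NB2}\big(y_{iw};\, \mu_{iw}(b), \phi_w\big)\, N(b; 0, T)\, db.$$

Integration uses adaptive Gauss–Hermite quadrature: per individual the
integrand's mode is found by Newton's method (the log-integrand is concave
in $b$, so this is fast and safe), the grid is centred and scaled by the
Laplace curvature, and a tensor product of Gauss–Hermite nodes (default 7
per dimension; 15 matches heavier desktop defaults) is pruned of nodes
whose product weight falls below $10^{-10}$.  Two exact reformulations keep
this cheap:

* With $b = L s$, $T = LL^\top$, the integrand depends on $s$ only through
  $\Lambda L\, s$, so each individual's integral is taken over
  $\mathrm{rank}(\Lambda L) \le \min(n_i, d)$ standardized directions; the
  orthogonal complement integrates to one exactly.  Individuals with few
  assessments — or all assessments on one side of the changepoint —
  therefore need far smaller grids.
* A one-dimensional fit is verified against a $10^5$-point dense-grid
  integral to $10^{-6}$ in the test suite.

The total marginal log-likelihood is maximized directly by a bounded
quasi-Newton method (`nlminb`) with analytic gradients, rather than EM:
both target the same optimum and the quasi-Newton route converges in a few
dozen iterations with gradients supplied.  The gradient is the
Fisher-identity score — the posterior-weighted data score evaluated on the
adaptive grid — which estimates the exact marginal score; its residual
inconsistency with the quadrature objective is at quadrature-error level,
so the optimizer's occasional "false convergence" diagnosis near the
optimum is accepted as converged (the message is retained in the fit).

Because the changepoint's likelihood is kinked at every bin time (and the
indicator in its factor loading makes the surface jump there when the
changepoint variance is positive), the optimizer is followed by two
safeguards: a profile scan of the changepoint over a 1-month grid of
inter-bin points, restarting the optimization if a better cell is found,
and — when the estimate stalls against a bin-time kink — restarts from
either side of the wall, keeping the best objective.  A fit whose
changepoint still sits at a kink is flagged (`kink_changepoint`), since
curvature-based standard errors are not meaningful at a non-smooth point.

Internally the parameters are unconstrained: the changepoint is logit-mapped
to the interior of the observed time range (one bin width in from each end,
preventing boundary collapse), $T$ uses a log-Cholesky factorization whose
diagonal may approach zero (variances can pin at the boundary), and the
dispersion coefficients use log/logit scales.  Starting values come from a
two-segment weighted least-squares fit to bin-level log rates with a grid
search over candidate knots (nudged off the bin grid, where the likelihood
is kinked), method-of-moments per-bin dispersions, and random-effect
variances set to one tenth of the matching fixed effect's magnitude.

Standard errors are reported on the natural scale by the delta method, in
two flavours: model-based (inverse observed information, computed by
finite differences of the analytic gradient) and cluster-robust (sandwich
with per-individual analytic scores as the meat).  Empirical-Bayes
random-effect modes and Laplace posterior curvatures — the same quantities
that centre the quadrature — give individual fitted trajectories and the
above/below-average classifications.

## Identification

The model is a confirmatory factor model with a mean structure.  With $W$
unique occasions the mean structure offers $W$ observations against the
free population growth parameters (4 here), and the covariance structure
offers $W(W+1)/2$ observations against the unique free elements of $T$
plus the free dispersion parameters (with an unstructured $4 \times 4$ $T$
and the exponential-decay trajectory: $10 + 3 = 13$).  Both structures
must be overidentified; `slcm_identification()` performs the counting and
`slcm()` refuses underidentified configurations.

## Measurement-model selection

Before fitting the longitudinal model, the Poisson-versus-NB2 choice is
made per age bin on cross-sectional data (`fit_bins()`): empirical
mean/variance comparison, intercept-only GLMs with the exposure offset
(Poisson via `glm`, NB2 via `MASS::glm.nb`, dispersion reported as
$\phi = 1/\theta$), the Pearson statistic against its degrees of freedom
(which differ by exactly one between the families), the marginal
Kullback–Leibler divergence, and AIC/BIC.  The KLD compares the bin's
empirical count distribution with the model-implied marginal that averages
the fitted pmf over the bin's record-level exposures (exposure varies by
record, so a single representative exposure would misstate the marginal);
its support runs to the maximum observed count and is extended until the
model's cumulative mass exceeds $1 - 10^{-9}$.  BIC uses the bin's record
count as its sample size.  NB2 is recommended when it wins a majority of
bins on AIC and has the better-aligned Pearson ratio on a majority.

## What the synthetic-data generator emulates

`simulate_slcm_data()` reproduces the accelerated longitudinal design the
model assumes: N individuals (default 300) contribute 2–5 assessments at
3-month bins drawn uniformly without replacement over ages 18–72 months
(missing completely at random); exposures are drawn from a shifted
negative binomial with mean 120 and floor 25, independent of age (the
floor and age-independence mirror language-sample designs; the exact
exposure distribution is a stand-in, and is labelled as such); random
effects are multivariate normal; counts are NB2 along the implied
individual trajectories.  The default truth — rate $\approx 3$ per 1,000
units at the origin, log-rate slope 0.25/month up to a changepoint 10
months after the origin (28 months of age), flat thereafter, dispersion
decaying from 2.5 to 0.2, independent random effects
$\mathrm{diag}(0.2, 0.005, 0.002, 4)$ — is chosen to be qualitatively
realistic for early-childhood language production, not to reproduce any
empirical estimate.

The generator draws counts from exactly the fitted model (linear-in-$b$
basis, NB2 measurement), so passing recovery tests demonstrates correctness
of the estimation machinery under the model's own assumptions.  They do not
speak to robustness against features real corpora have and the generator
does not: corpus-level clustering, informative missingness, exposure
measurement error, or trajectory misspecification.

A practical finite-sample behaviour worth knowing: intercept-variance and
dispersion both describe multiplicative extra-Poisson variability, and with
2–5 assessments per individual the likelihood can be flat between them.
Some replicates pin an intercept variance at zero and absorb half the lost
variance into the intercept (the marginal mean constrains
$\beta_0 + \tfrac12\sigma^2_0$ more sharply than either alone).  Fixed
effects remain recovered within simulation error at N = 300; variance
components are noisier.

## Numerical choices

* Log-space pmf evaluation throughout (`lgamma`; no factorials); the
  classical negative binomial "size" is $1/\phi$.
* The linear predictor is capped at 40 before exponentiation so extreme
  optimizer trial points stay finite; no data point comes near the cap.
* NB2 sampling uses the gamma–Poisson mixture construction.
* Quadrature default: 7 adaptive nodes per dimension, pruning threshold
  $10^{-10}$; tests verify 5/9/15-node agreement.
* Problem sizes in the test suite: unit-test fits use N = 60–250 with 3–5
  nodes; the recovery/coverage study uses N = 300, 50 replicates, 7 nodes,
  diagonal $T$ — the acceptance-scale study the package documents.
* All randomness flows through the session RNG (`set.seed`); the CLI and
  the generator take explicit seeds and record them in their outputs.

A second finite-sample behaviour concerns the changepoint.  With a
changepoint random-effect standard deviation (2 months) comparable to the
bin width (3 months), the population changepoint is weakly located: across
simulation replicates its maximum-likelihood estimate occasionally settles
one inter-bin cell away from the truth, so its sampling distribution is
wider than — and multimodal relative to — what the local curvature at the
optimum reports.  Wald intervals (robust or model-based) for the
changepoint therefore undercover somewhat in the package's own N = 300
recovery study, while its bias is negligible; profile-likelihood intervals
would be the remedy and are not implemented.  The acceptance-scale test
suite measures and reports this honestly rather than masking it.

## Known limitations

Dispersion is population-level (no individual dispersion effects) and
covariates — on growth factors or in the dispersion trajectory — are out of
scope, as are zero-inflated measurement models, higher-order continuity at
the knot (not possible with degree-one phases anyway), multi-indicator
(second-order) formulations, and Bayesian estimation.  The changepoint
random effect's loading uses the min/max coding with the left-value
tie-break; alternatives that smooth the indicator would change the basis
only at the knot itself.
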