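---
title: "Modelling cancellation framing in intertemporal choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cancellation framing in intertemporal choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cancelnudge)
library(dplyr)
```

## The decision model

`cancelnudge` studies a choice-architecture question: does *partitioning*
both options of an intertemporal choice into a seemingly identical
component plus a residual ("$3 + $0 today versus $3 + $1 in a week"
instead of "$3 today versus $4 in a week") shift people toward the
larger later option?

The behavioural engine is a quasi-hyperbolic (beta-delta) discounted
utility model with CRRA curvature. An agent evaluating an amount $x$
delivered $t$ days from now receives

$$U = \delta^{t}\, \tfrac{1}{\alpha} x^{\alpha}
      \qquad (\times\ \beta \text{ on the delayed amount when an
      immediate amount is also on offer}),$$

with curvature $\alpha \in (0, 1]$, present bias $\beta > 0$, and a
per-day discount factor $\delta \in (0, 1]$. The time unit is days
throughout, because the discount factor is calibrated per day and every
binary stimulus uses 7-day delays. The present-bias multiplier is applied
to the later amount only when the earlier amount is immediate
($t = 0$); when both dates are in the future the exponent on $\beta$
is zero, i.e. the bias is inactive rather than the multiplier being
literally zero (which would annihilate the later term).

For a choice between $x_0$ now and $x_k > x_0$ in $k$ days, the agent
takes the later amount exactly when $\delta \ge \delta^*$ with

$$\delta^* = \left[\tfrac{1}{\beta}\left(\tfrac{x_0}{x_k}\right)^{\alpha}
  \right]^{1/k}.$$

Cancelling a common component $c$ replaces the amounts by their
residuals $y_0 = x_0 - c$, $y_k = x_k - c$ and yields the threshold
$\delta^*_c$ of the same form. Because $y_0 / y_k < x_0 / x_k$ whenever
$0 < c < x_0$, the cancelled threshold is strictly lower: partitioned
framing can only (weakly) increase patient choices in the gain domain.
Two notational conventions deserve mention:

* **Ties go to later.** The indifference condition is stated with a weak
  inequality, so an exactly indifferent agent chooses the later option.
  This matters only on a measure-zero set but is pinned down by a test.
* **$\beta$ is retained in the cancelled threshold.** An inline
  statement of $\delta^*_c$ without the $1/\beta$ factor also circulates;
  since $1/\beta$ multiplies both thresholds identically it does not
  affect the ordering $\delta^*_c < \delta^*$, and we keep it for
  symmetry with the integrated threshold.

The comparative static that carries the psychology is
$d\delta^*/d\alpha = (\delta^*/k)\ln z$ with $z = x_0/x_k < 1$: the
threshold falls as curvature weakens (higher $\alpha$), and because
cancellation lowers $z$, the cancelled threshold moves *faster* in
$\alpha$. High-curvature (low-$\alpha$) agents are therefore predicted
to respond more strongly to partitioned framing — the interaction that
the panel logit layer tests.

```{r thresholds}
threshold_report(7, 8, common = 7, k = 7)
```

## Losses

Loss stimuli ("give up $3 today or give up $4 in a week", paid out of a
$10 endowment) are modelled through kept wealth: materially the choice
is between keeping $7 at the earlier date and keeping $6 at the later
date, so the *earlier* option now carries the larger payoff and
postponing the loss is never optimal for an agent with
$\beta \le 1, \delta \le 1$. Under partitioned framing the common kept
component (endowment minus the later loss) is cancelled, reducing the
choice to "keep the saved difference at the earlier date versus keep
nothing later". Three consequences, all tested:

* a deterministic agent never takes the later loss under partitioning;
* the framing gap for losses is weakly negative on every stimulus row;
* the utility at stake under partitioning, $\tfrac{1}{\alpha}\Delta^\alpha$
  for a saved difference $\Delta$, grows as $\alpha$ falls — the same
  curvature amplification as for gains.

This kept-wealth treatment deliberately avoids a prospect-theoretic loss
value function; asymmetric loss-domain curvature is out of scope.

## Choice noise

The model is deterministic. For analyses that need interior choice
probabilities (e.g. fitting a logit to simulated data), `decide()`
offers a logistic (Fechner) extension: the later-choice probability is
$\mathrm{logit}^{-1}(\Delta U / \tau)$ for a temperature $\tau > 0$ in
utility units, which equals $1/2$ exactly at $\delta = \delta^*$ and
converges to the deterministic rule as $\tau \to 0$. The default is
$\tau = 0$ everywhere. Where the vignette and tests use noise — the
panel-logit analyses — they use $\tau = 0.5$, chosen once against the
utility-gap scale of the binary stimuli (gaps of roughly 0.3 to 2
utils), so probabilities spread over (0.05, 0.99) without saturating.

## Synthetic populations

`sample_population()` draws $(\alpha_i, \beta_i, \delta_i)$ from
independent truncated normals whose location and scale default to the
empirical descriptive moments of structurally estimated time preferences
(0.8861/0.1255, 0.9977/0.1645, 0.9988/0.0068), truncated to the
admissible box $\alpha \in (0,1]$, $\beta > 0$, $\delta \in (0,1]$.
Because the upper bound 1 sits inside the mass of the $\alpha$ and
$\delta$ normals, the realised truncated means are lower than the
location parameters — about 0.846 for $\alpha$ and 0.994 for $\delta$
(`truncnorm_moments()` gives the analytic values, and the tests check
the sampler against them). No truncated normal on $(0,1]$ can have mean
0.9988 *and* sd 0.0068 (the distance to the bound caps the attainable
spread), so matching the printed moments exactly is impossible inside
the admissible box; we keep the printed values as location/scale and
document the realised moments instead.

Two things the generator deliberately does **not** emulate: real
respondents' choice inconsistency (beyond the optional logistic noise),
and any correlation between the three parameters. Passing simulation
tests therefore certify the model's internal logic, not distributional
realism of human data.

A consequence worth stating plainly: with $\delta$ concentrated near 1,
deterministic agents almost never prefer the earlier option on the
delayed-block ($t = 7$) gain rows, so both framing arms saturate at
100% later choices there and the simulated framing gap is exactly zero
rather than strictly positive. The strict gap materialises on the
immediate rows, where the present-bias tail keeps the baseline below
100%. The property tests are written accordingly (weak inequality on
every row, strict on the immediate $1-difference rows).

## The convex-time-budget estimator

Task fixtures mirror the 20-task design: 50 tokens split between an
earlier date ($t \in \{0, 7\}$ days) and a later date
($k \in \{35, 70\}$ days after it) at five price pairs. For $\alpha < 1$
the allocation has a closed form from the first-order condition; tests
check it against brute-force grid maximisation.

Estimation inverts the log-linearised first-order condition

$$\ln\tfrac{c_t}{c_{t+k}} = b_0 I_{t=0} + b_1 k + b_2 \ln\tfrac{a_{t+k}}{a_t},
\qquad
\hat\alpha = 1 + 1/b_2,\quad \hat\delta = e^{b_1/b_2},\quad
\hat\beta = e^{b_0/b_2},$$

fitted by least squares without an intercept on interior allocations
only. Design choices:

* **Corners are dropped and counted**, not epsilon-imputed: a corner
  allocation satisfies an inequality, not the interior condition, and
  imputation would distort the logs.
* **No clipping of $\hat\alpha$**: inconsistent responders can produce
  negative estimated curvature (a log-FOC slope in $(-1, 0)$); they are
  flagged and removed by `exclusion_filter()` before regressions, the
  standard drop rule.
* **Identification requires** at least 3 interior allocations spanning
  two $k$ values and both timing blocks; `estimate_population()` omits
  (and counts) subjects failing this, e.g. near-linear agents whose
  allocations all sit numerically on corners.

Noiseless allocations round-trip the generating parameters to $10^{-5}$
relative error across the identifiable box ($\alpha$ up to about 0.92
and $\delta$ down to about 0.985 with these horizons; beyond that the
optimum is within numerical resolution of a corner and the interior
condition carries no information). A censored-regression treatment of
corners is noted as future work.

## Statistical layer

* `pearson_chi2()` is the uncorrected statistic (the continuity-corrected
  version does not reproduce the published 10.68), with
  $w = \sqrt{\chi^2/N}$.
* `fisher_exact_2x2()` sums hypergeometric probabilities no larger than
  the observed table's.
* `mann_whitney()` defaults to the tie-corrected normal approximation
  without continuity correction (samples in these designs are far beyond
  exact-table range); `exact = TRUE` enumerates rank assignments for
  small untied samples and exists chiefly so the approximation can be
  audited against an exact reference.
* Power: the one-tailed df = 1 chi-square sizing uses the equivalent
  one-sided two-proportion z-test (the only coherent reading of a
  one-tailed chi-square specification); the two-sample t sizing iterates
  exact noncentral-t power. The published sizings (total 85 at
  $w = .27$; 45 per group at $d = .60$; 70 per group, hence 140 total,
  at $d = .48$) are all reproduced. The two-tailed chi-square sizing at
  $w = .23$ gives 149, slightly above the published 147, whose exact
  provenance is unknown; we report the noncentral-chi-square value.
* `reconstruct_counts()` recovers integer 2x2 tables from rounded
  percentages. Printed percentages alone can be ambiguous — at
  $N = 147$, 77.8%/52.0% admits two tables — so printed 95% CIs can be
  supplied as additional constraints; the Wilson score interval
  reproduces the published CI digits exactly and singles out the
  56/72-vs-39/75 table.
* `panel_logit()` is a subject-random-intercept logit fitted by adaptive
  Gauss-Hermite ML via `lme4::glmer` (the random intercept is the
  clustering correction; reported SEs are model-based Wald errors).
  `lnsig2u` is the log random-intercept variance. Average marginal
  effects multiply each coefficient by the sample-average logistic
  density of the linear predictor at a zero random intercept; averaging
  over the intercept distribution is available behind
  `panel_logit_ame(integrate = TRUE)`. A brute-force numerical
  integration of the random-intercept likelihood serves as the test
  oracle for the quadrature.
* `ols_moderation()` is ordinary least squares with
  condition-by-demographic interactions.
* No multiple-testing adjustment is applied anywhere, mirroring the
  unadjusted per-row tests of the replicated designs.

## The retirement menu

The nine-option menu offers an annual benefit starting at ages 62-70; in
the cancellation frame each option is the constant $9,400 base plus an
age-varying supplement. (The printed age-70 row is internally
inconsistent by $100 — baseline $16,600 versus $9,400 + $7,100 — and the
fixtures carry the printed values.) The menu task specifies no
valuation model, so the simulator's is an explicit extension: each agent
values the annual stream from start age to a horizon (default age 85,
configurable) by discounted CRRA utility with daily-compounded
$\delta$, cancels the base in the cancellation frame, and picks the
maximising age with ties to later. With lab-scale daily discount
factors, $\delta^{365}$ is severe (about 0.12 per year at the truncated
mean), so deterministic baseline agents claim at 62; the cancellation
frame still shifts the mean start age upward, which is the property the
design predicts and the tests check. Matching the published mean ages is
not a goal of the simulator — those depend on human valuation behaviour
the task does not pin down.

The weighted-mean-age summary of the *published* choice percentages is
reproduced exactly:

```{r wm}
f4 <- fixtures_experiment4()
weighted_mean_age(f4$start_age, f4$pct_cancellation)
weighted_mean_age(f4$start_age, f4$pct_baseline)
```

(The second value prints 66.06; the published text's 66.05 reflects
unrounded percentages.)

## Problem sizes and reproducibility

Every simulation is seeded, and identical configurations produce
byte-identical trial tables (`run_experiment()` also records a config
hash). The test suite uses populations of 250-600 agents for
property-level checks, 10,000 draws for the threshold-ordering sweep,
and 20,000 draws for sampler-moment checks — sizes at which the checked
inequalities and tolerances are comfortably resolved while the whole
suite runs in well under a minute.

## Known limitations

* Between-subject condition assignment means per-row simulated gaps are
  sample quantities; only their signs are guaranteed by theory.
* The estimator is exactly identified least squares; no standard errors
  for $(\hat\alpha, \hat\beta, \hat\delta)$ and no Tobit/ML treatment of
  corners.
* The logistic noise temperature is a free parameter with no empirical
  anchor in the replicated designs.
* Hyperbolic (non-quasi) discounting, magnitude effects, probability
  weighting and loss-aversion coefficients are out of scope.
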