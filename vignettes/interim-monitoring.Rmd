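---
title: "Interim monitoring with time-lagged outcomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interim monitoring with time-lagged outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gslag)
```

## The problem

In a two-arm randomized trial the primary outcome $Y$ of a subject is often
ascertained only after a subject-specific lag $T$, bounded by a maximum
follow-up $\mathcal{T}_F$ at which the outcome is known with certainty
(`pr(T <= TF) = 1`).  With staggered entry at calendar times $E_i$, an interim
analysis at calendar time $t$ observes, for each enrolled subject
($E_i \le t$), the censoring time $C_i(t) = t - E_i$, the observed time
$U_i(t) = \min\{T_i, C_i(t)\}$, the ascertainment indicator
$\Delta_i(t) = I\{T_i \le C_i(t)\}$, the outcome only when $\Delta_i(t) = 1$,
baseline covariates $X_i$, and the time-dependent covariate history up to
$U_i(t)$.  Because $T$ and $Y$ may be correlated (death is observed sooner
than survival to $\mathcal{T}_F$), the naive complete-case analysis is
biased, and the conventional fix — using only subjects with
$C_i(t) \ge \mathcal{T}_F$ — discards most of the accrued information.

## Estimators

The treatment effect $\beta$ is the last coordinate of $(\alpha, \beta)$ in a
marginal model fit by estimating equations $\sum_i M(Y_i, A_i; \alpha, \beta)
= 0$: difference of means, log relative risk, or a proportional odds model on
cumulative indicators $I(Y \le j)$ (so $\beta > 0$ favors lower categories —
mind the sign convention relative to other software).  The influence function
of the full-data estimator is $m_i = G\,M_i$ with $G$ the last row of the
inverse negated mean Jacobian.

Four interim estimators are provided:

* **TF-only** (`fit_tf_only`): the full-data fit restricted to subjects with
  $C_i(t) \ge \mathcal{T}_F$.
* **IPWCC** (`fit_ipwcc`): the weighted fit over all complete cases, each
  weighted by $1/\hat{K}_t\{U_i(t), A_i\}$ where $\hat{K}_t(\cdot, a)$ is the
  arm-specific Kaplan-Meier estimate of the censoring survival
  $pr\{C(t) \ge u\}$.  For a binary outcome this is algebraically the log
  ratio of treatment-specific Kaplan-Meier event probabilities at
  $\mathcal{T}_F$ (a tested identity).  Arm-specific censoring weights are
  the default: they never hurt and typically help, even though randomization
  makes the true censoring distribution arm-free.
* **AIPW1 / AIPW2** (`fit_aipwcc`): a one-step augmentation.  Step 1 forms
  the per-subject "dependent variable"
  $\hat{Y}_i(t) = \Delta_i m_i / \hat{K}_t(U_i, A_i) + \int_0^t
  d\hat{M}_{ci}(u, A_i)\, \hat\mu(m, u, A_i)/\hat{K}_t(u, A_i)$,
  whose mean is zero at the Step-1 solution.  Step 2 regresses it by OLS on
  "covariates" $(A_i - \hat\pi_t) f_m(X_i)$ (AIPW1) plus, per arm, martingale
  integrals of at-risk-centered basis functions
  $h_\ell\{u, X, \bar{L}(u)\}$ (AIPW2), and updates
  $\hat\beta(t) = \hat\beta_{\rm init}(t) - \overline{\rm Pred}$, with
  $SE = n(t)^{-1} \{\sum_i (\hat{Y}_i - {\rm Pred}_i)^2\}^{1/2}$.

The optimal augmentation functions are conditional expectations that are
unknown in practice; the package follows the linear-basis approximation and
defaults to using each covariate component as a basis function
(`default_basis`), which reproduces the benchmark simulation setup.  The
least-squares step is performed once (a one-step update, not iterated), and
$m_i$ in Step 2 is evaluated at $(\hat\alpha(t), \hat\beta_{\rm init}(t))$,
not re-evaluated at the updated $\hat\beta(t)$.

## Numerical conventions that matter

* **Censoring-survival evaluation.** $\hat{K}_t(u)$ estimates
  $pr\{C \ge u\}$, so evaluation at a subject's own $U_i$ multiplies only
  jumps strictly before $U_i$.  Ties between an ascertainment and a censoring
  event treat the ascertainment as occurring first (the complete case stays
  in the censoring risk set).  In the simulated scenarios censoring is
  continuous, so these conventions matter only for real data.
* **Hazard increments.** The cumulative censoring hazard is reported as
  $-\log \hat{K}_t(u)$, its continuous-time definition.  For the *discrete*
  martingale increments $d\hat{M}_{ci}(u) = dN_{ci}(u) -
  d\hat\Lambda_c(u) \mathcal{Y}_i(u)$ the package defaults to the
  product-limit-consistent (Nelson-Aalen) increments $d_j / Y_j$, under which
  the estimated martingale sums vanish exactly within each arm, the
  dependent variable has exactly zero mean at the Step-1 solution, and the
  no-censoring equivalences are bit-for-bit.  The asymptotically equivalent
  alternative $-\log(1 - d_j/Y_j)$ (differences of $-\log \hat{K}$) is
  available as `censoring_km(hazard = "neglog-km")`.  A related point: the
  arm-wise sums of the *centered* time-dependent augmentation columns are
  mean-zero noise, not an exact identity — the compensator part cancels by
  centering, but the $dN$ part contributes the censored subject's deviation
  from the at-risk average; tests therefore check a studentized mean rather
  than machine zero.
* **Integrals.** All martingale integrals are exact finite sums over
  censoring jump times; no quadrature grid is introduced.
* **Solver.** The two 2-parameter models are solved in closed form.  The
  proportional-odds equations (working independence by default, as in the
  benchmark studies; full multinomial covariance available for cross-checks)
  use Newton iteration with analytic Jacobian, step-halving, and a
  numeric-Jacobian fallback; convergence demands
  $\lVert \text{equations} \rVert_\infty \le 10^{-9} \times$ sample size.
  Separation or an empty arm raises an error advising a later analysis time.
* **Degenerate interims.** The method requires $pr\{C(t) > \mathcal{T}_F\} >
  0$; the first analysis should come at least $\mathcal{T}_F$ after start.
  A zero estimated censoring survival at an ascertained observation time is
  an error (an infinite weight), not a truncation.

## Information accounting and boundaries

Monitoring needs an information fraction per look.  Under fixed-sample
monitoring the TF-only estimator uses $n_A(t)/n_{\max}$.  For the weighted
estimators the package uses the **effective sample size**
$n_{ESS}(t) = \widehat{\rm var}\{m\} / SE\{\hat\beta(t)\}^2$, with
$\widehat{\rm var}\{m\}$ the inverse-weighted mean of squared influence
values — residualized on the *baseline* augmentation columns by weighted
least squares for both AIPW1 and AIPW2 (one formula serves both, as defined).
Influence values there are evaluated at $(\hat\alpha(t), \hat\beta(t))$ with
the Step-1 $G$ row reused.  $n_{ESS}$ lies between $n_A(t)$ and $n(t)$ in
simulation, and equals $n$ exactly at the final analysis for the IPW
estimator (for the augmented ones the two sides evaluate $m$ at
$\hat\beta_{\rm init}$ vs $\hat\beta$, so equality is only near-exact; the
Monte Carlo driver pins the final fraction to 1, its value by definition).
Fractions can be non-monotone under estimator noise; monitoring bumps them
by $10^{-6}$ with a warning.  Under information-based monitoring the
fraction is $SE^{-2}/MI$ with
$MI = \{(z_{\alpha/2} + z_\gamma)/\beta_A\}^2 \cdot IF$; the inflation
factor is a user input, and fractions above 1 are clipped with a warning
(the behaviour at a late interim under information monitoring is not
otherwise specified anywhere authoritative, so clipping was the design
choice).

Boundaries use Lan-DeMets error spending with the two standard shapes,
O'Brien-Fleming-type $2\{1 - \Phi(z_{\alpha/2}/\sqrt{s})\}$ and Pocock-type
$\alpha \ln\{1 + (e - 1)s\}$ — the forms that reproduce the published
benchmark boundary tables.  One-sided plans spend all of $\alpha$ on one
tail.  The recursion propagates the continuing-region subdensity of the
score process on a grid (4000 points per stage by default, trapezoidal
integration, bisection to $10^{-6}$; validated against a multivariate-normal
oracle to about $10^{-5}$).  The Monte Carlo driver recomputes boundaries per
replicate from the realized fraction path with a coarser 301-point grid
(agreement with the default grid is better than $10^{-4}$ on the z scale).
An incremental spend below $10^{-12}$ yields an `Inf` boundary with a
warning.  Futility boundaries are out of scope; monitoring is efficacy-only.

## The synthetic trials

`generate_trial` implements three benchmark generative scenarios that fix
the package's "stated world"; none of their constants are tuning knobs.

1. **Ordinal** (`n_max = 602`, accrual over 240 days,
   $\mathcal{T}_F = 90$, looks at 150/195/240/285, final at 330): a latent
   $\Upsilon \sim U(0,1)$ is transformed in the treated arm by the inverse
   of $u \mapsto u e^\beta / (1 - u + u e^\beta)$ so a proportional odds
   model holds exactly; six categories are cut at
   $(0, .12, .35, .52, .62, .67, 1)$.  Death (category 6) is ascertained at
   a uniform death time (U(0,30) control, U(20,50) treated); everything else
   at 90 days.  Covariates: $X \sim N\{1.5(\Upsilon - .5), 1\}$, a
   hospital-discharge indicator $L_1(u) = I(\mathcal{W} < u)$ and expected
   days out of hospital $L_2(u) = (90 - \mathcal{W}) L_1(u)$.  $L_1$ is the
   literal indicator formula even though it reads as "out of hospital";
   the accompanying prose description has the opposite direction, and the
   formula is what reproduces the benchmark construction.  Covariate paths
   are truncated at the ascertainment time.
2. **Binary** (`n_max = 900`): same latent machinery;
   $Y = I(\text{latent} \ge 0.67)$ (control rate 0.33; treated 0.247 under
   odds ratio 1.5, implying log relative risk $-0.289$).
3. **Continuous** (`n_max = 300`, accrual 156 weeks, $\mathcal{T}_F = 52$,
   looks 104/130/156/182, final 208): a linear mixed model at visit weeks
   (0, 4, 12, 24, 52) with random intercept/slope covariance
   $\mathrm{vech}(D) = (80, -0.5, 0.08)$, residual SD 4.5, group means
   (65, 60, 55, 49) over a 4-level covariate with probabilities
   (.4, .3, .2, .1), and arm-specific slopes $\xi_1 = -0.3$,
   $\xi_2 = \xi_1 + \beta/52$.  The outcome is the week-52 value; the
   baseline covariate is the week-0 value (the group label is deliberately
   withheld, as it would be in practice); the time-dependent covariate is
   the last observed measurement.  Here $T \equiv \mathcal{T}_F$, so the
   TF-only and IPWCC point estimates coincide.

RNG discipline: each subject consumes a fixed block of uniform draws
(normals by inversion), so the same seed yields the same early subjects
regardless of `n_max`.

What a green simulation test does *not* establish: the generators use
completely random (entry-time-independent) enrollment, continuous censoring
without ties, correct model specification, and 1:1 randomization.  Real
trials with drifting covariate distributions over accrual, tied event times,
or covariate-dependent censoring are outside what these tests exercise
(covariate-dependent censoring models are an explicit non-goal).

## Monte Carlo driver

`run_monte_carlo` replicates whole trials, fits any subset of the four
estimators at any subset of looks (Step 1 is shared between IPW and the two
augmented estimators at a look), and applies per-replicate monitoring with
boundaries recomputed from that replicate's realized fraction path — the
spending approach, which is how a data-dependent fraction would be used in
practice.  Replicates are independent units keyed by (master seed, replicate
index), so results do not depend on execution order; failures are caught,
counted, and reported rather than fatal.  The reference operating
characteristics in the acceptance tests use 2000 replicates (the published
tables use 10000) to stay within a practical time budget; tolerances are
correspondingly Monte Carlo-aware.

## Worked example

```{r example, eval = FALSE}
cfg <- scenario_config("ordinal", beta = log(1.5))
full <- generate_trial(cfg, seed = 11)
snap <- interim_data(full, 150)
po <- outcome_model("proportional_odds", n_categories = 6)

tf <- fit_tf_only(snap, po)
a2 <- fit_aipwcc(snap, po)
information_fraction(tf, n_max = cfg$n_max)
information_fraction(a2, n_max = cfg$n_max, interim = snap)

monitor_trial(c(2.496, 2.765, 2.445, 2.828),
              c(0.257, 0.432, 0.611, 0.809),
              spending_plan(0.025, "obf"))
```

## Known limitations

* Two arms only; no conditional-on-covariates inference under
  entry-time/covariate dependence; no sample-size re-estimation; no
  hazard-ratio endpoints (they lack a $\mathcal{T}_F$).
* The optimal augmentation is approximated by user-chosen linear bases; a
  poor basis costs efficiency, never validity.
* The independent-increments property underpinning the boundary machinery is
  verified empirically by the Monte Carlo covariance diagnostic, not proved
  within the package.
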