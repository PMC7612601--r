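---
title: "Response-adaptive roll-out in stepped-wedge cluster randomized trials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-adaptive roll-out in stepped-wedge cluster randomized trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raswcrt)
```

## The design problem

A stepped-wedge cluster randomized trial (SW-CRT) enrols $C$ clusters for
$P$ time periods and rolls an intervention out one-way: each cluster starts
in the control condition and, once switched, stays in the intervention. The
roll-out is encoded in a binary allocation matrix $X = \{X_{ij}\}$, with
$X_{ij} = 1$ when cluster $i$ is in the intervention condition in period
$j$, and rows constrained to be monotone (no switch-back). Conventionally
$X$ is fixed before the trial — which commits, pre-trial, to giving every
cluster the intervention whether or not the accumulating data support it.

`raswcrt` implements a response-adaptive alternative: at a prespecified set
of interim analyses (after periods $p_1 < \dots < p_L \le P - 1$), the
planned roll-out for the remaining periods may be replaced by any
*admissible continuation* — a matrix agreeing with the realized allocations
in periods $1..p$ whose already-switched clusters remain switched. The
continuation is chosen to balance statistical information (power) against
the desire to expose more cluster-periods to an apparently effective
intervention, or fewer to an apparently ineffective one.

## Analysis model

Each cluster-period contributes $m$ measurements, from new individuals each
period (cross-sectional) or from the same $m$ individuals throughout
(closed cohort). Responses follow the linear mixed model

$$Y_{ijk} = \beta_j + \theta X_{ij} + c_i + \pi_{ij} + s_{ik} +
\epsilon_{ijk},$$

with period fixed effects $\beta_j$, intervention effect $\theta$, and
independent normal random effects: cluster $c_i \sim N(0, \sigma^2_c)$,
cluster-period $\pi_{ij} \sim N(0, \sigma^2_\pi)$, individual
$s_{ik} \sim N(0, \sigma^2_s)$ (closed cohorts; identically zero for
cross-sectional sampling) and residual
$\epsilon_{ijk} \sim N(0, \sigma^2_\epsilon)$. The variance components are
treated as **known** throughout — the analysis is generalized least squares
(GLS) under the true covariance, with no REML step. This matches the
framework's use of the design-determined information and keeps the interim
Wald statistic exactly pivotal under the null; the consequences of
estimating the components instead are deliberately out of scope.

With data through period $p$ stacked as $Y_p$, the GLS estimate is
$\hat\theta_{p|X} = (D'\Sigma^{-1}D)^{-1}D'\Sigma^{-1}Y_p$ (last
coordinate), the Wald statistic $Z_{p|X} =
\hat\theta_{p|X}/\mathrm{SE}$, and the *information*
$I_{p|X} = 1/[(D'\Sigma^{-1}D)^{-1}]_{qq}$ — a pure design quantity,
computable before any data exist. The final analysis rejects the one-sided
null $H_0 : \theta \le 0$ when $Z_{P|X_P} > \Phi^{-1}(1-\alpha)$.

Two computational representations are provided. The default collapses each
cluster-period to its mean, whose per-cluster covariance block is
$\sigma^2_c + [\text{closed}]\,\sigma^2_s/m$ off the diagonal plus
$\sigma^2_\pi + \sigma^2_\epsilon/m$ on it; for equal $m$ this reduction is
exact — the collapsed and observation-level GLS agree on $\hat\theta$, $Z$
and $I$ to solver precision, a property the test suite verifies directly.
The observation-level path is retained for that validation and for users
who want it. The fixed-effect parameterization uses $p$ period indicators
and no separate intercept (the model has none; adding one would make the
design matrix rank-deficient).

## The adaptation rule

At an interim after period $p$ with current matrix $X_p$ and statistic
$Z = Z_{p|X_p}$, every admissible continuation is scored by

$$s(X') = w\,\frac{I_{P|X'}}{\max_{X''} I_{P|X''}} +
(1-w)\,\frac{b(X')}{\max_{X''} b(X'')}, \qquad w \in [0,1],$$

and the maximizer becomes the planned matrix for periods $p+1, \dots, P$.
The benefit score $b$ is the probability mass that a binomial places on the
candidate's roll-out speed: with $n$ clusters still in control there are
$N = (P-p)\,n$ *modifiable* cluster-periods, the candidate spends $S$ of
them in the intervention, and

$$b(X') = \Pr(S^* = S), \qquad S^* \sim
\mathrm{Bin}\!\left(N,\; \Phi\!\left[\frac{Z - \eta}{\gamma\,(1 - p/P)}
\right]\right).$$

The success probability maps the interim evidence onto a preferred roll-out
speed: as $Z \to \infty$ it tends to 1 and the immediate-full-switch
continuation is selected; as $Z \to -\infty$ the frozen roll-out wins.

Tunables, defaults, and their meaning:

* `w` (default 1/2) — weight on information; `w = 999/1000` essentially
  fixes the roll-out at the information-maximizing continuation regardless
  of the data, while small `w` lets the benefit term dominate. The extremes
  0 and 1 are allowed but flagged, since they leave ties between designs
  with equal $I$ or equal $b$ unbroken by the data.
* `eta` (default 0, on the $Z$ scale) — evidence threshold; larger values
  slow the roll-out by shrinking the success probability.
* `gamma` (default 2.5, dimensionless scale, $> 0$) — larger values pull
  the success probability toward 1/2, favouring steadier roll-outs.
* `restriction` — `"none"`, or `"must_complete_rollout"` to force every
  cluster into the intervention by period $P$ (removing "never" from the
  admissible switch times); an arbitrary `admissible` predicate can prune
  further.

The defaults (`w = 1/2`, `eta = 0`, `gamma = 2.5`, interims after periods 3
and 6 for the 20-cluster reference scenario) are the reference policy of
the simulation study the package reproduces; they gave monotone-increasing
allocation with little error-rate inflation there, and are a starting
point, not a recommendation — the package exists so that these parameters
can be chosen by simulation for the design at hand.

## Enumeration and exchangeability

A continuation is determined by a *multiset* of new switch times over
$\{p+1, \dots, P, \text{never}\}$ for the $n$ control clusters, so the
candidate count is the combinations-with-repetition number
$\binom{n + K - 1}{n}$, $K = P - p + 1$. Under the exchangeable-cluster
model every design quantity ($I$, $S$, hence $b$ and $s$) depends on a
matrix only through its switch-time histogram, so scoring operates on
these equivalence classes; the scored multiset is mapped to a concrete
matrix by a fixed convention — control clusters in ascending row order
receive the new switch times in nondecreasing order. Because the selection
rule sees the data only through the scalar $Z$, the operating
characteristics are invariant to this convention; fixing it buys exact
reproducibility.

Information is assembled per histogram as the weighted sum of
per-switch-time single-cluster cross-product blocks
$D_t'V^{-1}D_t$, and cached: within a simulation the candidate set and its
information vector are computed once per interim state and reused by every
replicate and every effect size (the first interim of the 20-cluster
scenario has $\binom{20}{14} = 38{,}760$ candidates; caching reduces each
replicate's scoring to a binomial-pmf lookup and a vectorized argmax).

## Numerical choices

* **Singularity.** $D'\Sigma^{-1}D$ with reciprocal condition number below
  $10^{-12}$ raises an explicit error rather than falling back to a
  pseudo-inverse, which would silently misreport information. This also
  covers the degenerate interim with no intervention exposure (the
  exposure column is then collinear with the period effects): the interim
  statistic is undefined and the error says so, rather than defaulting
  $Z = 0$.
* **Benefit underflow.** $\Phi[(Z-\eta)/\cdot]$ underflows for
  $|Z| \gtrsim 8$; the binomial pmf is evaluated in log space and the
  maximum subtracted before exponentiation, so the normalized ratio
  $b/\max b$ stays well-defined at any $Z$.
* **Ties.** Exact score ties are measure-zero in $Z$ but possible at
  $w \in \{0, 1\}$; they are broken toward larger information, then by the
  earlier position in the enumeration order (ascending lexicographic order
  of the sorted switch-time tuple, "never" last).
* **Solves.** All linear algebra goes through Cholesky factorizations of
  the small per-cluster blocks; $\Sigma$ is never formed or inverted
  densely.

## The synthetic-data generator

Monte-Carlo replicates draw all random effects **up front**, before any
allocation decision, at cluster-period-mean granularity: the mean noise of
cluster $i$ in period $j$ is $c_i + \pi_{ij} + [\text{closed}]\,\bar s_i +
\bar\epsilon_{ij}$ with $\bar s_i \sim N(0, \sigma^2_s/m)$ shared across
periods and $\bar\epsilon_{ij} \sim N(0, \sigma^2_\epsilon/m)$. Responses
are then the noise plus $\theta X_{ij}$, so the adaptive procedure can
influence what is observed only through the fixed part — decisions depend
on the data only through $Z$, as the framework requires. Period effects
$\beta_j$ are set to zero in generation: with known covariance the GLS
Wald statistic's distribution is invariant to them. Mean-level generation
is distributionally exact for equal $m$ (verified against observation-level
generation in the tests) and cuts the number of random draws by a factor
of $m$.

What the generator does *not* emulate about real trials — and hence what
passing simulations do not establish: unequal or time-varying cluster
sizes, missing cluster-periods, attrition in closed cohorts, non-normal or
discrete outcomes, decaying within-cluster correlation, mis-specified or
estimated variance components, and calendar-time confounding beyond the
linear period effects. The framework itself only requires an interim
effect estimate, but every operating characteristic reported here is
conditional on the model above being true.

Replicates use independent L'Ecuyer-CMRG substreams derived from the
scenario seed, so results are bit-reproducible and independent of
execution order. Three built-in scenarios (`tds("TDS1")`, `"TDS2"`,
`"TDS3"`) cover a 20-cluster cross-sectional design, a small 4-cluster
cross-sectional design used for the worked example, and a 12-cluster
closed-cohort design; their dimensions, variance components, error-rate
targets and roll-outs are documented in `?tds`.

## Problem sizes

The reference simulation study behind the built-in scenarios used 100,000
replicates per grid point. The package defaults to 10,000 replicates —
enough to estimate error rates to about a quarter of a percentage point
(Monte-Carlo standard errors are attached to every summary) while keeping
a full scenario evaluation in the minutes range on a single core; `n_reps`
scales this freely. The bundled acceptance script evaluates the 20-cluster
reference policy at three effect sizes with 10,000 replicates each.

## Known limitations

* Variance components are assumed known; no small-sample or
  degrees-of-freedom corrections are applied, so the modest type-I
  inflation that adaptation induces (about 5.6% at a nominal 5% in the
  20-cluster reference scenario, as the acceptance suite measures) is
  reported, not corrected.
* The final estimator ignores the adaptive selection; for benefit-weighted
  policies ($w \ne 999/1000$) it carries a small bias that the operating
  characteristics quantify but the package does not remove.
* Open-cohort sampling, early stopping, sample-size re-estimation,
  incomplete designs and non-continuous outcomes are out of scope.
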