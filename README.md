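# raswcrt — response-adaptive stepped-wedge cluster randomized trials

Stepped-wedge cluster randomized trials (SW-CRTs) roll an intervention out
across clusters one-way — once a cluster switches from control to
intervention it never switches back — and conventionally commit, before any
data are seen, to giving every cluster the intervention on a fixed
schedule. When there is genuine uncertainty about the intervention's
effect (and especially when it carries cost or safety concerns), that
pre-trial commitment is hard to defend. `raswcrt` is for trial
statisticians who want to *adapt the roll-out instead*: at prespecified
interim analyses, the planned allocation matrix is replaced by the
admissible continuation that best balances statistical power against
patient benefit, and the package quantifies — by simulation — what that
adaptivity costs and buys.

## The method in brief

Responses follow the linear mixed model
`Y_ijk = β_j + θ X_ij + c_i + π_ij + s_ik + ε_ijk`
with known variance components (cluster `σ²_c`, cluster-period `σ²_π`,
individual `σ²_s` for closed cohorts, residual `σ²_ε`); the intervention
effect θ is estimated by generalized least squares, giving after period p
the Wald statistic `Z_p` and the design-only information
`I_p = 1/Var(θ̂_p)`. At an interim after period p, each admissible
continuation X′ (past columns frozen, no switch-back) is scored by

```
s(X′) = w · I_P|X′ / max I  +  (1 − w) · b(X′) / max b
```

where `b(X′)` is the probability that `Bin(N, Φ[(Z − η)/(γ(1 − p/P))])`
equals the number S of modifiable cluster-periods X′ spends in the
intervention (N = modifiable cluster-periods in total). The s-maximizing
continuation is adopted; the final analysis rejects `H0: θ ≤ 0` when
`Z_P > Φ⁻¹(1 − α)`. Monte-Carlo machinery estimates the resulting operating
characteristics: rejection probability (type-I error, power), the average /
spread / pmf of the proportion of cluster-periods spent in the
intervention (EACP, ESDCP), and the bias and RMSE of the final estimate.

## Worked example

The built-in 4-cluster, 5-period scenario (`tds("TDS2")`) plans one
cluster switch per period. Suppose an interim analysis after period 3
finds `Z = 1` — mild evidence in favour of the intervention. Scoring the
six admissible continuations with the default policy (w = 1/2, η = 0,
γ = 2.5):

```r
library(raswcrt)
sc <- tds("TDS2")
score_candidates(sc$design$X_init, p = 3, Z = 1, sc$design, sc$vc, sc$policy)
#>                    matrix S   I        b     s selected
#> 1 01111,00111,00011,00011 4 170 0.501067 0.878     TRUE
#> 2 01111,00111,00011,00001 3 215 0.377952 0.856    FALSE
#> 3 01111,00111,00011,00000 2 222 0.106907 0.601    FALSE
#> 4 01111,00111,00001,00001 2 205 0.106907 0.563    FALSE
#> 5 01111,00111,00001,00000 1 225 0.013440 0.513    FALSE
#> 6 01111,00111,00000,00000 0 188 0.000634 0.420    FALSE
```

Each row is one continuation in compact form (rows of the allocation
matrix, `1` = intervention): `S` counts the modifiable cluster-periods it
spends in the intervention, `I` is its end-of-trial information, `b` the
benefit probability at Z = 1, and `s` the combined score. The mild
positive evidence selects the fastest roll-out (both remaining control
clusters switch at period 4; final intervention proportion 55%), at an
information cost — 170 versus the 225 achievable — that the benefit term
outweighs at this Z. `required_m(sc$design, sc$vc)` returns `70`, the
per-cluster-period sample size this design needs for 90% power at
θ = 0.2 with one-sided α = 0.05.

Operating characteristics of the 20-cluster reference scenario under the
default policy, at twice the design effect:

```r
oc <- sw_simulate(tds("TDS1", theta = 0.48, n_reps = 2000, seed = 1))
oc
#> Operating characteristics over 2000 replicates (theta = 0.48 ):
#>   ERP   0.9960 (MC SE 0.0014)
#>   EACP  67.85% (MC SE 0.08 pp)
#>   ESDCP 3.54 pp
#>   EB    +0.01874 (MC SE 0.00286)
#>   ERMSE 0.12923
```

A strongly effective intervention speeds the roll-out up: 67.9% of
cluster-periods end up in the intervention condition versus 54.4% under
the fixed design, with small spread and a modest upward bias in the final
estimate — the quantities a design team weighs when tuning w, η, γ and the
interim schedule via `sw_sweep()`.

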