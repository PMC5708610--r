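# coopeq

Cooperation in laboratory games sits awkwardly between two classic
predictions: one-shot rationality says nobody should cooperate in a
Prisoner's Dilemma (PD) or return anything in a Trust Game (TG), yet human
subjects do both — and do much more of it after a short in-lab socialization
stage. `coopeq` implements, end to end, the two models that bracket this
behaviour and the statistics that connect them to session data:

* **Logit quantal response equilibrium (QRE).** Players choose actions with
  probability proportional to `exp(λ·u)`; the precision `λ` interpolates
  between uniform play (`λ = 0`) and best response (`λ → ∞`). For the
  one-shot PD with prizes `(T, R, P, S) = (10, 5, 1, 0)` the symmetric QRE
  solves `p = 1 / (1 + exp(λ(4p + 1)))`, invertible in closed form:
  `λ = ln((1 − p)/p) / (4p + 1)`. For the sequential TG the package chains
  logit responses for gratefulness `p₂(k, n) ∝ exp(λ(3k − n))` and trust
  `p₁(k) ∝ exp(λ u₁(k))`, forecasts average trust and gratefulness, and fits
  `λ` to observed session averages by nearest forecast (Euclidean).
* **The iterated PD in memory-one (Markov) strategies.** A strategy is a
  pair `(α, γ)`: the probability of cooperating after the partner's
  defection (tolerance) and after cooperation (reciprocity). Stationary
  cooperation rates have a closed form, and the symmetric totally mixed Nash
  equilibria form the conic
  `5α² + 9γ² − 14αγ + 14α − 10γ + 1 = 0`, running from tit-for-tat `(0, 1)`
  to the maximum-tolerance point `(7 − √45, (5 + 7α*)/9) ≈ (0.3, 0.8)`.
  Session estimates `α̂ = N_tolerant/N_default`, `γ̂ = N_recoop/N_coop` are
  compared to the curve by signed same-`γ` tolerance distance and by the
  percent payoff a player loses by deviating in tolerance — the
  ε-equilibrium measure.

The package ships the published summary tables of eight 12-subject sessions
as plain-CSV fixtures, round-log readers/writers, seeded simulators of the
experimental design (random re-pairing before socialization, fixed groups of
four after), parameter-recovery harnesses, and ggplot2 figures
(`plot_equilibrium_curve()`, `autoplot()` methods).

## Worked example

Estimate memory-one strategies from the packaged conditional-move counts and
measure each session-stage point against the equilibrium curve:

```r
library(coopeq)

est <- estimate_strategy(coopeq_fixture("table5"))
dev <- deviation_report(dplyr::mutate(est, alpha = alpha_hat, gamma = gamma_hat))
dplyr::select(dev, date, stage, alpha_hat, gamma_hat, alpha_curve, distance, deviation_pct)
#> # A tibble: 16 × 7
#>   date       stage  alpha_hat gamma_hat alpha_curve distance deviation_pct
#>   <chr>      <chr>      <dbl>     <dbl>       <dbl>    <dbl>         <dbl>
#> 1 15.09.2015 before     0.104     0.226     0.0714    0.0327        0.0349
#> 2 21.09.2015 before     0.139     0.105    -0.00377   0.142         0.916
#> 3 28.09.2015 before     0.329     0.5       0.217     0.112         0.251
#> 4 05.10.2015 before     0.228     0.143     0.0202    0.208         1.68
#> 5 09.10.2015 before     0.286     0.419     0.178     0.108         0.262
#> 6 12.10.2015 before     0.368     0.481     0.208     0.160         0.511
#> # ℹ 10 more rows
```

Reading row 1: in the 15.09.2015 session before socialization, subjects
tolerated defection 10.4% of the time and reciprocated cooperation 22.6% of
the time; the equilibrium with the same reciprocity has tolerance 7.1%, so
the session sits 0.033 to the right of the curve, and a player deviating by
that much loses only 0.03% of the equilibrium payoff — an ε-equilibrium for
a tiny ε. (Row 2 carries a negative `alpha_curve`: with `γ < 1/9` the curve
point is a formal extension outside the unit square, flagged by a warning.)

Fit the Trust Game precision to a session's observed averages:

```r
fit_lambda_tg(trust = 5.38, gratefulness = 3.17)
#> Trust Game logit-QRE fit
#>   observed:  trust 5.38, gratefulness 3.17
#>   lambda:    0.1500  (searched [0, 2])
#>   forecast:  trust 4.39, gratefulness 3.63  (distance 1.088)
```

Simulate the pre-socialization design at the maximum-tolerance equilibrium
and check the stationary prediction `p = α/(1 + α − γ) = 0.6`:

```r
log <- simulate_pd_session(n_players = 12, alpha = 0.3, gamma = 0.8,
                           rounds = 1000, seed = 7)
cooperation_level(log)
#> # A tibble: 1 × 4
#>   session_id stage  n_moves coop_rate
#>   <chr>      <chr>    <int>     <dbl>
#> 1 sim01      before   12000     0.594
```

`run_full_analysis()` chains all of the above over the fixtures (or over
your own round/trust logs) and returns the per-table replicas plus a summary
of the headline statistics; `glance()` and `autoplot()` work on the result.

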