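---
title: "Cooperation equilibria: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperation equilibria: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopeq)
```

coopeq analyses cooperation in two classic laboratory games — the iterated
Prisoner's Dilemma (PD) and the Trust Game (TG) — played by small groups of
human subjects before and after an in-lab socialization stage. This vignette
is the package's own account of the models it implements, the estimators that
connect them to data, and the numerical and design choices behind them.

## The games

In the PD each of two players either cooperates or defects. With the payoff
ordering $T > R > P > S$ (here $10 > 5 > 1 > 0$; see `pd_payoffs()`),
defection strictly dominates, yet mutual cooperation beats mutual defection —
the unique one-shot Nash equilibrium is mutual defection. In the TG, a
grantor passes an integer stake $k \in \{0,\dots,10\}$, the stake triples in
transit, and the grateful player returns $n \in \{0,\dots,3k\}$; backward
induction predicts $n = 0$ and hence $k = 0$. Observed behaviour departs from
both predictions, and the size and structure of the departure is what the
package quantifies.

The sessions have a fixed structure: twelve anonymous players re-paired at
random each round ("before" socialization), then fixed groups of four
("after"). The two stages are labels carried on every record; the analysis
treats them symmetrically.

## Quantal response equilibrium in the one-shot PD

Under logit quantal response with precision $\lambda \ge 0$, action
probabilities are proportional to $e^{\lambda u}$ for expected payoff $u$
(`logit_choice()`). In the symmetric one-shot PD, if everyone cooperates with
probability $p$, the payoff gap between defection and cooperation is
$u_D - u_C = 4p + 1$ for the default prizes, so a QRE solves the fixed point

$$p = \frac{1}{1 + e^{\lambda (4p + 1)}}.$$

The right-hand side is strictly decreasing in $p$, so the root is unique;
`qre_cooperation_prob()` brackets it by bisection on $[0,1]$ (no derivatives,
guaranteed convergence; 200 halvings, bracket tolerance $10^{-15}$). The map
is invertible in closed form, which is how an observed cooperation rate is
turned into a precision estimate (`lambda_from_cooperation()`):

$$\lambda = \frac{\ln\!\big((1-p)/p\big)}{4p + 1}.$$

At $p = 0.5$ the precision is zero (uniform, "chaotic" play); $p > 0.5$
yields $\lambda < 0$, which the function reports with a warning because the
QRE error model cannot rationalise majority cooperation in a PD — exactly
the situation in the post-socialization stages, and the reason the package
also implements the repeated-game model below. Both directions support
arbitrary `pd_payoffs()`; the $4p+1$ form is the default-payoff
specialisation of $u_D(p) - u_C(p)$.

A reproduction caveat worth stating openly: inverting a cooperation rate
that was itself rounded to three decimals can move $\lambda$ by up to about
$0.005$ (the inversion's slope near $p \approx 0.12$ is roughly $-10$), which
is more than the last printed digit of a precision column. The package always
reports the exact inversion of whatever input it is given.

## Quantal response equilibrium in the Trust Game

The sequential TG model chains three logit responses at a single precision
$\lambda$ (`gratitude_distribution()`, `expected_grantor_payoff()`,
`trust_distribution()`):

$$p_2(k, n) \propto e^{\lambda (3k - n)}, \qquad
  u_1(k) = 10 - k + \sum_{n=0}^{3k} n\, p_2(k, n), \qquad
  p_1(k) \propto e^{\lambda u_1(k)},$$

and forecasts average trust and gratefulness as the expectations
$k(\lambda) = \sum_k k\, p_1(k)$ and
$n(\lambda) = \sum_k p_1(k) \sum_n n\, p_2(k,n)$
(`forecast_trust_gratefulness()`). At $\lambda = 0$ these are exactly 5 and
7.5; as $\lambda \to \infty$ both collapse to the backward-induction zeros.

`fit_lambda_tg()` matches the forecast pair to a session's observed averages
$(k^\*, n^\*)$. The matching criterion is a genuine design choice — the
source analysis states only "as close as possible" — and the package uses
the Euclidean distance on the $(k, n)$ plane, for three reasons: both
coordinates are in points on comparable scales (0–10 and 0–30 but observed
within 0–7), the forecast path is a smooth curve in that plane so the nearest
point is well defined, and fits under this metric reproduce the published
fitted precisions to within $\pm 0.01$ and the published forecast pairs to
within $\pm 0.01$ — strong evidence it is the metric actually used. The
objective is scanned on a grid of step $10^{-3}$ over $[0, 2]$ (the fitted
values for these data all lie below $0.4$; the range and step are arguments)
and refined with `stats::optimize()` in the winning cell; exact grid ties
resolve to the smaller $\lambda$. One subtlety the fitted object makes
visible: published forecast columns correspond to the *unrounded* fitted
precision, so forecasts evaluated at a 2-dp rounded precision can differ in
the second decimal, noticeably so where the forecast curve is steep (small
$\lambda$).

Averages over rounds may violate the single-round feasibility bound
$n \le 3k$, so the fit only requires $n^\* \ge 0$.

## The iterated PD in memory-one strategies

A memory-one (Markov) strategy reacts only to the partner's previous move:
cooperate with probability $\gamma$ after cooperation (reciprocal
cooperation) and $\alpha$ after defection (tolerance to defection). For a
pair of such strategies the joint play is a four-state Markov chain
(`transition_matrix()`); in its stationary regime the cooperation marginals
solve a linear pair with the closed form

$$p_i^c = \frac{\alpha_i - \alpha_j(\alpha_i - \gamma_i)}
               {1 - (\alpha_1 - \gamma_1)(\alpha_2 - \gamma_2)}$$

(`stationary_cooperation()`). The stationary covariance between the two
players' moves is exactly zero, so the joint stationary law is the product of
the marginals — the package tests this against the chain's eigenvector and
against long simulations. The denominator vanishes only for
$|\alpha_i - \gamma_i| = 1$ on both sides with product $+1$ (e.g. two exact
tit-for-tat players), where the long-run outcome genuinely depends on the
first move; the function refuses that case rather than assuming a
convention, and the simulator exposes the convention explicitly
(`first_move_rule`, default "always cooperate", under which a tit-for-tat
pair locks into full cooperation).

Player 1's stationary payoff is the bilinear form
$U_1 = -4 p_1 p_2 - p_1 + 9 p_2 + 1$ for the default prizes; all
coefficients are derived from `pd_payoffs()` at run time, and the printed
form is asserted as a test for the default. Setting the derivative of $U_1$
in one's own stationary probability to zero — against an opponent whose
stationary response is $p_2 = \alpha + (\gamma - \alpha) p_1$ — yields the
symmetric totally mixed equilibrium conic

$$5\alpha^2 + 9\gamma^2 - 14\alpha\gamma + 14\alpha - 10\gamma + 1 = 0$$

(`equilibrium_residual()`, `foc_residual()`; the package verifies the two
characterisations coincide). The curve runs from tit-for-tat $(0, 1)$ down
to $\gamma = 1/9$ inside the unit square; its point of maximum tolerance,
$\alpha^\* = 7 - \sqrt{45} \approx 0.292$,
$\gamma^\* = (5 + 7\alpha^\*)/9 \approx 0.783$ (`max_tolerance_point()`,
closed form from the tangency condition $18\gamma - 14\alpha - 10 = 0$), is
the landmark separating the low-cooperation and high-cooperation branches.
Because the payoff is concave in one's own stationary probability whenever
the opponent is responsive ($\gamma > \alpha$), points on the curve are
genuine equilibria; `best_response_check()` verifies this by brute-force
deviation scans.

### Distances and epsilon-equilibrium

`deviation_report()` implements the headline empirical measure. For each
estimated session point $(\hat\alpha, \hat\gamma)$ it finds the curve point
with the same reciprocal cooperation — the larger root of
$5\alpha^2 + 14(1-\gamma)\alpha + (9\gamma^2 - 10\gamma + 1) = 0$ — and
reports the signed horizontal distance plus the payoff cost of the
tolerance deviation: one player plays $\hat\alpha$ against an opponent
holding the curve strategy, and the loss is expressed as a percentage of the
symmetric equilibrium payoff.

Two deliberate conventions:

* **Always the larger root, even when negative.** For $\gamma < 1/9$ both
  roots are below zero; the larger root is then a formal extension of the
  curve outside the strategy square. It is used anyway — flagged as
  `formal_extension` with a warning — because one pre-socialization session
  has $\hat\gamma = 2/19 < 1/9$ and its published distance and deviation are
  reproducible only under this formal extension. The stationary formulas
  remain valid algebraically for such parameters, which is why
  `stationary_cooperation()` does not clamp its inputs to $[0,1]$.
* **No clamping of losses.** `deviation_pct` could only be negative if a
  deviation gained, which concavity rules out on this data; the value is
  reported as computed rather than floored at zero.

The summary thresholds — a point counts as "consistent with theory" when its
absolute distance is below 0.1, and a loss counts as negligible at or below
0.5% — mirror the published reading of the result and are both arguments of
`run_full_analysis()`.

## Estimators

`count_conditional_moves()` classifies every move from a stage's second
round onward by the move of the player's *previous-round* partner — under
anonymous re-pairing this may be a different person from the current
partner. This is the literal reading of "responds to the move made by their
partner in the previous round", and it is the convention under which the
conditional counts are the exact sufficient statistics of the memory-one
model (the simulator generates moves by exactly this rule). First-round
moves are never classified; a move whose player has no record in the
preceding round is skipped with a warning. The estimators are then the exact
ratios $\hat\alpha = N_{tolerant}/N_{default}$,
$\hat\gamma = N_{recoop}/N_{coop}$ (`estimate_strategy()`), kept at full
double precision and rounded only for display; a zero denominator yields
`NA`, never zero.

## The simulators and what they do (not) establish

`simulate_pd_session()` emulates the experimental design's statistical
skeleton: memory-one agents, twelve players with a fresh uniform random
perfect matching each round before socialization, or re-matching within
fixed even-sized groups (default four) after. Defaults are the study's
conditions: 12 players, 11 rounds before / 18 after, cooperative first moves.
The matching law within a round is a uniformly random perfect matching
(seeded shuffle) — the design description says only that pairs "changed
randomly", so uniformity is the natural minimal assumption.
`simulate_trust_session()` draws each round's $(k, n)$ from the QRE
distributions at a known precision. Both are deterministic functions of
their seed, and `recovery_experiment()` derives independent per-replication
seeds from one root seed up front, so enlarging one replication never shifts
another's draws.

The generators emulate the *strategic* structure only: stationary
memory-one play, the pairing protocols, and logit trust behaviour. They do
not model learning within a session, subject heterogeneity beyond per-player
$(\alpha_i, \gamma_i)$, the socialization procedure itself (strategies are
exogenous inputs; nothing here explains *why* parameters shift after
socialization), or payment incentives. Passing recovery tests therefore
shows the estimation chain is consistent for data generated by the model —
not that human sessions satisfy the model's assumptions.

## Numerical choices and problem sizes

* Fixed-point root: bisection, bracket $10^{-15}$, residuals below
  $10^{-9}$ asserted in tests.
* Trust fitting: grid step $10^{-3}$ on $[0, 2]$ plus local refinement, tie
  break toward smaller $\lambda$.
* Chain oracle agreement asserted at $10^{-10}$; conic/first-order-condition
  agreement at $10^{-8}$; deviation-scan gains bounded by $10^{-9}$.
* Simulation checks compare against three *batch-means* standard errors
  (batches of 500 rounds), since rounds are serially dependent and the
  i.i.d. standard error would be anti-conservative.
* Validation runs use sessions of $2\times 10^4$ rounds and recovery studies
  of 50 replications $\times$ $10^4$ rounds — sizes at which the binomial
  standard errors of the ratio estimators are a few $10^{-3}$, small enough
  to resolve biases of $10^{-2}$ while keeping the whole suite quick on one
  CPU. At the real sessions' length (11 rounds) the same harness documents,
  without asserting, how noisy the estimators are.

## Known limitations

* The TG model is a plain logit chain at one shared precision; no
  agent-QRE or repeated-TG dynamics.
* Only the symmetric totally mixed equilibrium family of the iterated PD is
  computed; asymmetric equilibria and longer memories are out of scope.
* Precision inversion from published cooperation rates inherits their
  3-decimal rounding (see above); distances and deviations computed from
  integer count tables do not suffer this.
* No significance testing of before/after differences is provided; observed
  standard deviations are carried as data, never recomputed.
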