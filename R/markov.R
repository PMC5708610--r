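# Bilinear payoff coefficients: U1(p1, p2) = A p1 p2 + B p1 + C p2 + P.
# Defaults (10, 5, 1, 0) give U1 = -4 p1 p2 - p1 + 9 p2 + 1.
payoff_coefs <- function(payoffs) {
  list(
    A = payoffs$R - payoffs$S - payoffs$T + payoffs$P,
    B = payoffs$S - payoffs$P,
    C = payoffs$T - payoffs$P,
    base = payoffs$P
  )
}

# Coefficients of the symmetric totally mixed equilibrium curve
# qa2 a^2 + qag a g + qg2 g^2 + qa a + qg g + q0 = 0,
# normalised so the defaults give 5a^2 - 14ag + 9g^2 + 14a - 10g + 1 = 0.
curve_coefs <- function(payoffs) {
  co <- payoff_coefs(payoffs)
  list(
    qa2 = co$A + co$C,
    qag = -(co$A + 2 * co$C),
    qg2 = co$C,
    qa = -(co$A - co$C + co$B),
    qg = -(co$C - co$B),
    q0 = -co$B
  )
}

#' Stationary cooperation probabilities of a memory-one strategy pair
#'
#' A memory-one (Markov) strategy is a pair `(alpha, gamma)`: the probability
#' of cooperating after the partner defected (tolerance to defection) and
#' after the partner cooperated (reciprocal cooperation). Two such strategies
#' induce a Markov chain over the four joint states; in its stationary
#' distribution each player cooperates with a fixed marginal probability
#' solving the linear pair `p_i = gamma_i p_j + alpha_i (1 - p_j)`:
#'
#' `p_i = (alpha_i - alpha_j (alpha_i - gamma_i)) /
#'        (1 - (alpha_1 - gamma_1)(alpha_2 - gamma_2))`
#'
#' The formula is evaluated formally even for parameters outside `[0, 1]`,
#' which the equilibrium-curve analysis needs for sessions whose same-gamma
#' curve point has a slightly negative tolerance. The solution fails to exist
#' only when `(alpha_1 - gamma_1)(alpha_2 - gamma_2) = 1` — e.g. a pair of
#' exact tit-for-tat strategies — where the long-run outcome depends on the
#' initial move (see `first_move_rule` in [simulate_pd_session()]).
#'
#' @param alpha1,gamma1 First player's strategy; vectorised.
#' @param alpha2,gamma2 Second player's strategy; defaults to the first
#'   player's (a symmetric pair).
#'
#' @return A tibble with columns `p1`, `p2`.
#' @examples
#' stationary_cooperation(0.3, 0.8) # symmetric: p = 0.3 / (1 + 0.3 - 0.8) = 0.6
#' stationary_cooperation(0.2, 0.9, 0.4, 0.6)
#' @export
stationary_cooperation <- function(alpha1, gamma1, alpha2 = alpha1, gamma2 = gamma1) {
  n <- max(length(alpha1), length(gamma1), length(alpha2), length(gamma2))
  alpha1 <- rep_len(alpha1, n)
  gamma1 <- rep_len(gamma1, n)
  alpha2 <- rep_len(alpha2, n)
  gamma2 <- rep_len(gamma2, n)
  d1 <- alpha1 - gamma1
  d2 <- alpha2 - gamma2
  denom <- 1 - d1 * d2
  if (any(abs(denom) < 1e-12)) {
    abort(paste(
      "The stationary distribution is not unique: |alpha - gamma| = 1 for both",
      "players (e.g. a pair of exact tit-for-tat strategies), so the long-run",
      "play depends on the initial conditions. Simulate with an explicit",
      "`first_move_rule` instead."
    ))
  }
  tibble(
    p1 = (alpha1 - alpha2 * d1) / denom,
    p2 = (alpha2 - alpha1 * d2) / denom
  )
}

#' Transition matrix of the paired memory-one chain
#'
#' Row-stochastic 4x4 matrix over the joint states `CC`, `CD`, `DC`, `DD`
#' (first letter: player 1's move). From state `(a, b)`, player 1 next
#' cooperates with probability `gamma1` if `b = C` else `alpha1`; player 2
#' with probability `gamma2` if `a = C` else `alpha2`; the next moves are
#' conditionally independent. Used mainly as an exact cross-check of
#' [stationary_cooperation()]: for interior strategies the stationary vector
#' of this chain is the outer product of the two marginals.
#'
#' @param alpha1,gamma1,alpha2,gamma2 Strategy parameters in `[0, 1]`.
#'
#' @return A 4x4 matrix with dimnames `c("CC", "CD", "DC", "DD")`.
#' @examples
#' transition_matrix(0.3, 0.8, 0.3, 0.8)
#' @export
transition_matrix <- function(alpha1, gamma1, alpha2 = alpha1, gamma2 = gamma1) {
  pars <- c(alpha1, gamma1, alpha2, gamma2)
  if (!is.numeric(pars) || length(pars) != 4 || any(pars < 0) || any(pars > 1)) {
    abort("All strategy parameters must be single probabilities in [0, 1].")
  }
  states <- c("CC", "CD", "DC", "DD")
  m <- matrix(0, 4, 4, dimnames = list(states, states))
  for (s in seq_along(states)) {
    partner_coop <- substr(states[s], 2, 2) == "C" # what player 1 saw
    own_coop <- substr(states[s], 1, 1) == "C" # what player 2 saw
    c1 <- if (partner_coop) gamma1 else alpha1
    c2 <- if (own_coop) gamma2 else alpha2
    m[s, ] <- c(c1 * c2, c1 * (1 - c2), (1 - c1) * c2, (1 - c1) * (1 - c2))
  }
  m
}

#' Expected per-round payoff at stationary cooperation probabilities
#'
#' Player 1's expected payoff when the players cooperate independently with
#' probabilities `p1` and `p2`: the bilinear form
#' `R p1 p2 + S p1 (1 - p2) + T (1 - p1) p2 + P (1 - p1)(1 - p2)`, which for
#' the default payoffs reduces to `-4 p1 p2 - p1 + 9 p2 + 1`.
#'
#' @param p1,p2 Cooperation probabilities of players 1 and 2; vectorised.
#' @param payoffs A [pd_payoffs()] object.
#'
#' @return Numeric vector of expected points for player 1.
#' @examples
#' expected_payoff(1, 1) # mutual cooperation: 5
#' expected_payoff(0, 1) # temptation corner: 10
#' @export
expected_payoff <- function(p1, p2, payoffs = pd_payoffs()) {
  payoffs <- as_pd_payoffs(payoffs)
  co <- payoff_coefs(payoffs)
  co$A * p1 * p2 + co$B * p1 + co$C * p2 + co$base
}

#' Residual of the symmetric totally mixed equilibrium curve
#'
#' The symmetric totally mixed Nash equilibria of the iterated Prisoner's
#' Dilemma in memory-one strategies form a conic in the `(alpha, gamma)`
#' plane; for the default payoffs it is
#' `5 alpha^2 + 9 gamma^2 - 14 alpha gamma + 14 alpha - 10 gamma + 1 = 0`.
#' This function returns the left-hand side (zero on the curve), with
#' coefficients derived from `payoffs` at run time.
#'
#' @param alpha,gamma Strategy coordinates; vectorised.
#' @param payoffs A [pd_payoffs()] object.
#'
#' @return Numeric vector of residuals.
#' @examples
#' equilibrium_residual(0, 1) # tit-for-tat lies on the curve: 0
#' equilibrium_residual(0, 0) # 1
#' @export
equilibrium_residual <- function(alpha, gamma, payoffs = pd_payoffs()) {
  payoffs <- as_pd_payoffs(payoffs)
  cc <- curve_coefs(payoffs)
  cc$qa2 * alpha^2 + cc$qag * alpha * gamma + cc$qg2 * gamma^2 +
    cc$qa * alpha + cc$qg * gamma + cc$q0
}

#' Equilibrium tolerance at a given reciprocal-cooperation level
#'
#' Solves the equilibrium conic for `alpha` at fixed `gamma`, taking the
#' larger quadratic root: for the default payoffs
#' `5 alpha^2 + 14 (1 - gamma) alpha + (9 gamma^2 - 10 gamma + 1) = 0`.
#' For `gamma < 1/9` the larger root is slightly negative; the formal value is
#' still returned (and flagged downstream by [deviation_report()]), because
#' the published distance and deviation tables use exactly this formal
#' extension of the curve for the one session whose reciprocal cooperation
#' falls below 1/9.
#'
#' @param gamma Reciprocal-cooperation level(s) in `[0, 1]`; vectorised.
#' @param payoffs A [pd_payoffs()] object.
#'
#' @return Numeric vector of equilibrium tolerance values.
#' @examples
#' curve_alpha_given_gamma(1) # 0 (tit-for-tat end of the curve)
#' curve_alpha_given_gamma(0.8)
#' @export
curve_alpha_given_gamma <- function(gamma, payoffs = pd_payoffs()) {
  payoffs <- as_pd_payoffs(payoffs)
  if (!is.numeric(gamma) || any(!is.finite(gamma))) {
    abort("`gamma` must be finite numeric.")
  }
  cc <- curve_coefs(payoffs)
  qa <- cc$qa2
  qb <- cc$qag * gamma + cc$qa
  qc <- cc$qg2 * gamma^2 + cc$qg * gamma + cc$q0
  disc <- qb^2 - 4 * qa * qc
  if (any(disc < 0)) {
    abort("No real equilibrium tolerance at this `gamma` (negative discriminant).")
  }
  (-qb + sqrt(disc)) / (2 * qa)
}

#' Equilibrium point of maximum tolerance to defection
#'
#' The point on the symmetric equilibrium curve where tolerance `alpha` is
#' maximal, found in closed form from the tangency condition (the
#' `gamma`-gradient of the conic vanishes: `18 gamma - 14 alpha - 10 = 0` for
#' the default payoffs). With the default payoffs
#' `alpha* = 7 - sqrt(45) ~ 0.2918` and `gamma* = (5 + 7 alpha*) / 9 ~ 0.7825`
#' — the `(0.3, 0.8)` point separating the low-cooperation and
#' high-cooperation branches of the curve.
#'
#' @param payoffs A [pd_payoffs()] object.
#'
#' @return A one-row tibble with columns `alpha`, `gamma`.
#' @examples
#' max_tolerance_point()
#' @export
max_tolerance_point <- function(payoffs = pd_payoffs()) {
  payoffs <- as_pd_payoffs(payoffs)
  cc <- curve_coefs(payoffs)
  # tangency line: d(residual)/d(gamma) = 0 => gamma = -(qag a + qg) / (2 qg2)
  gamma_line <- function(a) -(cc$qag * a + cc$qg) / (2 * cc$qg2)
  f <- function(a) equilibrium_residual(a, gamma_line(a), payoffs)
  # f is exactly quadratic in alpha: recover its coefficients by evaluation
  c0 <- f(0)
  c2 <- (f(2) - 2 * f(1) + f(0)) / 2
  c1 <- f(1) - c0 - c2
  disc <- c1^2 - 4 * c2 * c0
  if (disc < 0) {
    abort("The equilibrium curve has no real tangency point for these payoffs.")
  }
  roots <- c((-c1 - sqrt(disc)) / (2 * c2), (-c1 + sqrt(disc)) / (2 * c2))
  gammas <- gamma_line(roots)
  ok <- roots >= 0 & roots <= 1 & gammas >= 0 & gammas <= 1
  if (!any(ok)) {
    abort("No tangency point inside the unit square for these payoffs.")
  }
  alpha <- max(roots[ok])
  gamma <- gamma_line(alpha)
  stopifnot(abs(equilibrium_residual(alpha, gamma, payoffs)) <= 1e-9)
  tibble(alpha = alpha, gamma = gamma)
}

#' First-order-condition residual at a symmetric memory-one point
#'
#' The derivative of player 1's stationary payoff with respect to their own
#' stationary cooperation probability, evaluated at the symmetric stationary
#' point induced by `(alpha, gamma)` with the opponent's stationary response
#' `p2 = alpha + (gamma - alpha) p1`. For the default payoffs the residual is
#' `-8 (gamma - alpha) p + 9 (gamma - alpha) - 4 alpha - 1` with
#' `p = alpha / (1 + alpha - gamma)`. Its zero set coincides with the
#' equilibrium conic of [equilibrium_residual()] wherever `gamma > alpha`.
#'
#' @param alpha,gamma Strategy coordinates with `gamma != alpha`; vectorised.
#' @param payoffs A [pd_payoffs()] object.
#'
#' @return Numeric vector of first-order-condition residuals.
#' @examples
#' pt <- max_tolerance_point()
#' foc_residual(pt$alpha, pt$gamma) # ~0
#' @export
foc_residual <- function(alpha, gamma, payoffs = pd_payoffs()) {
  payoffs <- as_pd_payoffs(payoffs)
  if (any(gamma == alpha)) {
    abort("`gamma` must differ from `alpha`: an unconditional opponent makes the response slope degenerate.")
  }
  co <- payoff_coefs(payoffs)
  d <- gamma - alpha
  p <- alpha / (1 + alpha - gamma)
  co$A * p * (1 + d) + co$B + co$C * d
}

#' Verify an equilibrium point by grid search over unilateral deviations
#'
#' Holds the opponent fixed at `(alpha, gamma)` and scans the deviator's
#' memory-one strategies over a unit-square grid, computing the stationary
#' payoff of each deviation minus the equilibrium payoff. For a point on the
#' equilibrium curve with `gamma > alpha` the payoff is concave in the induced
#' stationary cooperation probability and the first-order condition holds, so
#' the maximal gain is nonpositive up to numerical noise.
#'
#' @param alpha,gamma The candidate equilibrium point (scalar).
#' @param grid_step Deviation grid resolution (default 0.01).
#' @param payoffs A [pd_payoffs()] object.
#'
#' @return The largest payoff gain over all scanned deviations (a scalar;
#'   `<= 0` up to numerical noise for true equilibria).
#' @examples
#' pt <- max_tolerance_point()
#' best_response_check(pt$alpha, pt$gamma, grid_step = 0.05)
#' @export
best_response_check <- function(alpha, gamma, grid_step = 0.01, payoffs = pd_payoffs()) {
  payoffs <- as_pd_payoffs(payoffs)
  stopifnot(length(alpha) == 1, length(gamma) == 1)
  grid <- tidyr::expand_grid(
    a1 = seq(0, 1, by = grid_step),
    g1 = seq(0, 1, by = grid_step)
  )
  prof <- stationary_cooperation(grid$a1, grid$g1, alpha, gamma)
  u_dev <- expected_payoff(prof$p1, prof$p2, payoffs)
  p_eq <- alpha / (1 + alpha - gamma)
  u_eq <- expected_payoff(p_eq, p_eq, payoffs)
  max(u_dev) - u_eq
}

#' Distance and payoff deviation from the equilibrium curve
#'
#' The headline epsilon-equilibrium analysis. For each empirical
#' `(alpha, gamma)` point (one per session and stage), the function finds the
#' equilibrium point with the same reciprocal cooperation
#' ([curve_alpha_given_gamma()]), the signed horizontal tolerance distance to
#' it, and the payoff cost of the deviation: player 1 plays the empirical
#' tolerance against an opponent holding the curve strategy, and the percent
#' loss relative to the symmetric equilibrium payoff is reported.
#'
#' @param data A data frame with numeric columns `alpha` and `gamma`; other
#'   columns (session ids, stages) are carried through.
#' @param payoffs A [pd_payoffs()] object.
#'
#' @return The input tibble with columns added: `alpha_curve` (same-gamma
#'   equilibrium tolerance), `distance` (`alpha - alpha_curve`, signed),
#'   `u_eq` (symmetric equilibrium payoff), `u_dev` (the deviating player's
#'   stationary payoff), `deviation_pct` (`100 (u_eq - u_dev) / u_eq`) and
#'   `formal_extension` (`TRUE` where `alpha_curve < 0`, i.e. the curve point
#'   lies formally outside the unit square; a warning is issued).
#' @examples
#' deviation_report(data.frame(alpha = 23 / 221, gamma = 7 / 31))
#' @export
deviation_report <- function(data, payoffs = pd_payoffs()) {
  payoffs <- as_pd_payoffs(payoffs)
  if (!is.data.frame(data) || !all(c("alpha", "gamma") %in% names(data))) {
    abort("`data` must be a data frame with columns `alpha` and `gamma`.")
  }
  out <- as_tibble(data)
  out$alpha_curve <- curve_alpha_given_gamma(out$gamma, payoffs)
  out$distance <- out$alpha - out$alpha_curve
  p_eq <- out$alpha_curve / (1 + out$alpha_curve - out$gamma)
  out$u_eq <- expected_payoff(p_eq, p_eq, payoffs)
  prof <- stationary_cooperation(out$alpha, out$gamma, out$alpha_curve, out$gamma)
  out$u_dev <- expected_payoff(prof$p1, prof$p2, payoffs)
  out$deviation_pct <- 100 * (out$u_eq - out$u_dev) / out$u_eq
  out$formal_extension <- out$alpha_curve < 0
  if (any(out$formal_extension)) {
    warn(paste(
      "For", sum(out$formal_extension), "point(s) the same-gamma equilibrium",
      "tolerance is negative (gamma < 1/9): the formal extension of the curve",
      "outside the unit square is used."
    ))
  }
  out
}
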