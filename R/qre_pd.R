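#' Logit choice probabilities
#'
#' The logistic quantal response function: action `j` is chosen with
#' probability proportional to `exp(lam * u_j)`. `lam` is the precision
#' (inverse-temperature) parameter: `lam = 0` gives uniform play, and as
#' `lam` grows the choice concentrates on the best response. Computed with the
#' usual max-shift for numerical stability.
#'
#' @param utilities Numeric vector of expected payoffs, one per action.
#' @param lam Nonnegative precision parameter.
#'
#' @return A probability vector of the same length as `utilities`, summing
#'   to 1.
#' @examples
#' logit_choice(c(5, 5), lam = 2) # equal utilities: (0.5, 0.5)
#' logit_choice(c(0, 1), lam = log(9)) # (0.1, 0.9)
#' @export
logit_choice <- function(utilities, lam) {
  if (!is.numeric(utilities) || length(utilities) < 1 || any(!is.finite(utilities))) {
    abort("`utilities` must be a finite numeric vector.")
  }
  check_lambda(lam)
  w <- exp(lam * (utilities - max(utilities)))
  w / sum(w)
}

check_lambda <- function(lam) {
  if (!is.numeric(lam) || length(lam) != 1 || !is.finite(lam) || lam < 0) {
    abort("`lam` must be a single nonnegative finite number.")
  }
  invisible(lam)
}

# expected-payoff disadvantage of cooperation, u_D(p) - u_C(p), when the
# partner cooperates with probability p; 4p + 1 for the default payoffs
pd_utility_gap <- function(p, payoffs) {
  (payoffs$T - payoffs$R - payoffs$P + payoffs$S) * p + (payoffs$P - payoffs$S)
}

#' QRE cooperation probability in the one-shot Prisoner's Dilemma
#'
#' Solves the symmetric logit-QRE fixed point
#' `p = 1 / (1 + exp(lam * (u_D(p) - u_C(p))))`, where `u_C(p)` and `u_D(p)`
#' are the expected payoffs of cooperating and defecting against a partner who
#' cooperates with probability `p`. For the default payoffs the gap
#' `u_D - u_C` is `4p + 1`, so the right-hand side is strictly decreasing in
#' `p` and the root is unique; it is located by bisection on `[0, 1]`.
#' At `lam = 0` the solution is exactly 0.5 (uniform play); as `lam` grows it
#' decreases towards the Nash prediction 0.
#'
#' @param lam Nonnegative precision parameter; vectorised.
#' @param payoffs A [pd_payoffs()] object.
#' @param tol Bisection stops when the bracket is narrower than `tol`.
#'
#' @return Numeric vector of cooperation probabilities in `(0, 1)`.
#' @examples
#' qre_cooperation_prob(0) # 0.5
#' qre_cooperation_prob(1.334) # ~0.121
#' @seealso [lambda_from_cooperation()] for the closed-form inverse.
#' @export
qre_cooperation_prob <- function(lam, payoffs = pd_payoffs(), tol = 1e-15) {
  payoffs <- as_pd_payoffs(payoffs)
  vapply(lam, function(l) {
    check_lambda(l)
    resid <- function(p) 1 / (1 + exp(l * pd_utility_gap(p, payoffs))) - p
    lo <- 0
    hi <- 1
    # resid(0) > 0 > resid(1); monotone residual, so plain bisection converges
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (resid(mid) > 0) lo <- mid else hi <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Precision parameter from an observed cooperation rate
#'
#' Closed-form inversion of the one-shot QRE fixed point: for an observed
#' cooperation rate `p`, `lambda = log((1 - p) / p) / (u_D(p) - u_C(p))`,
#' which is `log((1 - p) / p) / (4p + 1)` for the default payoffs. Rates at or
#' above one half give a nonpositive `lambda` (with a warning): the QRE error
#' model cannot rationalise majority cooperation in a Prisoner's Dilemma, as
#' happens for the post-socialization stages.
#'
#' @param p Observed cooperation rate(s), strictly inside `(0, 1)`.
#' @param payoffs A [pd_payoffs()] object.
#'
#' @return Numeric vector of precision parameters.
#' @examples
#' lambda_from_cooperation(0.121) # ~1.336
#' lambda_from_cooperation(0.28) # ~0.44
#' lambda_from_cooperation(0.5) # 0
#' @export
lambda_from_cooperation <- function(p, payoffs = pd_payoffs()) {
  payoffs <- as_pd_payoffs(payoffs)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("`p` must lie strictly inside (0, 1).")
  }
  if (any(p >= 0.5)) {
    warn(paste(
      "Cooperation rate(s) at or above 0.5 imply a nonpositive precision;",
      "the QRE concept is not fully applicable there."
    ))
  }
  log((1 - p) / p) / pd_utility_gap(p, payoffs)
}
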