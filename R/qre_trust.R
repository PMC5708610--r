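#' Gratefulness distribution in the Trust Game QRE
#'
#' Given an entrusted amount `k`, the grateful player keeps `3k - n` of the
#' tripled stake when returning `n`. Under logit quantal response at precision
#' `lam`, the return level is therefore distributed proportionally to
#' `exp(lam * (3k - n))` over `n = 0, ..., 3k`. At `lam = 0` the distribution
#' is uniform; for large `lam` it concentrates on returning nothing (the
#' backward-induction behaviour).
#'
#' @param k Integer trust level in `[0, 10]`.
#' @param lam Nonnegative precision parameter.
#'
#' @return A tibble with columns `k`, `n` (`0:3k`) and `prob`.
#' @examples
#' gratitude_distribution(2, lam = 0) # uniform over 0..6
#' gratitude_distribution(1, lam = 1)
#' @export
gratitude_distribution <- function(k, lam) {
  check_trust_k(k)
  check_lambda(lam)
  n <- 0:(3 * k)
  tibble(k = k, n = n, prob = logit_choice(3 * k - n, lam))
}

check_trust_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 0 || k > 10) {
    abort("`k` must be a single integer between 0 and 10.")
  }
  invisible(k)
}

# E[n | k] under the logit gratefulness distribution
expected_return <- function(k, lam) {
  n <- 0:(3 * k)
  sum(n * logit_choice(3 * k - n, lam))
}

#' Expected grantor payoff for a given trust level
#'
#' The grantor who entrusts `k` keeps `10 - k` and receives the return `n`
#' drawn from the logit gratefulness distribution, so the expected payoff is
#' `10 - k + E[n | k]`. Entrusting nothing always yields exactly 10; at
#' `lam = 0` the expected return is `3k / 2`, so trusting is attractive; for
#' large `lam` the expectation tends to `10 - k` and trust does not pay.
#'
#' @param k Integer trust level(s) in `[0, 10]`; vectorised.
#' @param lam Nonnegative precision parameter.
#'
#' @return Numeric vector of expected payoffs.
#' @examples
#' expected_grantor_payoff(0, lam = 1) # 10
#' expected_grantor_payoff(10, lam = 0) # 15
#' @export
expected_grantor_payoff <- function(k, lam) {
  check_lambda(lam)
  vapply(k, function(ki) {
    check_trust_k(ki)
    10 - ki + expected_return(ki, lam)
  }, numeric(1))
}

#' Trust distribution in the Trust Game QRE
#'
#' The grantor's trust level is itself a logit response, at the same
#' precision, to the expected payoffs [expected_grantor_payoff()] of each
#' level `k = 0, ..., 10`: `p1(k)` is proportional to `exp(lam * u1(k))`.
#'
#' @param lam Nonnegative precision parameter.
#'
#' @return A tibble with columns `k` (`0:10`), `u1` (expected grantor payoff)
#'   and `prob`.
#' @examples
#' trust_distribution(0) # uniform over 0..10
#' trust_distribution(0.15)
#' @export
trust_distribution <- function(lam) {
  check_lambda(lam)
  k <- 0:10
  u1 <- expected_grantor_payoff(k, lam)
  tibble(k = k, u1 = u1, prob = logit_choice(u1, lam))
}

#' QRE forecast of average trust and gratefulness
#'
#' Expected trust `k(lam)` under the trust distribution and expected return
#' `n(lam)` under the joint distribution of trust and gratefulness. At
#' `lam = 0` these are exactly 5 and 7.5 (uniform play).
#'
#' @param lam Nonnegative precision parameter(s); vectorised.
#'
#' @return A tibble with columns `lambda`, `trust`, `gratefulness`.
#' @examples
#' forecast_trust_gratefulness(0) # (5, 7.5)
#' forecast_trust_gratefulness(0.15) # ~(4.39, 3.63)
#' @export
forecast_trust_gratefulness <- function(lam) {
  purrr::map_dfr(lam, function(l) {
    d <- trust_distribution(l)
    # E[n | k] = u1(k) - (10 - k)
    tibble(
      lambda = l,
      trust = sum(d$prob * d$k),
      gratefulness = sum(d$prob * (d$u1 - 10 + d$k))
    )
  })
}

#' Fit the Trust Game precision parameter to observed averages
#'
#' Chooses `lambda` so that the QRE forecast pair
#' ([forecast_trust_gratefulness()]) is as close as possible, in Euclidean
#' distance, to the observed average trust and gratefulness of a session. The
#' objective is scanned on a dense grid over `[0, lambda_max]` and then
#' refined locally with [stats::optimize()]; ties break toward the smaller
#' `lambda`.
#'
#' Averages over rounds may violate the single-round constraint
#' `n <= 3k`, so only nonnegativity of `gratefulness` is required.
#'
#' @param trust Observed average trust, in `[0, 10]`.
#' @param gratefulness Observed average gratefulness (nonnegative points).
#' @param lambda_max Upper end of the search range (default 2; the fitted
#'   values for the laboratory sessions are all below 0.4).
#' @param grid_step Grid resolution of the first-stage scan.
#'
#' @return An object of class `tg_qre_fit` with elements `lambda`, `trust`,
#'   `gratefulness` (the observations), `trust_fit`, `gratefulness_fit` (the
#'   forecasts at the fitted `lambda`) and `distance`. Use [tidy()] or
#'   [glance()] for a tibble view.
#' @examples
#' fit <- fit_lambda_tg(5.38, 3.17)
#' tidy(fit)
#' @export
fit_lambda_tg <- function(trust, gratefulness, lambda_max = 2, grid_step = 1e-3) {
  if (!is.numeric(trust) || length(trust) != 1 || trust < 0 || trust > 10) {
    abort("`trust` must be a single value in [0, 10].")
  }
  if (!is.numeric(gratefulness) || length(gratefulness) != 1 || gratefulness < 0) {
    abort("`gratefulness` must be a single nonnegative value.")
  }
  objective <- function(l) {
    f <- forecast_trust_gratefulness(l)
    sqrt((f$trust - trust)^2 + (f$gratefulness - gratefulness)^2)
  }
  grid <- seq(0, lambda_max, by = grid_step)
  dist_grid <- vapply(grid, objective, numeric(1))
  best <- which.min(dist_grid) # first minimum: ties toward smaller lambda
  lam <- grid[best]
  lo <- max(0, lam - grid_step)
  hi <- min(lambda_max, lam + grid_step)
  refined <- optimize(objective, c(lo, hi))
  if (refined$objective < dist_grid[best]) {
    lam <- refined$minimum
    dist <- refined$objective
  } else {
    dist <- dist_grid[best]
  }
  f <- forecast_trust_gratefulness(lam)
  structure(
    list(
      lambda = lam,
      trust = trust,
      gratefulness = gratefulness,
      trust_fit = f$trust,
      gratefulness_fit = f$gratefulness,
      distance = dist,
      lambda_max = lambda_max,
      grid_step = grid_step
    ),
    class = "tg_qre_fit"
  )
}

#' @export
print.tg_qre_fit <- function(x, ...) {
  cat("Trust Game logit-QRE fit\n")
  cat(sprintf("  observed:  trust %.2f, gratefulness %.2f\n", x$trust, x$gratefulness))
  cat(sprintf("  lambda:    %.4f  (searched [0, %g])\n", x$lambda, x$lambda_max))
  cat(sprintf("  forecast:  trust %.2f, gratefulness %.2f  (distance %.3f)\n",
              x$trust_fit, x$gratefulness_fit, x$distance))
  invisible(x)
}

#' @rdname fit_lambda_tg
#' @param x A `tg_qre_fit` object.
#' @param ... Unused.
#' @export
tidy.tg_qre_fit <- function(x, ...) {
  tibble(
    lambda = x$lambda,
    trust = x$trust,
    gratefulness = x$gratefulness,
    trust_fit = x$trust_fit,
    gratefulness_fit = x$gratefulness_fit,
    distance = x$distance
  )
}

#' @rdname fit_lambda_tg
#' @export
glance.tg_qre_fit <- function(x, ...) {
  tibble(
    lambda = x$lambda,
    distance = x$distance,
    lambda_max = x$lambda_max,
    grid_step = x$grid_step
  )
}
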