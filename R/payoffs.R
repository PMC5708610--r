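#' Prisoner's Dilemma payoff structure
#'
#' The four prizes of a 2x2 Prisoner's Dilemma, ordered T > R > P > S:
#' temptation (defect against a cooperator), reward (mutual cooperation),
#' punishment (mutual defection) and the sucker payoff (cooperate against a
#' defector). The default `(10, 5, 1, 0)` is the parameterisation used in the
#' laboratory sessions this package analyses.
#'
#' @param temptation,reward,punishment,sucker Numeric scalars satisfying
#'   `temptation > reward > punishment > sucker`.
#'
#' @return An object of class `pd_payoffs`: a list with elements `T`, `R`,
#'   `P`, `S`.
#' @examples
#' pd_payoffs()
#' pd_payoffs(temptation = 4, reward = 3, punishment = 1, sucker = 0)
#' @export
pd_payoffs <- function(temptation = 10, reward = 5, punishment = 1, sucker = 0) {
  vals <- c(temptation, reward, punishment, sucker)
  if (!is.numeric(vals) || length(vals) != 4L || any(!is.finite(vals))) {
    abort("All four payoffs must be finite numeric scalars.")
  }
  if (!(temptation > reward && reward > punishment && punishment > sucker)) {
    abort("Payoffs must be strictly ordered: temptation > reward > punishment > sucker.")
  }
  structure(
    list(T = temptation, R = reward, P = punishment, S = sucker),
    class = "pd_payoffs"
  )
}

#' @export
print.pd_payoffs <- function(x, ...) {
  cat(sprintf(
    "Prisoner's Dilemma payoffs: T = %g, R = %g, P = %g, S = %g\n",
    x$T, x$R, x$P, x$S
  ))
  invisible(x)
}

as_pd_payoffs <- function(payoffs) {
  if (!inherits(payoffs, "pd_payoffs")) {
    abort("`payoffs` must be created with `pd_payoffs()`.")
  }
  payoffs
}

check_moves <- function(move, arg = "move") {
  if (!is.character(move) || !all(move %in% c("C", "D"))) {
    abort(sprintf("`%s` must be a character vector of \"C\" (cooperate) or \"D\" (defect).", arg))
  }
  move
}

#' Prisoner's Dilemma payoff of a single move pair
#'
#' Maps a pair of moves to the first player's prize: (C,C) gives the reward,
#' (C,D) the sucker payoff, (D,C) the temptation and (D,D) the punishment.
#' Vectorised over both move arguments.
#'
#' @param my_move,partner_move Character vectors of `"C"` / `"D"`.
#' @param payoffs A [pd_payoffs()] object.
#'
#' @return Numeric vector of points for the player making `my_move`.
#' @examples
#' pd_payoff("C", "C") # reward, 5
#' pd_payoff(c("D", "D", "C"), c("C", "D", "D")) # 10, 1, 0
#' @export
pd_payoff <- function(my_move, partner_move, payoffs = pd_payoffs()) {
  payoffs <- as_pd_payoffs(payoffs)
  check_moves(my_move, "my_move")
  check_moves(partner_move, "partner_move")
  me_c <- my_move == "C"
  you_c <- partner_move == "C"
  dplyr::case_when(
    me_c & you_c ~ payoffs$R,
    me_c & !you_c ~ payoffs$S,
    !me_c & you_c ~ payoffs$T,
    .default = payoffs$P
  )
}

#' Trust Game payoffs
#'
#' In the Trust Game the grantor sends an integer stake `trust_k` between 0
#' and 10, the stake is tripled in transit, and the grateful player returns an
#' integer `return_n` between 0 and `3 * trust_k`. The grantor ends with
#' `10 - trust_k + return_n` points and the grateful player with
#' `3 * trust_k - return_n`, so the pair always splits `10 + 2 * trust_k`.
#'
#' @param trust_k Integer vector in `[0, 10]`, the amount entrusted.
#' @param return_n Integer vector in `[0, 3 * trust_k]`, the amount returned.
#'
#' @return A tibble with columns `trust_k`, `return_n`, `grantor`, `grateful`.
#' @examples
#' trust_payoffs(4, 5)
#' trust_payoffs(c(0, 10), c(0, 30))
#' @export
trust_payoffs <- function(trust_k, return_n) {
  check_trust_levels(trust_k, return_n)
  tibble(
    trust_k = as.integer(trust_k),
    return_n = as.integer(return_n),
    grantor = 10 - trust_k + return_n,
    grateful = 3 * trust_k - return_n
  )
}

check_trust_levels <- function(trust_k, return_n) {
  if (!is.numeric(trust_k) || any(trust_k != round(trust_k)) ||
      any(trust_k < 0) || any(trust_k > 10)) {
    abort("`trust_k` must be integers between 0 and 10.")
  }
  if (!is.numeric(return_n) || any(return_n != round(return_n)) ||
      any(return_n < 0) || any(return_n > 3 * trust_k)) {
    abort("`return_n` must be integers between 0 and 3 * trust_k.")
  }
  invisible(NULL)
}
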