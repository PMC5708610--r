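#' Conditional move counts from a round-level session log
#'
#' Classifies every move from the second round of a stage onward by the move
#' the player's previous-round partner actually made (under anonymous
#' re-pairing this may be a different person from the current partner):
#'
#' * `n_coop` — occasions on which the previous partner cooperated;
#' * `n_recoop` — cooperative replies among those (`n_recoop <= n_coop`);
#' * `n_default` — occasions on which the previous partner defected;
#' * `n_tolerant` — cooperative replies among those (`n_tolerant <= n_default`).
#'
#' These four counts are the sufficient statistics for the memory-one
#' strategy parameters; see [estimate_strategy()]. First-round moves have no
#' previous partner move and are never classified. A move whose player lacks
#' a record in the immediately preceding round is skipped with a warning.
#'
#' @param log A round-log data frame (see [read_round_log()]).
#'
#' @return A tibble with one row per `(session_id, stage)` and the four count
#'   columns.
#' @examples
#' log <- simulate_pd_session(rounds = 50, seed = 1)
#' count_conditional_moves(log)
#' @export
count_conditional_moves <- function(log) {
  log <- as_tibble(log)
  required <- c("session_id", "stage", "round", "player_id", "partner_id", "move")
  missing <- setdiff(required, names(log))
  if (length(missing) > 0) {
    abort(sprintf("`log` lacks required column(s): %s.", paste(missing, collapse = ", ")))
  }
  moves <- dplyr::select(log, "session_id", "stage", "round", "player_id", "move")
  # the partner this player faced in the previous round
  prev_partner <- log |>
    dplyr::transmute(
      .data$session_id, .data$stage, round = .data$round + 1L,
      .data$player_id, prev_partner_id = .data$partner_id
    )
  classified <- log |>
    dplyr::inner_join(prev_partner,
                      by = c("session_id", "stage", "round", "player_id")) |>
    dplyr::left_join(
      moves |>
        dplyr::transmute(
          .data$session_id, .data$stage, round = .data$round + 1L,
          prev_partner_id = .data$player_id, prev_partner_move = .data$move
        ),
      by = c("session_id", "stage", "round", "prev_partner_id")
    )
  # moves after the first round of a stage whose player has no record in the
  # immediately preceding round cannot be classified
  first_round <- log |>
    dplyr::summarise(.first = min(.data$round), .by = c("session_id", "stage"))
  skipped <- log |>
    dplyr::left_join(first_round, by = c("session_id", "stage")) |>
    dplyr::filter(.data$round > .data$.first) |>
    dplyr::anti_join(prev_partner, by = c("session_id", "stage", "round", "player_id"))
  if (nrow(skipped) > 0) {
    warn(sprintf(
      "%d move(s) skipped: no record for the player in the preceding round.",
      nrow(skipped)
    ))
  }
  classified |>
    dplyr::summarise(
      n_coop = sum(.data$prev_partner_move == "C"),
      n_recoop = sum(.data$prev_partner_move == "C" & .data$move == "C"),
      n_default = sum(.data$prev_partner_move == "D"),
      n_tolerant = sum(.data$prev_partner_move == "D" & .data$move == "C"),
      .by = c("session_id", "stage")
    )
}

#' Estimate memory-one strategy parameters from conditional counts
#'
#' The natural ratio estimators of the memory-one strategy: tolerance to
#' defection `alpha_hat = n_tolerant / n_default` and reciprocal cooperation
#' `gamma_hat = n_recoop / n_coop`. Division is exact; rounding (3 decimals in
#' the published table) happens only at report time. A zero denominator
#' leaves the corresponding estimate `NA` (undefined, not zero) with a
#' warning.
#'
#' @param counts A data frame with columns `n_coop`, `n_recoop`, `n_default`,
#'   `n_tolerant` (e.g. from [count_conditional_moves()] or the `"table5"`
#'   fixture); other columns are carried through.
#'
#' @return The input tibble with `alpha_hat` and `gamma_hat` columns added.
#' @examples
#' estimate_strategy(data.frame(n_coop = 31, n_recoop = 7,
#'                              n_default = 221, n_tolerant = 23))
#' @export
estimate_strategy <- function(counts) {
  counts <- as_tibble(counts)
  required <- c("n_coop", "n_recoop", "n_default", "n_tolerant")
  missing <- setdiff(required, names(counts))
  if (length(missing) > 0) {
    abort(sprintf("`counts` lacks required column(s): %s.", paste(missing, collapse = ", ")))
  }
  bad <- counts$n_recoop > counts$n_coop | counts$n_tolerant > counts$n_default |
    counts$n_coop < 0 | counts$n_default < 0 |
    counts$n_recoop < 0 | counts$n_tolerant < 0
  if (any(bad)) {
    abort("Invalid counts: need 0 <= n_recoop <= n_coop and 0 <= n_tolerant <= n_default.")
  }
  out <- counts |>
    dplyr::mutate(
      alpha_hat = ifelse(.data$n_default > 0, .data$n_tolerant / .data$n_default, NA_real_),
      gamma_hat = ifelse(.data$n_coop > 0, .data$n_recoop / .data$n_coop, NA_real_)
    )
  if (anyNA(out$alpha_hat) || anyNA(out$gamma_hat)) {
    warn("Zero denominator: the corresponding estimate is undefined (NA).")
  }
  out
}

#' Average cooperation level per session and stage
#'
#' The fraction of cooperative moves among all moves of a stage, all rounds
#' included.
#'
#' @param log A round-log data frame (see [read_round_log()]).
#'
#' @return A tibble with one row per `(session_id, stage)`: `n_moves` and
#'   `coop_rate`.
#' @examples
#' log <- simulate_pd_session(rounds = 50, seed = 1)
#' cooperation_level(log)
#' @export
cooperation_level <- function(log) {
  log <- as_tibble(log)
  if (nrow(log) == 0) {
    abort("`log` is empty: the cooperation level is undefined.")
  }
  log |>
    dplyr::summarise(
      n_moves = dplyr::n(),
      coop_rate = mean(.data$move == "C"),
      .by = c("session_id", "stage")
    )
}

# lambda where the QRE error model applies (cooperation below one half),
# NA otherwise
lambda_where_applicable <- function(p, payoffs) {
  vapply(p, function(pi) {
    if (!is.finite(pi) || pi <= 0 || pi >= 0.5) NA_real_
    else lambda_from_cooperation(pi, payoffs)
  }, numeric(1))
}

#' End-to-end reproduction of the session analysis
#'
#' Runs the full analysis chain. With no arguments it reproduces the
#' published tables from the packaged fixtures ([coopeq_fixture()]):
#'
#' * `cooperation` — pre-socialization cooperation rates with the QRE
#'   precision recomputed by the closed-form inversion;
#' * `strategies` — memory-one `(alpha_hat, gamma_hat)` estimates from the
#'   conditional move counts (one row per session and stage);
#' * `deviations` — the same rows with the signed same-gamma tolerance
#'   distance to the equilibrium curve and the percent payoff deviation
#'   ([deviation_report()]), plus `consistent = |distance| < distance_threshold`;
#' * `trust` — Trust Game observations with the Euclidean-fitted precision
#'   and its forecasts ([fit_lambda_tg()]);
#' * `summary` — the headline statistics: how many points lie within the
#'   tolerance threshold of the curve, the maximum percent payoff deviation,
#'   and the share of deviations at or below `small_loss_pct`.
#'
#' Supplying `round_log` (and optionally `trust_log`) runs the same chain on
#' user data instead of the fixtures. In that case the QRE precision is `NA`
#' for stages with majority cooperation, where the inversion is not
#' applicable.
#'
#' @param round_log Optional round-log data frame; default uses the packaged
#'   count and cooperation tables.
#' @param trust_log Optional trust-log data frame; default uses the packaged
#'   trust averages.
#' @param payoffs A [pd_payoffs()] object.
#' @param distance_threshold Tolerance distance below which a point counts as
#'   consistent with the equilibrium curve (default 0.1).
#' @param small_loss_pct Percent payoff loss regarded as negligible when
#'   summarising the epsilon-equilibrium result (default 0.5).
#' @param lambda_max,grid_step Search range and grid for [fit_lambda_tg()].
#'
#' @return An object of class `coopeq_report`: a list of tibbles
#'   (`cooperation`, `strategies`, `deviations`, `trust`, `summary`) plus the
#'   parameters used. `glance()` returns the summary row; `autoplot()` draws
#'   the ordered payoff-deviation chart.
#' @examples
#' report <- run_full_analysis()
#' report$summary
#' @export
run_full_analysis <- function(round_log = NULL, trust_log = NULL,
                              payoffs = pd_payoffs(),
                              distance_threshold = 0.1, small_loss_pct = 0.5,
                              lambda_max = 2, grid_step = 1e-3) {
  payoffs <- as_pd_payoffs(payoffs)

  if (is.null(round_log)) {
    tab2 <- coopeq_fixture("table2")
    cooperation <- tab2 |>
      dplyr::transmute(
        session_id = .data$date, stage = "before",
        coop_rate = .data$coop,
        lambda = lambda_where_applicable(.data$coop, payoffs)
      )
    counts <- coopeq_fixture("table5") |>
      dplyr::rename(session_id = "date")
  } else {
    round_log <- validate_round_log(round_log, payoffs = payoffs)
    cooperation <- cooperation_level(round_log) |>
      dplyr::mutate(lambda = lambda_where_applicable(.data$coop_rate, payoffs))
    counts <- count_conditional_moves(round_log)
  }

  strategies <- estimate_strategy(counts)
  usable <- !is.na(strategies$alpha_hat) & !is.na(strategies$gamma_hat)
  if (!all(usable)) {
    warn(sprintf("%d session-stage(s) dropped from the deviation analysis (undefined estimates).",
                 sum(!usable)))
  }
  deviations <- strategies[usable, ] |>
    dplyr::mutate(alpha = .data$alpha_hat, gamma = .data$gamma_hat) |>
    deviation_report(payoffs) |>
    dplyr::mutate(consistent = abs(.data$distance) < distance_threshold) |>
    dplyr::select(-"alpha", -"gamma")

  if (is.null(trust_log) && is.null(round_log)) {
    trust_obs <- coopeq_fixture("table4") |>
      dplyr::transmute(session_id = .data$date, trust = .data$trust,
                       gratefulness = .data$gratefulness)
  } else if (!is.null(trust_log)) {
    trust_obs <- as_tibble(trust_log) |>
      dplyr::summarise(
        trust = mean(.data$trust_k),
        gratefulness = mean(.data$return_n),
        .by = "session_id"
      )
  } else {
    trust_obs <- NULL
  }
  trust <- NULL
  if (!is.null(trust_obs)) {
    trust <- trust_obs |>
      dplyr::mutate(fit = purrr::map2(
        .data$trust, .data$gratefulness,
        function(k, n) tidy(fit_lambda_tg(k, n, lambda_max = lambda_max,
                                          grid_step = grid_step))[
          , c("lambda", "trust_fit", "gratefulness_fit", "distance")]
      )) |>
      tidyr::unnest("fit")
  }

  summary <- tibble(
    n_points = nrow(deviations),
    n_consistent = sum(deviations$consistent),
    distance_threshold = distance_threshold,
    max_deviation_pct = max(deviations$deviation_pct),
    n_small_loss = sum(deviations$deviation_pct <= small_loss_pct),
    share_small_loss = mean(deviations$deviation_pct <= small_loss_pct),
    small_loss_pct = small_loss_pct
  )

  structure(
    list(
      cooperation = cooperation,
      strategies = strategies,
      deviations = deviations,
      trust = trust,
      summary = summary,
      payoffs = payoffs,
      params = list(distance_threshold = distance_threshold,
                    small_loss_pct = small_loss_pct,
                    lambda_max = lambda_max, grid_step = grid_step)
    ),
    class = "coopeq_report"
  )
}

#' @export
print.coopeq_report <- function(x, ...) {
  cat("Cooperation-equilibrium session report\n\n")
  cat("Pre-socialization cooperation and QRE precision:\n")
  print(as.data.frame(x$cooperation), digits = 3)
  cat("\nMemory-one estimates and deviation from the equilibrium curve:\n")
  dev <- x$deviations |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ round(.x, 4)))
  print(as.data.frame(dev))
  if (!is.null(x$trust)) {
    cat("\nTrust Game observations and fitted QRE forecasts:\n")
    print(as.data.frame(x$trust), digits = 3)
  }
  cat("\nSummary:\n")
  cat(sprintf("  %d of %d points within %.2f of the equilibrium curve\n",
              x$summary$n_consistent, x$summary$n_points,
              x$summary$distance_threshold))
  cat(sprintf("  maximum payoff deviation %.2f%%; %d of %d (%.0f%%) at or below %.1f%%\n",
              x$summary$max_deviation_pct, x$summary$n_small_loss,
              x$summary$n_points, 100 * x$summary$share_small_loss,
              x$summary$small_loss_pct))
  invisible(x)
}

#' @rdname run_full_analysis
#' @param x A `coopeq_report` object.
#' @param ... Unused.
#' @export
glance.coopeq_report <- function(x, ...) {
  x$summary
}
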