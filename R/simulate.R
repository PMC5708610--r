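#' Simulate an iterated Prisoner's Dilemma session
#'
#' Generates a round-level log with the statistical structure of the
#' laboratory design: `n_players` agents playing memory-one strategies, with
#' either uniform random re-pairing of the whole session each round (the
#' anonymous, pre-socialization protocol) or re-pairing within fixed small
#' groups (the post-socialization protocol, groups of 4 by default).
#'
#' In round 1 each agent cooperates according to `first_move_rule`; from
#' round 2 on, agent `i` cooperates with probability `gamma[i]` if its
#' previous-round partner cooperated and `alpha[i]` otherwise. The log is
#' fully reproducible from `seed` and always passes [validate_round_log()].
#'
#' @param n_players Even number of agents (12 in the laboratory sessions).
#' @param alpha,gamma Memory-one parameters; scalars (shared by all agents)
#'   or vectors of length `n_players`.
#' @param rounds Number of rounds (the sessions used 11 before and 18 after
#'   socialization).
#' @param pairing `"random_rematch"` (uniform random perfect matching each
#'   round) or `"fixed_group"` (random matching within fixed groups of
#'   `group_size`).
#' @param group_size Even group size for `"fixed_group"`; must divide
#'   `n_players`.
#' @param first_move_rule `"always_cooperate"` (the convention under which a
#'   tit-for-tat pair locks into full cooperation) or `"bernoulli"`.
#' @param p0 First-round cooperation probability under `"bernoulli"`.
#' @param seed Optional integer seed; the caller's RNG state is left
#'   untouched.
#' @param session_id,stage Labels written into the log. `stage` defaults to
#'   `"before"` for random re-pairing and `"after"` for fixed groups.
#' @param payoffs A [pd_payoffs()] object.
#'
#' @return A round-log tibble (see [read_round_log()]).
#' @examples
#' log <- simulate_pd_session(alpha = 0.3, gamma = 0.8, rounds = 11, seed = 42)
#' cooperation_level(log)
#' @export
simulate_pd_session <- function(n_players = 12, alpha = 0.3, gamma = 0.8,
                                rounds = 11,
                                pairing = c("random_rematch", "fixed_group"),
                                group_size = 4,
                                first_move_rule = c("always_cooperate", "bernoulli"),
                                p0 = 0.5, seed = NULL,
                                session_id = "sim01", stage = NULL,
                                payoffs = pd_payoffs()) {
  pairing <- match.arg(pairing)
  first_move_rule <- match.arg(first_move_rule)
  payoffs <- as_pd_payoffs(payoffs)
  if (n_players < 2 || n_players %% 2 != 0) {
    abort("`n_players` must be an even number of at least 2.")
  }
  if (rounds < 1) abort("`rounds` must be at least 1.")
  if (pairing == "fixed_group") {
    if (group_size < 2 || group_size %% 2 != 0 || n_players %% group_size != 0) {
      abort("`group_size` must be even and divide `n_players`.")
    }
  }
  if (!length(alpha) %in% c(1L, n_players) || !length(gamma) %in% c(1L, n_players)) {
    abort("`alpha` and `gamma` must have length 1 or `n_players`.")
  }
  if (any(alpha < 0) || any(alpha > 1) || any(gamma < 0) || any(gamma > 1)) {
    abort("`alpha` and `gamma` must be probabilities in [0, 1].")
  }
  alpha <- rep_len(alpha, n_players)
  gamma <- rep_len(gamma, n_players)
  stage <- stage %||% if (pairing == "random_rematch") "before" else "after"

  if (!is.null(seed)) withr::local_seed(seed)

  groups <- if (pairing == "fixed_group") {
    split(seq_len(n_players), rep(seq_len(n_players / group_size), each = group_size))
  } else {
    list(seq_len(n_players))
  }
  draw_partners <- function() {
    partner <- integer(n_players)
    for (g in groups) {
      perm <- g[sample.int(length(g))]
      odd <- perm[seq(1, length(perm), by = 2)]
      even <- perm[seq(2, length(perm), by = 2)]
      partner[odd] <- even
      partner[even] <- odd
    }
    partner
  }

  coop <- matrix(FALSE, n_players, rounds)
  partner <- matrix(0L, n_players, rounds)
  for (r in seq_len(rounds)) {
    partner[, r] <- draw_partners()
    if (r == 1) {
      coop[, 1] <- if (first_move_rule == "always_cooperate") {
        TRUE
      } else {
        runif(n_players) < p0
      }
    } else {
      prev_partner_coop <- coop[partner[, r - 1], r - 1]
      p_coop <- ifelse(prev_partner_coop, gamma, alpha)
      coop[, r] <- runif(n_players) < p_coop
    }
  }

  ids <- sprintf("P%02d", seq_len(n_players))
  move <- ifelse(coop, "C", "D")
  partner_move <- matrix(move[cbind(as.vector(partner),
                                    rep(seq_len(rounds), each = n_players))],
                         n_players, rounds)
  tibble(
    session_id = session_id,
    stage = stage,
    round = rep(seq_len(rounds), each = n_players),
    player_id = rep(ids, rounds),
    partner_id = ids[as.vector(partner)],
    move = as.vector(move),
    points = pd_payoff(as.vector(move), as.vector(partner_move), payoffs)
  )
}

#' Simulate a Trust Game session of logit-response agents
#'
#' Each round draws a trust level `k` from the QRE trust distribution
#' ([trust_distribution()]) and a return `n` from the gratefulness
#' distribution at that `k` ([gratitude_distribution()]), both at precision
#' `lam`. Used to validate the Trust Game fitting chain on data whose
#' generating precision is known.
#'
#' @param lam Nonnegative precision parameter of the generating agents.
#' @param rounds Number of rounds.
#' @param seed Optional integer seed.
#' @param session_id,grantor_id,grateful_id Labels written into the log.
#'
#' @return A trust-log tibble (see [read_trust_log()]).
#' @examples
#' simulate_trust_session(0.15, rounds = 5, seed = 1)
#' @export
simulate_trust_session <- function(lam, rounds = 11, seed = NULL,
                                   session_id = "sim01",
                                   grantor_id = "P01", grateful_id = "P02") {
  check_lambda(lam)
  if (rounds < 1) abort("`rounds` must be at least 1.")
  if (!is.null(seed)) withr::local_seed(seed)
  p1 <- trust_distribution(lam)$prob
  k <- sample(0:10, rounds, replace = TRUE, prob = p1)
  n <- integer(rounds)
  for (kv in unique(k)) {
    idx <- which(k == kv)
    if (kv == 0) {
      n[idx] <- 0L
    } else {
      p2 <- gratitude_distribution(kv, lam)$prob
      n[idx] <- sample(0:(3 * kv), length(idx), replace = TRUE, prob = p2)
    }
  }
  tibble(
    session_id = session_id,
    round = seq_len(rounds),
    grantor_id = grantor_id,
    grateful_id = grateful_id,
    trust_k = as.integer(k),
    return_n = n
  )
}

#' Parameter-recovery experiment for the memory-one estimators
#'
#' Validation harness for the full estimation chain: repeatedly simulates a
#' session at a known `(alpha, gamma)`, runs [count_conditional_moves()] and
#' [estimate_strategy()], and summarises bias, root-mean-square error and the
#' coverage of nominal three-standard-error intervals (binomial standard
#' errors from the realised conditional counts).
#'
#' @param alpha,gamma True memory-one parameters, strictly inside `(0, 1)`.
#' @param rounds Rounds per replication.
#' @param replications Number of independent replications.
#' @param n_players,pairing,first_move_rule Passed to [simulate_pd_session()].
#' @param seed Optional integer root seed; each replication receives an
#'   independent seed derived from it up front, so changing one replication's
#'   internals never shifts another's draws.
#'
#' @return An object of class `coopeq_recovery` with elements `estimates`
#'   (one row per replication) and `summary` (one row per parameter: `bias`,
#'   `rmse`, `coverage_3se`). `tidy()` returns the per-parameter summary,
#'   `glance()` a one-row overview.
#' @examples
#' rec <- recovery_experiment(0.3, 0.8, rounds = 500, replications = 5, seed = 7)
#' tidy(rec)
#' @export
recovery_experiment <- function(alpha, gamma, rounds = 1e4, replications = 50,
                                n_players = 12, pairing = "random_rematch",
                                first_move_rule = "always_cooperate",
                                seed = NULL) {
  if (alpha <= 0 || alpha >= 1 || gamma <= 0 || gamma >= 1) {
    abort("`alpha` and `gamma` must lie strictly inside (0, 1).")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, replications)
  estimates <- purrr::map_dfr(seq_len(replications), function(r) {
    log <- simulate_pd_session(
      n_players = n_players, alpha = alpha, gamma = gamma, rounds = rounds,
      pairing = pairing, first_move_rule = first_move_rule,
      seed = rep_seeds[r], session_id = sprintf("rep%03d", r)
    )
    est <- estimate_strategy(count_conditional_moves(log))
    dplyr::mutate(est, replication = r, .before = 1)
  })
  se_a <- sqrt(estimates$alpha_hat * (1 - estimates$alpha_hat) / estimates$n_default)
  se_g <- sqrt(estimates$gamma_hat * (1 - estimates$gamma_hat) / estimates$n_coop)
  summary <- tibble(
    parameter = c("alpha", "gamma"),
    true = c(alpha, gamma),
    mean_hat = c(mean(estimates$alpha_hat), mean(estimates$gamma_hat)),
    bias = .data$mean_hat - .data$true,
    rmse = c(
      sqrt(mean((estimates$alpha_hat - alpha)^2)),
      sqrt(mean((estimates$gamma_hat - gamma)^2))
    ),
    coverage_3se = c(
      mean(abs(estimates$alpha_hat - alpha) <= 3 * se_a),
      mean(abs(estimates$gamma_hat - gamma) <= 3 * se_g)
    )
  )
  structure(
    list(estimates = estimates, summary = summary,
         rounds = rounds, replications = replications,
         n_players = n_players, pairing = pairing),
    class = "coopeq_recovery"
  )
}

#' @export
print.coopeq_recovery <- function(x, ...) {
  cat(sprintf(
    "Memory-one parameter recovery: %d replications x %d rounds, %d players (%s)\n",
    x$replications, x$rounds, x$n_players, x$pairing
  ))
  print(as.data.frame(x$summary), digits = 4)
  invisible(x)
}

#' @rdname recovery_experiment
#' @param x A `coopeq_recovery` object.
#' @param ... Unused.
#' @export
tidy.coopeq_recovery <- function(x, ...) {
  x$summary
}

#' @rdname recovery_experiment
#' @export
glance.coopeq_recovery <- function(x, ...) {
  tibble(
    replications = x$replications,
    rounds = x$rounds,
    n_players = x$n_players,
    max_abs_bias = max(abs(x$summary$bias)),
    max_rmse = max(x$summary$rmse),
    min_coverage_3se = min(x$summary$coverage_3se)
  )
}
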