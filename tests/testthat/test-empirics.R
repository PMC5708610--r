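test_that("conditional counts classify replies by the previous partner's move", {
  counts <- count_conditional_moves(toy_two_player_log())
  expect_equal(counts$n_coop, 2L)
  expect_equal(counts$n_recoop, 1L)
  expect_equal(counts$n_default, 0L)
  expect_equal(counts$n_tolerant, 0L)
})

test_that("an all-defect log yields defections only, never tolerance", {
  log <- tibble::tibble(
    session_id = "s", stage = "before",
    round = rep(1:3, each = 2),
    player_id = rep(c("P1", "P2"), 3),
    partner_id = rep(c("P2", "P1"), 3),
    move = "D"
  )
  counts <- count_conditional_moves(log)
  expect_equal(counts$n_coop, 0L)
  expect_equal(counts$n_default, 4L)
  expect_equal(counts$n_tolerant, 0L)
})

test_that("under re-pairing the classification follows the previous partner, not the current one", {
  counts <- count_conditional_moves(toy_rematch_log())
  expect_equal(counts$n_coop, 3L)
  expect_equal(counts$n_recoop, 3L)
  expect_equal(counts$n_default, 1L)
  expect_equal(counts$n_tolerant, 0L)
})

test_that("moves without a preceding-round record are skipped with a warning", {
  log <- toy_two_player_log()
  log$round[3:4] <- 3L # rounds 1 and 3: round 3 has no round-2 history
  expect_warning(counts <- count_conditional_moves(log), "skipped")
  expect_equal(nrow(counts), 0L) # nothing classifiable remains
})

test_that("strategy estimates are the exact conditional ratios", {
  est <- estimate_strategy(data.frame(n_coop = 31, n_recoop = 7,
                                      n_default = 221, n_tolerant = 23))
  expect_equal(est$alpha_hat, 23 / 221, tolerance = 1e-15)
  expect_equal(est$gamma_hat, 7 / 31, tolerance = 1e-15)
  expect_equal(round(est$alpha_hat, 3), 0.104)
  expect_equal(round(est$gamma_hat, 3), 0.226)

  est2 <- estimate_strategy(data.frame(n_coop = 70, n_recoop = 61,
                                       n_default = 26, n_tolerant = 12))
  expect_equal(round(est2$alpha_hat, 3), 0.462)
  expect_equal(round(est2$gamma_hat, 3), 0.871)

  # perfect tit-for-tat behaviour
  est3 <- estimate_strategy(data.frame(n_coop = 10, n_recoop = 10,
                                       n_default = 10, n_tolerant = 0))
  expect_equal(est3$alpha_hat, 0)
  expect_equal(est3$gamma_hat, 1)
})

test_that("zero denominators give undefined estimates, not zeros", {
  expect_warning(
    est <- estimate_strategy(data.frame(n_coop = 0, n_recoop = 0,
                                        n_default = 5, n_tolerant = 2)),
    "undefined"
  )
  expect_true(is.na(est$gamma_hat))
  expect_equal(est$alpha_hat, 0.4)
  expect_error(
    estimate_strategy(data.frame(n_coop = 3, n_recoop = 5,
                                 n_default = 5, n_tolerant = 2)),
    "Invalid counts"
  )
})

test_that("cooperation level counts all rounds", {
  log <- toy_two_player_log()
  expect_equal(cooperation_level(log)$coop_rate, 0.75)
  log$move <- "C"
  expect_equal(cooperation_level(log)$coop_rate, 1)
  expect_error(cooperation_level(log[0, ]), "empty")
})

test_that("the estimation chain recovers known strategies from one long session", {
  log <- simulate_pd_session(n_players = 12, alpha = 0.3, gamma = 0.8,
                             rounds = 2e4, seed = 99)
  est <- estimate_strategy(count_conditional_moves(log))
  se_a <- sqrt(0.3 * 0.7 / est$n_default)
  se_g <- sqrt(0.8 * 0.2 / est$n_coop)
  expect_lt(abs(est$alpha_hat - 0.3), 3 * se_a)
  expect_lt(abs(est$gamma_hat - 0.8), 3 * se_g)
  # marginal cooperation near the stationary value alpha / (1 + alpha - gamma)
  expect_equal(cooperation_level(log)$coop_rate, 0.6, tolerance = 0.02 / 0.6)
})

test_that("the fixture-driven full analysis reproduces the headline summary", {
  report <- suppressWarnings(run_full_analysis())
  expect_s3_class(report, "coopeq_report")
  expect_named(glance(report), names(report$summary))
  expect_equal(report$summary$n_points, 16L)
  expect_equal(report$summary$n_consistent, 6L)
  expect_equal(report$summary$n_small_loss, 12L)
  expect_equal(round(report$summary$max_deviation_pct, 1), 1.7)
  expect_equal(nrow(report$trust), 7L)
  expect_output(print(report), "within 0.10 of the equilibrium curve")
})

test_that("the full analysis also runs end-to-end on user logs", {
  log <- dplyr::bind_rows(
    simulate_pd_session(n_players = 12, alpha = 0.2, gamma = 0.4, rounds = 11,
                        pairing = "random_rematch", seed = 21,
                        session_id = "s1", stage = "before"),
    simulate_pd_session(n_players = 12, alpha = 0.45, gamma = 0.85, rounds = 18,
                        pairing = "fixed_group", seed = 22,
                        session_id = "s1", stage = "after")
  )
  tg <- simulate_trust_session(0.2, rounds = 40, seed = 23, session_id = "s1")
  report <- suppressWarnings(run_full_analysis(round_log = log, trust_log = tg))
  expect_equal(nrow(report$deviations), 2L)
  expect_equal(sort(report$cooperation$stage), c("after", "before"))
  # QRE inversion is not applicable to the majority-cooperation stage
  after <- report$cooperation[report$cooperation$stage == "after", ]
  if (after$coop_rate >= 0.5) expect_true(is.na(after$lambda))
  expect_equal(nrow(report$trust), 1L)
  expect_equal(report$trust$lambda, 0.2, tolerance = 0.1 / 0.2)
})
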