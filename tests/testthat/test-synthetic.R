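test_that("simulation is deterministic in the seed and leaves the RNG alone", {
  a <- simulate_pd_session(rounds = 30, seed = 123)
  b <- simulate_pd_session(rounds = 30, seed = 123)
  expect_identical(a, b)
  c <- simulate_pd_session(rounds = 30, seed = 124)
  expect_false(identical(a, c))

  set.seed(555)
  before <- runif(1)
  simulate_pd_session(rounds = 5, seed = 1)
  set.seed(555)
  expect_identical(before, runif(1))
})

test_that("degenerate strategies produce the expected play", {
  log <- simulate_pd_session(n_players = 4, alpha = 1, gamma = 1, rounds = 10,
                             seed = 2)
  expect_true(all(log$move == "C"))
  expect_true(all(log$points == 5))

  grim <- simulate_pd_session(n_players = 4, alpha = 0, gamma = 0, rounds = 10,
                              first_move_rule = "always_cooperate", seed = 2)
  expect_true(all(grim$move[grim$round == 1] == "C"))
  expect_true(all(grim$move[grim$round > 1] == "D"))
})

test_that("generated logs satisfy every round-log invariant", {
  log <- simulate_pd_session(n_players = 12, rounds = 25, seed = 31)
  expect_silent(validate_round_log(log))
  log2 <- simulate_pd_session(n_players = 12, rounds = 25, seed = 32,
                              pairing = "fixed_group", group_size = 4)
  expect_silent(validate_round_log(log2))
  # fixed groups never mix across group boundaries
  grp <- function(id) (as.integer(sub("P", "", id)) - 1) %/% 4
  expect_true(all(grp(log2$player_id) == grp(log2$partner_id)))
  expect_equal(log2$stage[1], "after")
})

test_that("configuration errors are caught", {
  expect_error(simulate_pd_session(n_players = 5), "even")
  expect_error(simulate_pd_session(n_players = 12, pairing = "fixed_group",
                                   group_size = 5), "group_size")
  expect_error(simulate_pd_session(alpha = 1.2), "probabilities")
  expect_error(simulate_pd_session(rounds = 0), "rounds")
})

test_that("long-run cooperation matches the stationary prediction within 3 SE", {
  rounds <- 2e4
  log <- simulate_pd_session(n_players = 12, alpha = 0.3, gamma = 0.8,
                             rounds = rounds, seed = 1)
  rate <- mean(log$move == "C")
  # batch-means standard error (rounds are serially dependent)
  per_round <- tapply(log$move == "C", log$round, mean)
  batches <- tapply(per_round, (seq_len(rounds) - 1) %/% 500, mean)
  se <- sd(batches) / sqrt(length(batches))
  expect_lt(abs(rate - 0.6), 3 * se)
})

test_that("a fixed pair's joint moves are independent in the long run", {
  log <- simulate_pd_session(n_players = 2, alpha = 0.35, gamma = 0.75,
                             rounds = 3e4, pairing = "fixed_group",
                             group_size = 2, seed = 8)
  wide <- tidyr::pivot_wider(log[, c("round", "player_id", "move")],
                             names_from = "player_id", values_from = "move")
  tab <- table(wide$P01, wide$P02)
  # zero stationary covariance between the two players' moves
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("simulated trust sessions draw from the QRE distributions", {
  tg <- simulate_trust_session(0, rounds = 5000, seed = 4)
  expect_true(all(tg$return_n <= 3 * tg$trust_k))
  expect_equal(mean(tg$trust_k), 5, tolerance = 0.14 / 5)
  expect_equal(mean(tg$return_n), 7.5, tolerance = 0.35 / 7.5)

  rational <- simulate_trust_session(50, rounds = 200, seed = 4)
  expect_true(all(rational$trust_k == 0))
  expect_true(all(rational$return_n == 0))

  tg2 <- simulate_trust_session(0.15, rounds = 2e4, seed = 5)
  fit <- fit_lambda_tg(mean(tg2$trust_k), mean(tg2$return_n))
  expect_equal(fit$lambda, 0.15, tolerance = 0.02 / 0.15)
})

test_that("recovery experiments summarise bias, RMSE and coverage", {
  rec <- recovery_experiment(0.5, 0.5, rounds = 2000, replications = 8,
                             seed = 17)
  expect_s3_class(rec, "coopeq_recovery")
  expect_equal(nrow(rec$estimates), 8L)
  expect_named(tidy(rec), c("parameter", "true", "mean_hat", "bias",
                            "rmse", "coverage_3se"))
  expect_equal(nrow(glance(rec)), 1L)
  # unconditional play: both conditional rates estimate the same 0.5
  expect_lt(abs(mean(rec$estimates$alpha_hat) - mean(rec$estimates$gamma_hat)),
            0.02)
  expect_true(all(rec$summary$coverage_3se >= 0 & rec$summary$coverage_3se <= 1))
  expect_error(recovery_experiment(0, 0.5), "inside")
})

test_that("plot builders return ggplot objects", {
  p1 <- plot_equilibrium_curve(points = published_strategies)
  expect_s3_class(p1, "ggplot")
  report <- suppressWarnings(run_full_analysis())
  expect_s3_class(autoplot(report), "ggplot")
  fit <- fit_lambda_tg(5.38, 3.17)
  expect_s3_class(autoplot(fit), "ggplot")
})
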