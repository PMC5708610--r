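test_that("stationary cooperation solves the defining linear system", {
  # unconditional mixing: alpha = gamma = c keeps the rate at c
  for (c0 in c(0.1, 0.5, 0.9)) {
    prof <- stationary_cooperation(c0, c0)
    expect_equal(prof$p1, c0, tolerance = 1e-14)
    expect_equal(prof$p2, c0, tolerance = 1e-14)
  }
  # symmetric closed form alpha / (1 + alpha - gamma)
  prof <- stationary_cooperation(0.3, 0.8)
  expect_equal(prof$p1, 0.6, tolerance = 1e-14)
  expect_equal(prof$p2, 0.6, tolerance = 1e-14)

  set.seed(42)
  s <- tibble::tibble(a1 = runif(100), g1 = runif(100),
                      a2 = runif(100), g2 = runif(100))
  prof <- stationary_cooperation(s$a1, s$g1, s$a2, s$g2)
  expect_equal(prof$p1, s$g1 * prof$p2 + s$a1 * (1 - prof$p2), tolerance = 1e-12)
  expect_equal(prof$p2, s$g2 * prof$p1 + s$a2 * (1 - prof$p1), tolerance = 1e-12)
})

test_that("a tit-for-tat pair has no unique stationary distribution", {
  expect_error(stationary_cooperation(0, 1, 0, 1), "tit-for-tat")
  expect_error(stationary_cooperation(1, 0, 1, 0), "tit-for-tat")
})

test_that("the 4-state chain confirms the closed-form marginals and product form", {
  states <- c("CC", "CD", "DC", "DD")
  set.seed(7)
  for (i in 1:20) {
    a1 <- runif(1, 0.05, 0.95); g1 <- runif(1, 0.05, 0.95)
    a2 <- runif(1, 0.05, 0.95); g2 <- runif(1, 0.05, 0.95)
    m <- transition_matrix(a1, g1, a2, g2)
    expect_equal(unname(rowSums(m)), rep(1, 4), tolerance = 1e-14)

    ev <- eigen(t(m))
    j <- which.min(abs(ev$values - 1))
    pi_vec <- Re(ev$vectors[, j])
    pi_vec <- pi_vec / sum(pi_vec)
    names(pi_vec) <- states

    prof <- stationary_cooperation(a1, g1, a2, g2)
    expect_equal(pi_vec[["CC"]] + pi_vec[["CD"]], prof$p1, tolerance = 1e-10)
    expect_equal(pi_vec[["CC"]] + pi_vec[["DC"]], prof$p2, tolerance = 1e-10)
    # zero stationary covariance: the joint law is the product of marginals
    product <- c(prof$p1 * prof$p2, prof$p1 * (1 - prof$p2),
                 (1 - prof$p1) * prof$p2, (1 - prof$p1) * (1 - prof$p2))
    expect_equal(unname(pi_vec), product, tolerance = 1e-10)
  }
})

test_that("degenerate strategy pairs produce the expected chain structure", {
  # unconditional cooperators absorb at CC in one step
  m <- transition_matrix(1, 1, 1, 1)
  expect_equal(unname(m[, "CC"]), rep(1, 4))
  # two tit-for-tats cycle deterministically between CD and DC
  m2 <- transition_matrix(0, 1, 0, 1)
  expect_equal(m2["CD", "DC"], 1)
  expect_equal(m2["DC", "CD"], 1)
  expect_equal(m2["CC", "CC"], 1)
  expect_equal(m2["DD", "DD"], 1)
})

test_that("expected payoff is the bilinear form with the published coefficients", {
  expect_equal(expected_payoff(1, 1), 5)
  expect_equal(expected_payoff(0, 0), 1)
  expect_equal(expected_payoff(0, 1), 10)
  expect_equal(expected_payoff(1, 0), 0)
  set.seed(3)
  p1 <- runif(50); p2 <- runif(50)
  expect_equal(expected_payoff(p1, p2),
               -4 * p1 * p2 - p1 + 9 * p2 + 1, tolerance = 1e-12)
})

test_that("the equilibrium conic passes through tit-for-tat and excludes all-defect", {
  expect_equal(equilibrium_residual(0, 1), 0)
  expect_equal(equilibrium_residual(0, 0), 1)
})

test_that("the same-gamma curve root matches frozen quadratic solutions", {
  expect_equal(curve_alpha_given_gamma(1), 0, tolerance = 1e-12)
  expect_equal(curve_alpha_given_gamma(7 / 31), 0.07138216, tolerance = 1e-6)
  # below gamma = 1/9 the larger root goes (slightly) negative
  expect_equal(curve_alpha_given_gamma(2 / 19), -0.00376506, tolerance = 1e-6)
  # the root lies on the conic across the in-square branch
  g <- seq(1 / 9, 1, length.out = 200)
  expect_true(all(abs(equilibrium_residual(curve_alpha_given_gamma(g), g)) < 1e-10))
})

test_that("the maximum-tolerance point has its closed form and maximises the curve", {
  pt <- max_tolerance_point()
  expect_equal(pt$alpha, 7 - sqrt(45), tolerance = 1e-12)
  expect_equal(pt$gamma, (5 + 7 * pt$alpha) / 9, tolerance = 1e-12)
  expect_equal(round(pt$alpha, 1), 0.3)
  expect_equal(round(pt$gamma, 1), 0.8)
  expect_lt(abs(equilibrium_residual(pt$alpha, pt$gamma)), 1e-12)

  # dense-grid oracle over the curve
  g <- seq(1 / 9, 1, length.out = 20001)
  grid_max <- max(curve_alpha_given_gamma(g))
  expect_equal(grid_max, pt$alpha, tolerance = 1e-6)

  # works for a different payoff ordering too
  po <- pd_payoffs(temptation = 8, reward = 5, punishment = 2, sucker = 1)
  pt2 <- max_tolerance_point(po)
  expect_lt(abs(equilibrium_residual(pt2$alpha, pt2$gamma, po)), 1e-9)
})

test_that("the first-order condition vanishes exactly on the equilibrium curve", {
  g <- seq(0.15, 0.99, length.out = 50)
  a <- curve_alpha_given_gamma(g)
  expect_true(all(g > a)) # upper branch: responsive opponents
  expect_true(all(abs(foc_residual(a, g)) < 1e-9))
  # and is far from zero off the curve
  expect_gt(abs(foc_residual(0.5, 0.5001)), 1)
  expect_gt(abs(foc_residual(0.5, 0.9)), 0.5)
  expect_error(foc_residual(0.4, 0.4), "degenerate")
})

test_that("no unilateral memory-one deviation improves on a curve point", {
  pt <- max_tolerance_point()
  expect_lte(best_response_check(pt$alpha, pt$gamma, grid_step = 0.01), 1e-9)
  # off-curve points are strictly improvable
  expect_gt(best_response_check(0.5, 0.9, grid_step = 0.05), 0.01)
})

test_that("deviation_report is exact on the curve and flags the formal extension", {
  g <- 0.6
  a <- curve_alpha_given_gamma(g)
  rep <- deviation_report(data.frame(alpha = a, gamma = g))
  expect_equal(rep$distance, 0, tolerance = 1e-12)
  expect_equal(rep$deviation_pct, 0, tolerance = 1e-9)
  expect_false(rep$formal_extension)

  expect_warning(
    rep2 <- deviation_report(data.frame(alpha = 14 / 101, gamma = 2 / 19)),
    "formal extension"
  )
  expect_true(rep2$formal_extension)
  expect_lt(rep2$alpha_curve, 0)

  expect_error(deviation_report(data.frame(x = 1)), "alpha")
})
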