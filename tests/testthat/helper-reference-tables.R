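# Published per-session reference values used as expected outputs.
# The inputs (cooperation levels, trust averages, conditional counts) ship as
# CSV fixtures; the tables below are the published *results* those inputs
# should reproduce.

session_dates <- c(
  "15.09.2015", "21.09.2015", "28.09.2015", "05.10.2015",
  "09.10.2015", "12.10.2015", "19.10.2015", "26.10.2015"
)

# memory-one estimates (3 dp), per session x stage
published_strategies <- tibble::tibble(
  date = rep(session_dates, 2),
  stage = rep(c("before", "after"), each = 8),
  alpha = c(
    0.104, 0.139, 0.329, 0.228, 0.286, 0.368, 0.260, 0.160,
    0.462, 0.395, 0.411, 0.329, 0.358, 0.439, 0.650, 0.239
  ),
  gamma = c(
    0.226, 0.105, 0.500, 0.143, 0.419, 0.481, 0.465, 0.346,
    0.871, 0.736, 0.763, 0.756, 0.670, 0.816, 0.855, 0.813
  )
)

# signed same-gamma tolerance distances to the equilibrium curve, as printed
# (precision varies by cell)
published_distances <- tibble::tibble(
  date = rep(session_dates, 2),
  stage = rep(c("before", "after"), each = 8),
  distance = c(
    0.03269024, 0.14237892, 0.11205629, 0.20802336,
    0.10754084, 0.1597411, 0.05905651, 0.01923364,
    0.185075, 0.106521, 0.119693, 0.038593,
    0.081434, 0.148679, 0.367935, -0.0512
  ),
  printed_dp = c(8, 8, 8, 8, 8, 7, 8, 8, 6, 6, 6, 6, 6, 6, 6, 4)
)

# percent payoff deviations of the deviating player (2 dp)
published_deviation_pct <- tibble::tibble(
  date = rep(session_dates, 2),
  stage = rep(c("before", "after"), each = 8),
  deviation_pct = c(
    0.03, 0.92, 0.25, 1.68, 0.26, 0.51, 0.08, 0.01,
    0.31, 0.16, 0.19, 0.02, 0.11, 0.25, 1.01, 0.04
  )
)

# a hand-built 2-player toy log: both cooperate in round 1; in round 2
# player 1 cooperates again while player 2 defects
toy_two_player_log <- function() {
  tibble::tibble(
    session_id = "toy",
    stage = "before",
    round = c(1L, 1L, 2L, 2L),
    player_id = c("P1", "P2", "P1", "P2"),
    partner_id = c("P2", "P1", "P2", "P1"),
    move = c("C", "C", "C", "D")
  )
}

# 4 players, re-paired between rounds: round 1 pairs (P1,P2), (P3,P4) with
# moves C, D, C, C; round 2 pairs (P1,P3), (P2,P4) with moves D, C, C, C.
# Classified by the PREVIOUS partner's actual move this gives counts
# (n_coop, n_recoop, n_default, n_tolerant) = (3, 3, 1, 0); the alternative
# "current partner's previous move" convention would give (3, 2, 1, 1).
toy_rematch_log <- function() {
  tibble::tibble(
    session_id = "toy",
    stage = "before",
    round = rep(c(1L, 2L), each = 4),
    player_id = rep(c("P1", "P2", "P3", "P4"), 2),
    partner_id = c("P2", "P1", "P4", "P3", "P3", "P4", "P1", "P2"),
    move = c("C", "D", "C", "C", "D", "C", "C", "C")
  )
}
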