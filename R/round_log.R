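#' Read a round-level Prisoner's Dilemma session log
#'
#' Session logs are comma-separated UTF-8 files with header
#' `session_id,stage,round,player_id,partner_id,move,points`; `move` is a
#' single character `C`/`D` and `stage` is `before` or `after` (the
#' socialization split). The `points` column is optional: the analysis needs
#' only moves, so points are recomputed from the move pair when absent.
#'
#' On load every record is validated: stages and moves must come from the
#' fixed vocabularies, pairing within each (session, stage, round) must be an
#' involution (your partner's partner is you), and any supplied points must
#' equal the payoff implied by the move pair. Violations are reported with row
#' numbers.
#'
#' @param path Path to a CSV file.
#' @param payoffs A [pd_payoffs()] object used to recompute or check points.
#' @param recompute_points If `TRUE` (default), `points` is recomputed from
#'   the move pair; a supplied points column is then checked against it.
#'
#' @return A tibble with columns `session_id`, `stage`, `round`, `player_id`,
#'   `partner_id`, `move`, `points`.
#' @seealso [write_round_log()], [validate_round_log()], [simulate_pd_session()]
#' @export
read_round_log <- function(path, payoffs = pd_payoffs(), recompute_points = TRUE) {
  spec <- list(
    session_id = readr::col_character(),
    stage = readr::col_character(),
    round = readr::col_integer(),
    player_id = readr::col_character(),
    partner_id = readr::col_character(),
    move = readr::col_character(),
    points = readr::col_double()
  )
  header <- strsplit(readr::read_lines(path, n_max = 1), ",")[[1]]
  raw <- readr::read_csv(
    path,
    col_types = do.call(readr::cols,
                        c(spec[intersect(names(spec), header)],
                          .default = list(readr::col_character())))
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "Malformed round log `%s`: parse problem at row %d (%s).",
      path, probs$row[1], probs$expected[1]
    ))
  }
  required <- c("session_id", "stage", "round", "player_id", "partner_id", "move")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Round log `%s` lacks required column(s): %s.",
                  path, paste(missing, collapse = ", ")))
  }
  validate_round_log(raw, payoffs = payoffs, recompute_points = recompute_points)
}

#' Validate a round-level session log
#'
#' Checks the invariants of the round-log dialect (see [read_round_log()]) on
#' an in-memory data frame and returns the log as a tibble with `points`
#' filled in.
#'
#' @param log A data frame with the round-log columns.
#' @inheritParams read_round_log
#' @return The validated log as a tibble, with a `points` column.
#' @export
validate_round_log <- function(log, payoffs = pd_payoffs(), recompute_points = TRUE) {
  payoffs <- as_pd_payoffs(payoffs)
  log <- as_tibble(log)
  bad_stage <- which(!log$stage %in% c("before", "after"))
  if (length(bad_stage) > 0) {
    abort(sprintf("Invalid `stage` (must be \"before\"/\"after\") at row(s): %s.",
                  paste(head(bad_stage, 5), collapse = ", ")))
  }
  bad_move <- which(!log$move %in% c("C", "D"))
  if (length(bad_move) > 0) {
    abort(sprintf("Invalid `move` (must be \"C\"/\"D\") at row(s): %s.",
                  paste(head(bad_move, 5), collapse = ", ")))
  }
  if (!is.numeric(log$round) || any(is.na(log$round)) || any(log$round < 1) ||
      any(log$round != round(log$round))) {
    abort("`round` must be positive integers.")
  }
  log$round <- as.integer(log$round)
  if (any(log$player_id == log$partner_id)) {
    abort(sprintf("Self-pairing at row(s): %s.",
                  paste(head(which(log$player_id == log$partner_id), 5), collapse = ", ")))
  }
  dup <- duplicated(log[, c("session_id", "stage", "round", "player_id")])
  if (any(dup)) {
    abort(sprintf("Duplicate (session, stage, round, player) record at row(s): %s.",
                  paste(head(which(dup), 5), collapse = ", ")))
  }

  # pairing must be an involution within (session, stage, round), and the
  # partner's own record must name this player back
  log$.row <- seq_len(nrow(log))
  mirror <- log |>
    dplyr::select("session_id", "stage", "round",
                  partner_id = "player_id", partner_of_partner = "partner_id",
                  partner_move = "move")
  joined <- log |>
    dplyr::left_join(mirror, by = c("session_id", "stage", "round", "partner_id"))
  no_partner <- which(is.na(joined$partner_of_partner))
  if (length(no_partner) > 0) {
    abort(sprintf("Partner record missing within the same round at row(s): %s.",
                  paste(head(no_partner, 5), collapse = ", ")))
  }
  not_involution <- which(joined$partner_of_partner != joined$player_id)
  if (length(not_involution) > 0) {
    abort(sprintf("Pairing is not an involution (partner's partner differs) at row(s): %s.",
                  paste(head(not_involution, 5), collapse = ", ")))
  }

  implied <- pd_payoff(joined$move, joined$partner_move, payoffs)
  if (!recompute_points && "points" %in% names(log)) {
    off <- which(abs(log$points - implied) > 1e-9)
    if (length(off) > 0) {
      abort(sprintf("`points` disagrees with the move pair at row(s): %s.",
                    paste(head(off, 5), collapse = ", ")))
    }
  } else if ("points" %in% names(log) && !all(is.na(log$points))) {
    off <- which(!is.na(log$points) & abs(log$points - implied) > 1e-9)
    if (length(off) > 0) {
      abort(sprintf("`points` disagrees with the move pair at row(s): %s.",
                    paste(head(off, 5), collapse = ", ")))
    }
  }
  log$points <- implied
  log$.row <- NULL
  log[, c("session_id", "stage", "round", "player_id", "partner_id", "move", "points")]
}

#' Write a round-level session log
#'
#' Writes the CSV dialect read by [read_round_log()]; the write/read
#' round trip is lossless for valid logs.
#'
#' @param log A round-log data frame (validated before writing).
#' @param path Output CSV path.
#' @inheritParams read_round_log
#' @return `path`, invisibly.
#' @export
write_round_log <- function(log, path, payoffs = pd_payoffs()) {
  log <- validate_round_log(log, payoffs = payoffs)
  readr::write_csv(log, path)
  invisible(path)
}

#' Read or write a Trust Game session log
#'
#' The trust-log dialect is a CSV with header
#' `session_id,round,grantor_id,grateful_id,trust_k,return_n`, one row per
#' trust interaction: `trust_k` in `[0, 10]` is the amount entrusted and
#' `return_n` in `[0, 3 * trust_k]` the amount returned.
#'
#' @param path Path to a CSV file.
#' @return `read_trust_log()` returns a validated tibble;
#'   `write_trust_log()` returns `path` invisibly.
#' @seealso [simulate_trust_session()]
#' @export
read_trust_log <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      session_id = readr::col_character(),
      round = readr::col_integer(),
      grantor_id = readr::col_character(),
      grateful_id = readr::col_character(),
      trust_k = readr::col_integer(),
      return_n = readr::col_integer()
    )
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed trust log `%s`: parse problem at row %d.",
                  path, probs$row[1]))
  }
  required <- c("session_id", "round", "grantor_id", "grateful_id", "trust_k", "return_n")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Trust log `%s` lacks required column(s): %s.",
                  path, paste(missing, collapse = ", ")))
  }
  check_trust_levels(raw$trust_k, raw$return_n)
  raw
}

#' @rdname read_trust_log
#' @param log A trust-log data frame.
#' @export
write_trust_log <- function(log, path) {
  check_trust_levels(log$trust_k, log$return_n)
  readr::write_csv(as_tibble(log), path)
  invisible(path)
}

#' Packaged session-summary tables
#'
#' The published summary tables of the eight 2015 laboratory sessions, shipped
#' as plain-CSV fixtures so the full analysis is reproducible without the raw
#' round-level data:
#'
#' * `"table2"` — average cooperation level before socialization (`coop`,
#'   with its standard deviation `sd`) and the published QRE precision
#'   `lambda`, per session date.
#' * `"table3"` — average cooperation level after socialization.
#' * `"table4"` — average trust and gratefulness in the Trust Game with the
#'   published fitted `lambda` and forecasts (one session lacks trust data and
#'   is absent).
#' * `"table5"` — conditional move counts per session and stage: `n_coop`
#'   (partner cooperated in the previous round), `n_recoop` (cooperative reply
#'   to cooperation), `n_default` (partner defected), `n_tolerant`
#'   (cooperative reply to defection).
#'
#' @param name One of `"table2"`, `"table3"`, `"table4"`, `"table5"`.
#' @return A tibble.
#' @examples
#' coopeq_fixture("table5")
#' @export
coopeq_fixture <- function(name = c("table2", "table3", "table4", "table5")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "coopeq")
  if (path == "") {
    abort(sprintf("Packaged fixture `%s` not found.", name))
  }
  readr::read_csv(path, col_types = readr::cols(
    date = readr::col_character(),
    .default = readr::col_guess()
  ))
}
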