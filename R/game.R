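#' Rock-paper-scissors choices
#'
#' The closed set of legal choices, in the order the words are spoken.
#'
#' @format Character vector of length 3.
#' @export
rps_choices <- c("rock", "paper", "scissors")

check_choice <- function(x, arg = deparse(substitute(x))) {
  if (!all(x %in% rps_choices)) {
    bad <- unique(x[!x %in% rps_choices])
    stop(sprintf("`%s` contains invalid choice(s): %s", arg,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Outcome of a rock-paper-scissors game
#'
#' Rock beats scissors, scissors beats paper, paper beats rock; equal choices
#' draw. Vectorised over both arguments.
#'
#' @param player,opponent Character vectors of choices
#'   (`"rock"`, `"paper"`, `"scissors"`).
#' @return Character vector: `"win"`, `"draw"` or `"loss"` from the player's
#'   perspective.
#' @examples
#' rps_outcome("paper", "rock")
#' rps_outcome(rps_choices, "scissors")
#' @export
rps_outcome <- function(player, opponent) {
  check_choice(player)
  check_choice(opponent)
  # position in the 3-cycle rock -> scissors -> paper -> rock
  beats <- c(rock = "scissors", paper = "rock", scissors = "paper")
  dplyr::case_when(
    player == opponent ~ "draw",
    beats[player] == opponent ~ "win",
    .default = "loss"
  )
}

#' The choice that beats a given choice
#'
#' `rps_outcome(rps_counter(x), x)` is `"win"` for every legal `x`.
#'
#' @param choice Character vector of choices.
#' @return Character vector of counter-choices.
#' @examples
#' rps_counter("rock") # "paper"
#' @export
rps_counter <- function(choice) {
  check_choice(choice)
  unname(c(rock = "paper", paper = "scissors", scissors = "rock")[choice])
}

#' Expected win rate of a probabilistic decoder-follower
#'
#' A player follows the decoder (plays the counter of the decoded choice) with
#' probability `follow_prob` and otherwise chooses uniformly at random.
#' Following wins exactly when the decode is correct, so the expected win rate
#' is `follow_prob * validity + (1 - follow_prob) / 3`.
#'
#' @param follow_prob Probability in \eqn{[0, 1]} of acting on the decoder.
#' @param validity Fraction in \eqn{[0, 1]} of games the decoder gets right.
#' @return Numeric expected win fraction.
#' @examples
#' expected_win_rate(1, 0.6)  # 0.6
#' expected_win_rate(0, 0.6)  # 1/3
#' @export
expected_win_rate <- function(follow_prob, validity) {
  if (any(follow_prob < 0 | follow_prob > 1)) {
    stop("`follow_prob` must lie in [0, 1]", call. = FALSE)
  }
  if (any(validity < 0 | validity > 1)) {
    stop("`validity` must lie in [0, 1]", call. = FALSE)
  }
  follow_prob * validity + (1 - follow_prob) / 3
}
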