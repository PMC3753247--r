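#' Player strategies
#'
#' A strategy decides, game by game, whether the player acts on the pupil
#' decoder. `strategy_follower(p)` plays the counter-move of the decoded
#' choice with probability `p` and a uniformly random choice otherwise;
#' `strategy_always_follow()` is `strategy_follower(1)` and
#' `strategy_uniform()` ignores the decoder entirely (equivalent to
#' `strategy_follower(0)` in distribution).
#'
#' `follow_prob` may be a vector; [play_session()] recycles it over games,
#' which is how block-wise schedules (e.g. a learning ramp over four blocks)
#' are expressed.
#'
#' @param follow_prob Probability (or per-game vector of probabilities) in
#'   \eqn{[0, 1]} of acting on the decoder.
#' @return A list of class `"rps_strategy"`.
#' @examples
#' strategy_follower(0.5)
#' @export
strategy_follower <- function(follow_prob = 1) {
  if (any(follow_prob < 0 | follow_prob > 1)) {
    stop("`follow_prob` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(kind = "probabilistic_follower", follow_prob = follow_prob),
            class = "rps_strategy")
}

#' @rdname strategy_follower
#' @export
strategy_always_follow <- function() {
  structure(list(kind = "always_follow", follow_prob = 1),
            class = "rps_strategy")
}

#' @rdname strategy_follower
#' @export
strategy_uniform <- function() {
  structure(list(kind = "uniform_random", follow_prob = 0),
            class = "rps_strategy")
}

#' Play one session against a set of opponent games
#'
#' Simulates a single player working through `games` under a strategy.
#' Follower strategies play [rps_counter()] of the decoded choice with their
#' follow probability; otherwise (and always for `strategy_uniform()`) the
#' player picks uniformly at random. Outcomes are scored against the true
#' `opponent_choice`.
#'
#' @param games An `"rps_games"` tibble; decoded automatically if the
#'   `decoded_choice` column is absent and the strategy needs it.
#' @param strategy An `"rps_strategy"` (default [strategy_uniform()]).
#' @param seed Optional integer seed for reproducibility.
#' @param shuffle Present the games in fresh random order (default `TRUE`,
#'   as sessions randomise game order; set `FALSE` when the order was fixed
#'   upstream, e.g. by [build_blocks()]).
#' @return A tibble of class `"rps_session"`: `game_index`, `game_id`,
#'   `player_choice`, `opponent_choice`, `outcome`, `win`, `cumulative_wins`.
#' @examples
#' \donttest{
#' s <- play_session(reference_fixture(), strategy_always_follow(), seed = 1)
#' sum(s$win)  # 45
#' }
#' @export
play_session <- function(games, strategy = strategy_uniform(), seed = NULL,
                         shuffle = TRUE) {
  stopifnot(inherits(strategy, "rps_strategy"))
  if (nrow(games) == 0L) stop("empty game set", call. = FALSE)
  uses_decoder <- strategy$kind != "uniform_random"
  if (uses_decoder && !"decoded_choice" %in% names(games)) {
    games <- decode_games(games)
  }
  with_seed_if(seed, {
    ord <- if (shuffle) sample.int(nrow(games)) else seq_len(nrow(games))
    n <- nrow(games)
    fp <- rep(strategy$follow_prob, length.out = n)
    follows <- uses_decoder & (runif(n) < fp)
    random_choice <- sample(rps_choices, n, replace = TRUE)
    decoded <- if (uses_decoder) games$decoded_choice[ord] else rep(NA_character_, n)
    player_choice <- ifelse(follows, rps_counter(
      ifelse(is.na(decoded), "rock", decoded)), random_choice)
    opponent_choice <- games$opponent_choice[ord]
    outcome <- rps_outcome(player_choice, opponent_choice)
    res <- tibble(
      game_index = seq_len(n),
      game_id = games$game_id[ord],
      player_choice = player_choice,
      opponent_choice = opponent_choice,
      outcome = outcome,
      win = outcome == "win",
      cumulative_wins = cumsum(outcome == "win")
    )
    class(res) <- c("rps_session", class(res))
    res
  })
}
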