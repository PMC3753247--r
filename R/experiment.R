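#' Select the 100%-validity subset of a game set
#'
#' From the decoder-valid games (global pupil maximum in the selected
#' interval), takes the first `n_per_interval` games in chronological order
#' (ascending `game_id`) for each selected interval. The result — 30 games by
#' default, 10 per interval, all valid — is the curated set used to test
#' whether players can learn a perfectly valid pupil signal.
#'
#' @param games An `"rps_games"` tibble; decoded automatically if needed.
#' @param n_per_interval Valid games to take per interval (default 10).
#' @return The subset, ordered by `game_id`.
#' @examples
#' \donttest{
#' nrow(select_100pct_subset(reference_fixture()))  # 30
#' }
#' @export
select_100pct_subset <- function(games, n_per_interval = 10) {
  if (!"valid" %in% names(games)) games <- decode_games(games)
  valid <- games |>
    dplyr::filter(.data$valid) |>
    dplyr::arrange(.data$game_id)
  counts <- valid |> dplyr::count(.data$selected_interval)
  for (i in 1:3) {
    n_i <- counts$n[match(i, counts$selected_interval)]
    if (is.na(n_i) || n_i < n_per_interval) {
      stop(sprintf("interval %d has only %d valid game(s); %d required",
                   i, ifelse(is.na(n_i), 0L, n_i), n_per_interval),
           call. = FALSE)
    }
  }
  valid |>
    dplyr::group_by(.data$selected_interval) |>
    dplyr::slice_head(n = n_per_interval) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$game_id)
}

#' Arrange a game subset into randomised blocks
#'
#' Repeats the subset `n_blocks` times, independently shuffling the game
#' order within each block (as when 30 curated games are replayed in 4
#' randomised blocks of 30).
#'
#' @param subset An `"rps_games"` tibble.
#' @param n_blocks Number of blocks (>= 1).
#' @param seed Optional integer seed.
#' @return A tibble of `n_blocks * nrow(subset)` game rows in session order,
#'   with a `block` column added.
#' @examples
#' \donttest{
#' s <- build_blocks(select_100pct_subset(reference_fixture()), 4, seed = 1)
#' table(s$block)  # 30 games per block
#' }
#' @export
build_blocks <- function(subset, n_blocks = 4, seed = NULL) {
  if (nrow(subset) == 0L) stop("empty subset", call. = FALSE)
  if (n_blocks < 1) stop("`n_blocks` must be >= 1", call. = FALSE)
  with_seed_if(seed, {
    blocks <- purrr::map(seq_len(n_blocks), function(b) {
      out <- subset[sample.int(nrow(subset)), ]
      out$block <- b
      out
    })
    dplyr::bind_rows(blocks)
  })
}

rps_condition_names <- c("naive_eye", "informed_eye", "reconstructed_pupil",
                         "no_video", "naive_100pct")

# Default strategy per condition. Naive and no-video players perform at
# chance (uniform random); informed and reconstructed-pupil players act on
# the decoder (upper-bound follow probability 1, a config knob in
# run_condition); the 100%-validity condition uses a block-ramped follow
# probability (0, 1/3, 2/3, 1) as a descriptive stand-in for within-session
# learning.
condition_defaults <- function(condition) {
  switch(condition,
    naive_eye = ,
    no_video = list(strategy = strategy_uniform(), blocks = 1L),
    informed_eye = ,
    reconstructed_pupil = list(strategy = strategy_always_follow(),
                               blocks = 1L),
    naive_100pct = list(strategy = NULL, blocks = 4L))
}

#' Simulate one experimental condition
#'
#' Runs `n_players` independent sessions of one of the five study conditions
#' and applies the per-player exact binomial tests (Bonferroni-corrected
#' across players) and the group t-test against chance (33%).
#'
#' Conditions: `naive_eye`, `no_video` — decoder-independent uniform-random
#' players over the full game set; `informed_eye`, `reconstructed_pupil` —
#' decoder-following players over the full set (the reconstructed-pupil
#' stimulus differs perceptually, not computationally); `naive_100pct` — the
#' 30-game 100%-validity subset played in 4 independently randomised blocks
#' with a block-ramped follow probability.
#'
#' @param games An `"rps_games"` tibble (the full game set; the
#'   `naive_100pct` subset is derived from it).
#' @param condition One of the five condition names.
#' @param n_players Number of simulated players (default 10).
#' @param seed Optional integer seed.
#' @param follow_prob Override of the condition's follow probability
#'   (scalar, per-game vector, or for `naive_100pct` a per-block vector).
#' @param alpha Family-wise significance level (default 0.05).
#' @return A list of class `"rps_condition"`: `condition`, `sessions` (long
#'   tibble over players), `players` (per-player wins and binomial test),
#'   `group` (t-test row), `n_games`.
#' @examples
#' \donttest{
#' rc <- run_condition(reference_fixture(), "informed_eye", n_players = 3,
#'                     seed = 1)
#' rc$players$k  # every always-follow player wins 45
#' }
#' @export
run_condition <- function(games,
                          condition = rps_condition_names,
                          n_players = 10, seed = NULL, follow_prob = NULL,
                          alpha = 0.05) {
  condition <- match.arg(condition)
  defaults <- condition_defaults(condition)
  if (condition == "naive_100pct") {
    subset <- select_100pct_subset(games)
    fp_blocks <- follow_prob %||% c(0, 1 / 3, 2 / 3, 1)
    fp <- rep(fp_blocks, each = nrow(subset), length.out =
                nrow(subset) * defaults$blocks)
    strategy <- strategy_follower(fp)
  } else {
    strategy <- if (!is.null(follow_prob)) {
      strategy_follower(follow_prob)
    } else {
      defaults$strategy
    }
    if (strategy$kind != "uniform_random") games <- decode_games(games)
  }
  sessions <- with_seed_if(seed, {
    purrr::map(seq_len(n_players), function(p) {
      sess <- if (condition == "naive_100pct") {
        blocks <- build_blocks(subset, defaults$blocks)
        play_session(blocks, strategy, shuffle = FALSE)
      } else {
        play_session(games, strategy, shuffle = TRUE)
      }
      sess$player <- p
      sess
    }) |> dplyr::bind_rows()
  })
  players <- sessions |>
    dplyr::group_by(.data$player) |>
    dplyr::summarise(n = dplyr::n(), k = sum(.data$win), .groups = "drop")
  bt <- binomial_tail(players$n, players$k, alpha = alpha,
                      m_comparisons = n_players)
  players <- players |>
    dplyr::mutate(win_fraction = .data$k / .data$n,
                  p_value = bt$p_value, significant = bt$significant)
  group <- rps_t_test(players$win_fraction, mu = 1 / 3, kind = "one_sample")
  structure(list(condition = condition, sessions = sessions,
                 players = players, group = group,
                 n_games = max(players$n), alpha = alpha),
            class = "rps_condition")
}

#' Replicate the full five-condition study
#'
#' Runs all five conditions against one opponent game set (default the
#' 75-game reference fixture) with `n_players` simulated players each, and
#' collects per-player, per-condition and group-level statistics.
#'
#' @param games Opponent game set (default [reference_fixture()]).
#' @param n_players Players per condition (default 10, the study's group
#'   size).
#' @param seed Optional integer seed; sub-seeds for the five conditions are
#'   derived from it, so a fixed seed reproduces the whole report.
#' @param alpha Family-wise significance level.
#' @return A list of class `"rps_study"` with one `"rps_condition"` per
#'   condition; see [tidy.rps_study()] and [glance.rps_study()].
#' @examples
#' \donttest{
#' st <- replicate_study(n_players = 3, seed = 42)
#' glance(st)
#' }
#' @export
replicate_study <- function(games = reference_fixture(), n_players = 10,
                            seed = NULL, alpha = 0.05) {
  games <- decode_games(games)
  seeds <- if (is.null(seed)) {
    vector("list", length(rps_condition_names))
  } else {
    as.list(seed + seq_along(rps_condition_names))
  }
  conditions <- purrr::map2(
    rps_condition_names, seeds,
    ~ run_condition(games, .x, n_players = n_players, seed = .y,
                    alpha = alpha))
  names(conditions) <- rps_condition_names
  structure(list(conditions = conditions, n_players = n_players,
                 seed = seed, alpha = alpha),
            class = "rps_study")
}
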