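#' Word schedule for one game
#'
#' The three words "rock", "paper", "scissors" are spoken in random order at
#' 4-s spacing; a schedule records the spoken order and the onset times.
#'
#' @param order Character permutation of `rps_choices`.
#' @param onsets_s Strictly increasing onset times in seconds (default 1, 5, 9:
#'   4-s spacing with a 1-s lead-in).
#' @return A list with elements `order` and `onsets_s`.
#' @examples
#' word_schedule(c("scissors", "rock", "paper"))
#' @export
word_schedule <- function(order = sample(rps_choices),
                          onsets_s = c(1, 5, 9)) {
  check_choice(order)
  if (length(order) != 3L || anyDuplicated(order)) {
    stop("`order` must be a permutation of rock, paper, scissors",
         call. = FALSE)
  }
  if (length(onsets_s) != 3L || any(diff(onsets_s) <= 0)) {
    stop("`onsets_s` must be three strictly increasing times", call. = FALSE)
  }
  list(order = order, onsets_s = as.numeric(onsets_s))
}

#' Configuration of the synthetic pupil-trace generator
#'
#' Defaults are calibrated so that a 75-game set reproduces the target trace
#' statistics: grand-mean diameter 4.6 mm and a within-game min-to-max range
#' of 3.8 mm on average (SD across games 1.0 mm). The decision-locked response
#' is a gamma-shaped transient peaking `peak_latency_s` after the onset of the
#' selected word; non-selected onsets may carry smaller "distractor"
#' transients, which (with the additive noise) are what occasionally pull the
#' global maximum away from the selected interval.
#'
#' @param sampling_rate_hz Sampling rate of the trace (Hz).
#' @param trace_duration_s Trace length in seconds; must cover the last onset
#'   plus the ~4-s response window that follows it.
#' @param baseline_mm Resting pupil diameter (mm).
#' @param kernel List: `amplitude_mm` (mean), `amplitude_sd_mm` (SD of the
#'   per-game amplitude draw), `peak_latency_s` (onset-to-peak time),
#'   `shape` (gamma shape; larger = narrower transient).
#' @param distractor List: `amplitude_mm`, `amplitude_sd_mm` and `prob`, the
#'   probability that each non-selected onset carries a transient.
#' @param noise_sd_mm SD of additive white measurement noise (mm).
#' @param clip_floor_mm Positive floor below which samples are clipped (a
#'   physical pupil cannot reach 0 mm); clipping triggers a warning.
#' @return A list of class `"rps_generator_config"`.
#' @export
generator_config <- function(sampling_rate_hz = 120,
                             trace_duration_s = 14,
                             baseline_mm = 3.87,
                             kernel = list(amplitude_mm = 3.2,
                                           amplitude_sd_mm = 1.3,
                                           peak_latency_s = 1.5,
                                           shape = 6),
                             distractor = list(amplitude_mm = 2.5,
                                               amplitude_sd_mm = 1.2,
                                               prob = 0.7),
                             noise_sd_mm = 0.05,
                             clip_floor_mm = 0.5) {
  cfg <- list(sampling_rate_hz = sampling_rate_hz,
              trace_duration_s = trace_duration_s,
              baseline_mm = baseline_mm,
              kernel = kernel, distractor = distractor,
              noise_sd_mm = noise_sd_mm, clip_floor_mm = clip_floor_mm)
  if (sampling_rate_hz <= 0 || trace_duration_s <= 0) {
    stop("sampling rate and duration must be positive", call. = FALSE)
  }
  if (baseline_mm <= 0 || kernel$peak_latency_s <= 0 || kernel$shape <= 0) {
    stop("baseline, latency and shape must be positive", call. = FALSE)
  }
  if (kernel$amplitude_mm < 0 || distractor$amplitude_mm < 0) {
    stop("amplitudes must be >= 0", call. = FALSE)
  }
  if (noise_sd_mm < 0) stop("`noise_sd_mm` must be >= 0", call. = FALSE)
  if (distractor$prob < 0 || distractor$prob > 1) {
    stop("`distractor$prob` must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "rps_generator_config")
}

# Gamma-shaped impulse response, normalised to peak at 1 at t = peak_latency.
# Zero for t < 0 (the pupil cannot anticipate the word).
pupil_kernel <- function(t, peak_latency_s, shape) {
  y <- numeric(length(t))
  pos <- t > 0
  r <- t[pos] / peak_latency_s
  y[pos] <- r^shape * exp(shape * (1 - r))
  y
}

# One amplitude draw, truncated away from zero so every transient is a real
# dilation event. A degenerate zero-amplitude configuration (used to build
# flat baseline traces) stays exactly zero.
draw_amplitude <- function(mean_mm, sd_mm, floor_mm = 0.2) {
  if (mean_mm == 0 && sd_mm == 0) return(0)
  max(rnorm(1, mean_mm, sd_mm), floor_mm)
}

#' Generate one synthetic pupil trace
#'
#' Builds baseline + a decision-locked transient at the selected word's onset
#' + zero or more distractor transients at the non-selected onsets + white
#' noise. Draws from the current RNG stream; wrap in [withr::with_seed()] (or
#' use [generate_game_set()]) for reproducibility.
#'
#' @param schedule A [word_schedule()].
#' @param selected_interval Which interval (1-3) the opponent chose.
#' @param config A [generator_config()].
#' @return A tibble with columns `time_s` and `diameter_mm`.
#' @examples
#' tr <- generate_trace(word_schedule(), 2)
#' range(tr$diameter_mm)
#' @export
generate_trace <- function(schedule, selected_interval,
                           config = generator_config()) {
  stopifnot(inherits(config, "rps_generator_config"))
  if (!selected_interval %in% 1:3) {
    stop("`selected_interval` must be 1, 2 or 3", call. = FALSE)
  }
  onsets <- schedule$onsets_s
  dur <- config$trace_duration_s
  if (max(onsets) + config$kernel$peak_latency_s >= dur) {
    stop("trace too short: the decision peak would fall beyond the trace end",
         call. = FALSE)
  }
  n <- round(dur * config$sampling_rate_hz)
  t <- (seq_len(n) - 1L) / config$sampling_rate_hz

  y <- rep(config$baseline_mm, n)
  k <- config$kernel
  amp_sel <- draw_amplitude(k$amplitude_mm, k$amplitude_sd_mm, floor_mm = 0.5)
  y <- y + amp_sel * pupil_kernel(t - onsets[selected_interval],
                                  k$peak_latency_s, k$shape)
  d <- config$distractor
  for (i in setdiff(1:3, selected_interval)) {
    if (runif(1) < d$prob) {
      amp <- draw_amplitude(d$amplitude_mm, d$amplitude_sd_mm)
      y <- y + amp * pupil_kernel(t - onsets[i], k$peak_latency_s, k$shape)
    }
  }
  if (config$noise_sd_mm > 0) y <- y + rnorm(n, 0, config$noise_sd_mm)

  if (any(y < config$clip_floor_mm)) {
    warning(sprintf("%d sample(s) clipped at the %.2f mm positivity floor",
                    sum(y < config$clip_floor_mm), config$clip_floor_mm))
    y <- pmax(y, config$clip_floor_mm)
  }
  tibble(time_s = t, diameter_mm = y)
}

# Split n_valid across intervals when the caller gives a single total: valid
# games are sampled uniformly without replacement across the whole set.
assign_valid_flags <- function(selected_interval, n_valid) {
  n <- length(selected_interval)
  if (length(n_valid) == 1L) {
    flags <- logical(n)
    flags[sample.int(n, n_valid)] <- TRUE
    return(flags)
  }
  stopifnot(length(n_valid) == 3L)
  flags <- logical(n)
  for (i in 1:3) {
    idx <- which(selected_interval == i)
    if (n_valid[i] > length(idx)) {
      stop(sprintf("interval %d has only %d games but %d valid requested",
                   i, length(idx), n_valid[i]), call. = FALSE)
    }
    flags[sample(idx, n_valid[i])] <- TRUE
  }
  flags
}

#' Generate a set of opponent games with exact validity control
#'
#' Generates `n_games` pupil traces with the requested number of opponent
#' selections per interval, then enforces that exactly `n_valid` of them are
#' "valid" — i.e. the global pupil maximum falls in the selected interval
#' under [decode_games()] — by rejection sampling: each game's trace is
#' regenerated (up to `max_attempts` times) until its decoded interval
#' matches, or deliberately mismatches, the selected interval.
#'
#' @param n_games Number of games.
#' @param interval_counts Length-3 counts of opponent selections per interval;
#'   must sum to `n_games`.
#' @param n_valid Either a single total, or a length-3 per-interval split, of
#'   games whose decoded interval must equal the selected interval.
#' @param config A [generator_config()].
#' @param seed Optional integer seed; the same seed reproduces the set
#'   bit-for-bit.
#' @param n_opponents Games are attributed to this many opponents in
#'   contiguous chronological thirds (the stimuli came from 3 opponents
#'   playing 25 games each).
#' @param max_attempts Rejection-sampling cap per game; exceeding it signals
#'   that the configuration makes the requested validity unreachable.
#' @return A tibble of class `"rps_games"`, one row per game, with columns
#'   `game_id`, `opponent_id`, `order` and `onsets_s` (list-columns),
#'   `selected_interval`, `opponent_choice`, `trace` (list-column of trace
#'   tibbles), plus the decode columns of [decode_games()]. The generator
#'   config and seed are attached as attributes `config` and `seed`.
#' @examples
#' gs <- generate_game_set(n_games = 6, interval_counts = c(2, 2, 2),
#'                         n_valid = 4, seed = 1)
#' validity(gs)
#' @export
generate_game_set <- function(n_games = 75,
                              interval_counts = c(28, 25, 22),
                              n_valid = 45,
                              config = generator_config(),
                              seed = NULL,
                              n_opponents = 3,
                              max_attempts = 1000) {
  if (length(interval_counts) != 3L || sum(interval_counts) != n_games) {
    stop("`interval_counts` must be 3 counts summing to `n_games`",
         call. = FALSE)
  }
  if (sum(n_valid) > n_games || any(n_valid < 0)) {
    stop("`n_valid` must lie between 0 and `n_games`", call. = FALSE)
  }
  games <- with_seed_if(seed, {
    sel <- rep.int(1:3, interval_counts)
    sel <- sel[sample.int(length(sel))]
    valid_target <- assign_valid_flags(sel, n_valid)
    rows <- purrr::map(seq_len(n_games), function(g) {
      sch <- word_schedule()
      for (attempt in seq_len(max_attempts)) {
        tr <- generate_trace(sch, sel[g], config)
        dec <- decode_trace(tr$time_s, tr$diameter_mm, sch$onsets_s)
        if ((dec$decoded_interval == sel[g]) == valid_target[g]) {
          return(tibble(
            game_id = g,
            order = list(sch$order),
            onsets_s = list(sch$onsets_s),
            selected_interval = sel[g],
            opponent_choice = sch$order[sel[g]],
            trace = list(tr),
            decoded_interval = dec$decoded_interval,
            decoded_choice = sch$order[dec$decoded_interval],
            peak_time_s = dec$peak_time_s,
            peak_value = dec$peak_value,
            valid = valid_target[g]
          ))
        }
      }
      stop(sprintf(paste0("game %d: could not reach the requested validity ",
                          "in %d attempts; the generator config makes it ",
                          "unreachable"), g, max_attempts), call. = FALSE)
    })
    dplyr::bind_rows(rows)
  })
  games <- dplyr::mutate(
    games,
    opponent_id = ceiling(.data$game_id * n_opponents / n_games),
    .after = "game_id")
  attr(games, "config") <- config
  attr(games, "seed") <- seed
  class(games) <- c("rps_games", class(tibble()))
  games
}

fixture_env <- new.env(parent = emptyenv())

#' The 75-game reference fixture
#'
#' A deterministic set of 75 opponent games with 28/25/22 selections of the
#' first/second/third interval, of which exactly 45 (60%) are decoder-valid,
#' split (16, 15, 14) across intervals so that the 100%-validity subset
#' selection (10 valid games per interval) always succeeds. Generated from a
#' fixed internal seed; repeated calls return the identical set (cached).
#'
#' @return An `"rps_games"` tibble of 75 games (see [generate_game_set()]).
#' @examples
#' \donttest{
#' validity(reference_fixture())  # 45 / 75 = 60%
#' }
#' @export
reference_fixture <- function() {
  if (is.null(fixture_env$games)) {
    fixture_env$games <- generate_game_set(
      n_games = 75, interval_counts = c(28, 25, 22),
      n_valid = c(16, 15, 14), config = generator_config(),
      seed = 20130903L)
  }
  fixture_env$games
}

#' Trace summary statistics of a game set
#'
#' @param games An `"rps_games"` tibble with a `trace` list-column.
#' @return A one-row tibble: `mean_diameter_mm` (grand mean over all samples
#'   of all games), `mean_range_mm` (per-game max minus min, averaged) and
#'   `sd_range_mm` (SD of the per-game ranges across games).
#' @examples
#' gs <- generate_game_set(n_games = 4, interval_counts = c(2, 1, 1),
#'                         n_valid = 2, seed = 1)
#' summarize_traces(gs)
#' @export
summarize_traces <- function(games) {
  if (nrow(games) == 0L) stop("empty game set", call. = FALSE)
  ranges <- purrr::map_dbl(games$trace,
                           ~ max(.x$diameter_mm) - min(.x$diameter_mm))
  tibble(
    mean_diameter_mm = mean(unlist(purrr::map(games$trace, "diameter_mm"))),
    mean_range_mm = mean(ranges),
    sd_range_mm = sd(ranges)
  )
}
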