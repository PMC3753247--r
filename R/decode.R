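# Core marker: attribute the time of the global diameter maximum to the word
# interval it follows. Window starts at the first onset (a peak before any
# word cannot follow a word); ties at the maximum break to the earliest
# sample (which.max's behaviour), so the decode is fully deterministic.
decode_trace <- function(time_s, value, onsets_s) {
  if (max(time_s) < max(onsets_s)) {
    stop("trace ends before the last word onset", call. = FALSE)
  }
  in_window <- which(time_s >= onsets_s[1])
  if (length(in_window) == 0L) stop("empty analysis window", call. = FALSE)
  peak <- in_window[which.max(value[in_window])]
  list(decoded_interval = findInterval(time_s[peak], onsets_s),
       peak_time_s = time_s[peak],
       peak_value = value[peak])
}

#' Decode the opponent's choice from each game's pupil trace
#'
#' For every game, finds the global maximum of the pupil diameter in the
#' analysis window (first word onset to trace end) and attributes it to the
#' latest word onset at or before the peak. The decoded choice is the word
#' spoken in that interval; a game is *valid* when the decoded interval
#' equals the opponent's selected interval.
#'
#' Because the argmax is invariant under positive affine transforms,
#' decoding gives identical results on raw and z-normalised traces; pass
#' `value_col = "diameter_z"` after [znormalize()] to check.
#'
#' @param games An `"rps_games"` tibble (see [generate_game_set()]).
#' @param value_col Trace column to maximise (default `"diameter_mm"`).
#' @param smooth_width_s Optional moving-average width in seconds applied
#'   before the argmax; `NULL` (default) applies no smoothing.
#' @return `games` with (re)computed columns `decoded_interval`,
#'   `decoded_choice`, `peak_time_s`, `peak_value` and `valid`.
#' @examples
#' gs <- generate_game_set(n_games = 3, interval_counts = c(1, 1, 1),
#'                         n_valid = 3, seed = 2)
#' decode_games(gs)$decoded_interval
#' @export
decode_games <- function(games, value_col = "diameter_mm",
                         smooth_width_s = NULL) {
  if (nrow(games) == 0L) stop("empty game set", call. = FALSE)
  dec <- purrr::map2(games$trace, games$onsets_s, function(tr, onsets) {
    v <- tr[[value_col]]
    if (!is.null(smooth_width_s)) {
      w <- max(1L, round(smooth_width_s * nrow(tr) / max(tr$time_s)))
      if (w %% 2L == 0L) w <- w + 1L
      sm <- stats::filter(v, rep(1 / w, w), sides = 2)
      v <- ifelse(is.na(sm), v, as.numeric(sm))
    }
    decode_trace(tr$time_s, v, onsets)
  })
  games$decoded_interval <- purrr::map_int(dec, ~ as.integer(.x$decoded_interval))
  games$decoded_choice <- purrr::map2_chr(games$order, games$decoded_interval,
                                          ~ .x[.y])
  games$peak_time_s <- purrr::map_dbl(dec, "peak_time_s")
  games$peak_value <- purrr::map_dbl(dec, "peak_value")
  games$valid <- games$decoded_interval == games$selected_interval
  games
}

#' Z-normalise pupil traces within each opponent
#'
#' Pools all samples of all games belonging to one opponent, and transforms
#' each sample to `(x - pooled mean) / pooled SD`. Adds a `diameter_z` column
#' to every trace; the per-opponent normalisation statistics are attached as
#' attribute `"norm_stats"`.
#'
#' @param games An `"rps_games"` tibble with an `opponent_id` column.
#' @return `games` with `diameter_z` added to each trace tibble.
#' @examples
#' gs <- generate_game_set(n_games = 3, interval_counts = c(1, 1, 1),
#'                         n_valid = 3, seed = 3)
#' zs <- znormalize(gs)
#' mean(unlist(lapply(zs$trace, `[[`, "diameter_z")))  # ~0
#' @export
znormalize <- function(games) {
  if (nrow(games) == 0L) stop("empty game set", call. = FALSE)
  stats_tbl <- games |>
    dplyr::group_by(.data$opponent_id) |>
    dplyr::summarise(
      mean_mm = mean(unlist(purrr::map(.data$trace, "diameter_mm"))),
      sd_mm = sd(unlist(purrr::map(.data$trace, "diameter_mm"))),
      .groups = "drop")
  if (any(stats_tbl$sd_mm == 0)) {
    stop("pooled SD is zero for at least one opponent (constant traces)",
         call. = FALSE)
  }
  lut <- stats_tbl |> tibble::column_to_rownames("opponent_id")
  games$trace <- purrr::map2(games$trace, games$opponent_id, function(tr, op) {
    s <- lut[as.character(op), ]
    tr$diameter_z <- (tr$diameter_mm - s$mean_mm) / s$sd_mm
    tr
  })
  attr(games, "norm_stats") <- stats_tbl
  games
}

#' Marker validity of a game set
#'
#' The fraction of games in which the decoded interval (global pupil maximum)
#' equals the opponent's selected interval. Decodes first if the set has not
#' been decoded.
#'
#' @param games An `"rps_games"` tibble.
#' @return A one-row tibble: `n_valid`, `n_total`, `fraction`.
#' @examples
#' \donttest{
#' validity(reference_fixture())  # 45, 75, 0.6
#' }
#' @export
validity <- function(games) {
  if (nrow(games) == 0L) stop("empty game set", call. = FALSE)
  if (!"valid" %in% names(games)) games <- decode_games(games)
  tibble(n_valid = sum(games$valid), n_total = nrow(games),
         fraction = mean(games$valid))
}
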