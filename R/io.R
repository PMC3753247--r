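#' Write a game set to disk
#'
#' Writes one CSV trace per game (columns `time_s`, `diameter_mm`, full
#' double precision so that decode argmax survives a round-trip) plus a JSON
#' manifest indexing the games: schedule, opponent choice, trace path and an
#' MD5 checksum per trace file. Output is deterministic for a fixed input.
#'
#' @param games A nonempty `"rps_games"` tibble.
#' @param out_dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @examples
#' gs <- generate_game_set(n_games = 2, interval_counts = c(1, 1, 0),
#'                         n_valid = 2, seed = 1)
#' d <- tempfile(); write_game_set(gs, d)
#' list.files(d)
#' @export
write_game_set <- function(games, out_dir) {
  if (nrow(games) == 0L) {
    stop("refusing to write an empty game set", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trace_paths <- sprintf("game_%03d.csv", games$game_id)
  purrr::walk2(games$trace, trace_paths, function(tr, path) {
    readr::write_csv(tr[c("time_s", "diameter_mm")],
                     file.path(out_dir, path))
  })
  checksums <- unname(tools::md5sum(file.path(out_dir, trace_paths)))
  cfg <- attr(games, "config")
  manifest <- list(
    schema_version = 1L,
    seed = attr(games, "seed"),
    config = if (is.null(cfg)) NULL else unclass(cfg),
    games = purrr::pmap(
      list(games$game_id, games$opponent_id, games$order, games$onsets_s,
           games$selected_interval, games$opponent_choice, trace_paths,
           checksums),
      function(id, op, ord, ons, sel, choice, path, md5) {
        list(game_id = id, opponent_id = op, word_order = ord,
             onsets_s = ons, selected_interval = sel,
             opponent_choice = choice, trace_path = path, md5 = md5)
      })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(manifest_path)
}

#' Read a game set from a manifest
#'
#' Round-trips with [write_game_set()]: trace files are checked to exist and
#' to match their manifest checksums, and each trace must parse as numeric
#' `time_s`, `diameter_mm` columns with uniform time steps.
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [write_game_set()].
#' @param check_checksums Verify the per-file MD5s (default `TRUE`).
#' @return An `"rps_games"` tibble.
#' @export
read_game_set <- function(manifest_path, check_checksums = TRUE) {
  manifest <- jsonlite::read_json(manifest_path)
  base <- dirname(manifest_path)
  rows <- purrr::map(manifest$games, function(g) {
    path <- file.path(base, g$trace_path)
    if (!file.exists(path)) {
      stop(sprintf("game %s: trace file %s is missing",
                   g$game_id, g$trace_path), call. = FALSE)
    }
    if (check_checksums && !is.null(g$md5) &&
        unname(tools::md5sum(path)) != g$md5) {
      stop(sprintf("game %s: checksum mismatch for %s",
                   g$game_id, g$trace_path), call. = FALSE)
    }
    tr <- readr::read_csv(path, col_types = readr::cols(
      time_s = readr::col_double(), diameter_mm = readr::col_double()))
    if (anyNA(tr$time_s) || anyNA(tr$diameter_mm)) {
      stop(sprintf("game %s: non-numeric values in %s",
                   g$game_id, g$trace_path), call. = FALSE)
    }
    steps <- diff(tr$time_s)
    if (any(steps <= 0) ||
        (max(steps) - min(steps)) > 1e-6 * stats::median(steps)) {
      stop(sprintf("game %s: time axis not uniformly increasing",
                   g$game_id), call. = FALSE)
    }
    tibble(
      game_id = as.integer(g$game_id),
      opponent_id = as.numeric(g$opponent_id),
      order = list(unlist(g$word_order)),
      onsets_s = list(as.numeric(unlist(g$onsets_s))),
      selected_interval = as.integer(g$selected_interval),
      opponent_choice = g$opponent_choice,
      trace = list(tr)
    )
  })
  games <- dplyr::bind_rows(rows)
  if (!is.null(manifest$config)) {
    cfg <- manifest$config
    cfg$kernel <- as.list(cfg$kernel)
    cfg$distractor <- as.list(cfg$distractor)
    attr(games, "config") <- structure(cfg, class = "rps_generator_config")
  }
  attr(games, "seed") <- manifest$seed
  class(games) <- c("rps_games", class(tibble()))
  games
}
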