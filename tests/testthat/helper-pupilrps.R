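# Noise-free, distractor-free config: the trace is baseline plus exactly one
# decision-locked transient, so the decode is known by construction.
clean_config <- function(amplitude = 2, latency = 1.5, rate = 40) {
  generator_config(
    sampling_rate_hz = rate,
    kernel = list(amplitude_mm = amplitude, amplitude_sd_mm = 0,
                  peak_latency_s = latency, shape = 6),
    distractor = list(amplitude_mm = 0, amplitude_sd_mm = 0, prob = 0),
    noise_sd_mm = 0)
}

# Flat trace at baseline: no transients, no noise.
flat_config <- function() clean_config(amplitude = 0)

# Build a minimal games tibble directly from diameter vectors (sampled at
# `rate` Hz, onsets at 1/5/9 s, word order rock/paper/scissors), bypassing
# the generator. Handy for hand-constructed decode cases.
manual_games <- function(diameters, selected = NULL, rate = 10) {
  n <- length(diameters)
  if (is.null(selected)) selected <- rep(1L, n)
  tibble::tibble(
    game_id = seq_len(n),
    opponent_id = 1,
    order = rep(list(c("rock", "paper", "scissors")), n),
    onsets_s = rep(list(c(1, 5, 9)), n),
    selected_interval = as.integer(selected),
    opponent_choice = purrr::map2_chr(
      rep(list(c("rock", "paper", "scissors")), n), selected, ~ .x[.y]),
    trace = purrr::map(diameters, function(d) {
      tibble::tibble(time_s = (seq_along(d) - 1) / rate, diameter_mm = d)
    })
  )
}

# Small fast game set for structural tests; regenerated per call.
small_set <- function(n_valid = 4, seed = 101) {
  generate_game_set(n_games = 6, interval_counts = c(2, 2, 2),
                    n_valid = n_valid, config = clean_config_noisy(),
                    seed = seed)
}

# Like clean_config but with distractors and noise on, at a reduced sampling
# rate, so both valid and invalid games are reachable quickly.
clean_config_noisy <- function(rate = 40) {
  generator_config(sampling_rate_hz = rate)
}
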