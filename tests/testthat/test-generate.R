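test_that("word schedules are validated", {
  ws <- word_schedule(c("scissors", "rock", "paper"))
  expect_equal(ws$onsets_s, c(1, 5, 9))
  expect_equal(diff(ws$onsets_s), c(4, 4))
  expect_error(word_schedule(c("rock", "rock", "paper")), "permutation")
  expect_error(word_schedule(onsets_s = c(1, 5, 5)), "strictly increasing")
})

test_that("a noise-free single-kernel trace peaks exactly at onset + latency", {
  cfg <- clean_config(latency = 1.5, rate = 40)
  ws <- word_schedule(c("rock", "paper", "scissors"))
  tr <- generate_trace(ws, 2, cfg)
  expect_equal(nrow(tr), round(14 * 40))
  expect_equal(tr$time_s[which.max(tr$diameter_mm)], 5 + 1.5)
})

test_that("zero amplitudes and zero noise give a flat trace at baseline", {
  tr <- generate_trace(word_schedule(), 1, flat_config())
  expect_true(all(tr$diameter_mm == flat_config()$baseline_mm))
})

test_that("generation errors on impossible timing or interval", {
  cfg <- generator_config(trace_duration_s = 5)
  expect_error(generate_trace(word_schedule(), 3, cfg), "beyond the trace end")
  expect_error(generate_trace(word_schedule(), 4, clean_config()),
               "selected_interval")
  expect_error(generator_config(sampling_rate_hz = -1), "positive")
  expect_error(generator_config(noise_sd_mm = -0.1), "noise_sd_mm")
})

test_that("game sets honour requested interval counts and exact validity", {
  gs <- generate_game_set(n_games = 9, interval_counts = c(4, 3, 2),
                          n_valid = 5, config = clean_config_noisy(),
                          seed = 11)
  expect_equal(as.vector(table(gs$selected_interval)), c(4, 3, 2))
  expect_equal(sum(gs$valid), 5)
  # re-decoding from the raw traces confirms the stored flags
  redecoded <- decode_games(gs)
  expect_equal(redecoded$decoded_interval, gs$decoded_interval)
  expect_equal(sum(redecoded$valid), 5)
  # the word order invariant: opponent_choice sits at selected_interval
  expect_equal(purrr::map2_chr(gs$order, gs$selected_interval, ~ .x[.y]),
               gs$opponent_choice)
  expect_error(generate_game_set(n_games = 5, interval_counts = c(2, 2, 2)),
               "summing")
})

test_that("a fully valid set decodes to its selected intervals everywhere", {
  gs <- generate_game_set(n_games = 6, interval_counts = c(2, 2, 2),
                          n_valid = 6, config = clean_config_noisy(),
                          seed = 12)
  expect_true(all(decode_games(gs)$valid))
})

test_that("identical seeds reproduce game sets bit-for-bit", {
  a <- small_set(seed = 42)
  b <- small_set(seed = 42)
  expect_identical(a$trace, b$trace)
  expect_identical(a$opponent_choice, b$opponent_choice)
  c <- small_set(seed = 43)
  expect_false(identical(a$trace, c$trace))
})

test_that("all generated samples stay positive", {
  gs <- small_set(seed = 5)
  expect_true(all(purrr::map_lgl(gs$trace, ~ all(.x$diameter_mm > 0))))
})

test_that("trace summaries match hand computation and degenerate cases", {
  # two games with within-game ranges 2 and 4 -> mean range 3
  g <- manual_games(list(c(1, 2, 3), c(2, 6, 4)))
  s <- summarize_traces(g)
  expect_equal(s$mean_range_mm, 3)
  expect_equal(s$sd_range_mm, sd(c(2, 4)))
  expect_equal(s$mean_diameter_mm, mean(c(1, 2, 3, 2, 6, 4)))
  # flat traces have zero range
  flat <- manual_games(list(rep(2, 5), rep(3, 5)))
  expect_equal(summarize_traces(flat)$mean_range_mm, 0)
  expect_equal(summarize_traces(flat)$sd_range_mm, 0)
  expect_error(summarize_traces(manual_games(list())), "empty")
})

test_that("the reference fixture has the documented structure", {
  f <- reference_fixture()
  expect_equal(nrow(f), 75)
  expect_equal(as.vector(table(f$selected_interval)), c(28, 25, 22))
  expect_equal(sum(f$valid), 45)
  # enough valid games per interval for the 100%-validity selection
  valid_per_interval <- table(f$selected_interval[f$valid])
  expect_true(all(valid_per_interval >= 10))
  # cached: repeated calls return the identical object
  expect_identical(f, reference_fixture())
  # three opponents, 25 games each, in chronological thirds
  expect_equal(as.vector(table(f$opponent_id)), c(25, 25, 25))
})

test_that("default calibration reproduces the target trace statistics", {
  # Deterministic check on the fixture; the ±10% band reflects sampling
  # variability of 75-game statistics around the calibration targets
  # (4.6 mm grand mean, 3.8 mm mean range, 1.0 mm range SD).
  s <- summarize_traces(reference_fixture())
  expect_lt(abs(s$mean_diameter_mm - 4.6) / 4.6, 0.10)
  expect_lt(abs(s$mean_range_mm - 3.8) / 3.8, 0.10)
  expect_lt(abs(s$sd_range_mm - 1.0) / 1.0, 0.10)
})
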