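# Independent oracle: direct term-by-term summation of the binomial tail.
naive_tail <- function(n, k, p = 1 / 3) {
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

test_that("binomial tail matches brute-force summation for all n <= 30", {
  for (n in 1:30) {
    expected <- vapply(0:n, function(k) naive_tail(n, k), numeric(1))
    got <- binomial_tail(n, 0:n)$p_value
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("binomial tail reproduces the printed individual result", {
  expect_equal(round(binomial_tail(75, 37)$p_value, 3), 0.003)
  expect_true(binomial_tail(75, 37)$significant)  # 0.003 < 0.005
  expect_equal(binomial_tail(1, 1)$p_value, 1 / 3)
})

test_that("binomial tail is normalised at k = 0 and monotone in k", {
  expect_equal(binomial_tail(1:100, 0)$p_value, rep(1, 100))
  for (n in c(5, 20, 75)) {
    p <- binomial_tail(n, 0:n)$p_value
    expect_true(all(diff(p) < 0))
  }
  expect_error(binomial_tail(10, 11), "k <= n")
  expect_error(binomial_tail(10, 5, p_chance = 1), "p_chance")
})

test_that("bonferroni correction is alpha over m", {
  expect_equal(bonferroni(0.05, 10), 0.005)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(0.05, 5), 0.01)
  expect_error(bonferroni(0.05, 0), "m")
})

test_that("significance boundary is the least k with tail below alpha", {
  b <- significance_boundary(200)
  expect_true(is.na(b$k_min[1]))  # n = 1: tail at k = 1 is 1/3 > 0.05
  # brute-force verification over all n
  for (n in c(2, 7, 30, 75, 200)) {
    tails <- vapply(0:n, function(k) naive_tail(n, k), numeric(1))
    hit <- which(tails < 0.05)
    expected <- if (length(hit)) hit[1] - 1L else NA_integer_
    expect_equal(b$k_min[n], expected)
  }
  expect_lte(b$k_min[75], 37)  # 37/75 is already significant at 5%
  # boundary fraction decreases toward chance with n
  frac <- b$k_min / b$n
  expect_true(all(frac > 1 / 3, na.rm = TRUE))
  expect_lt(frac[200], frac[30])
  expect_true(is.na(b$k_min[1]) || b$k_min[1] >= 1)
  expect_true(all(diff(b$k_min[!is.na(b$k_min)]) >= 0))  # k_min nondecreasing
})

test_that("learning curves flag sequential significance correctly", {
  all_win <- tibble::tibble(game_index = 1:75, cumulative_wins = 1:75)
  lc <- learning_curve(all_win)
  expect_lt(first_significant_game(lc), 20)
  all_loss <- tibble::tibble(game_index = 1:75,
                             cumulative_wins = rep(0, 75))
  expect_true(is.na(first_significant_game(learning_curve(all_loss))))
  # significance at n = 75 depends only on (75, 37), wherever the wins fall
  wins <- c(rep(0, 38), rep(1, 37))
  sess <- tibble::tibble(game_index = 1:75, cumulative_wins = cumsum(wins))
  lc2 <- learning_curve(sess)
  expect_true(lc2$significant[75])
  expect_equal(round(lc2$p_value[75], 3), 0.003)
  expect_error(learning_curve(all_win[0, ]), "empty")
})

test_that("t-tests handle standard and degenerate inputs as documented", {
  # non-degenerate one-sample agrees with stats::t.test
  x <- c(0.40, 0.52, 0.61, 0.47, 0.55)
  got <- rps_t_test(x, mu = 1 / 3)
  ref <- t.test(x, mu = 1 / 3)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
  expect_equal(got$df, 4)
  # unpaired uses the pooled-variance Student form: df = n1 + n2 - 2
  y <- c(0.30, 0.36, 0.33, 0.41)
  got2 <- rps_t_test(x, y, kind = "unpaired")
  ref2 <- t.test(x, y, var.equal = TRUE)
  expect_equal(got2$statistic, unname(ref2$statistic))
  expect_equal(got2$df, length(x) + length(y) - 2)
  # identical groups, paired: t = 0, p = 1
  same <- rps_t_test(x, x, kind = "paired")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # group constant at the null value
  const <- rps_t_test(rep(1 / 3, 6), mu = 1 / 3)
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)
  # zero variance but off the null: undefined t reported as p = 0
  expect_warning(off <- rps_t_test(rep(0.6, 6), mu = 1 / 3), "zero variance")
  expect_equal(off$p_value, 0)
  expect_error(rps_t_test(0.5), "at least 2")
})

test_that("the per-player test keeps its type-I rate under the null strategy", {
  # 1,000 uniform-random 75-game sessions: the fraction declared significant
  # at the corrected 0.005 level must not exceed nominal plus sampling error
  f <- reference_fixture()
  withr::with_seed(1234, {
    sig <- replicate(1000, {
      s <- play_session(f, strategy_uniform(), shuffle = FALSE)
      binomial_tail(75, sum(s$win))$significant
    })
  })
  se <- sqrt(0.005 * 0.995 / 1000)
  expect_lte(mean(sig), 0.005 + 3 * se)
})
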