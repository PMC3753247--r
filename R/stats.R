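#' Exact one-sided binomial test for k or more wins in n games
#'
#' Upper-tail probability \eqn{p = \sum_{k \le i \le n} C(n,i) p_c^i
#' (1-p_c)^{n-i}} of observing `k` or more wins by chance, computed through
#' the regularized incomplete beta function (numerically stable for large
#' `n`). The test is one-sided because learning can only be expected to
#' improve performance. Vectorised over `n` and `k`.
#'
#' @param n Number of games.
#' @param k Number of wins.
#' @param p_chance Chance win probability (default 1/3: one winning move out
#'   of three).
#' @param alpha Nominal significance level.
#' @param m_comparisons Number of simultaneous tests; `alpha` is
#'   Bonferroni-corrected by this factor before flagging significance.
#' @return A tibble with columns `n`, `k`, `p_chance`, `p_value`, `alpha`,
#'   `alpha_corrected`, `significant`.
#' @examples
#' binomial_tail(75, 37)$p_value       # 0.003 to 3 decimals
#' binomial_tail(1, 1)$p_value         # 1/3
#' @export
binomial_tail <- function(n, k, p_chance = 1 / 3, alpha = 0.05,
                          m_comparisons = 10) {
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n", call. = FALSE)
  if (any(p_chance <= 0) || any(p_chance >= 1)) {
    stop("`p_chance` must lie strictly in (0, 1)", call. = FALSE)
  }
  alpha_corrected <- bonferroni(alpha, m_comparisons)
  p <- pbinom(k - 1, n, p_chance, lower.tail = FALSE)
  tibble(n = n, k = k, p_chance = p_chance, p_value = p,
         alpha = alpha, alpha_corrected = alpha_corrected,
         significant = p < alpha_corrected)
}

#' Bonferroni-corrected alpha level
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m Number of simultaneous tests.
#' @return `alpha / m`.
#' @examples
#' bonferroni(0.05, 10)  # 0.005
#' @export
bonferroni <- function(alpha, m) {
  if (any(m < 1)) stop("`m` must be >= 1", call. = FALSE)
  if (any(alpha <= 0) || any(alpha >= 1)) {
    stop("`alpha` must lie strictly in (0, 1)", call. = FALSE)
  }
  alpha / m
}

#' Exact-binomial significance boundary per number of games
#'
#' For each `n` in `1:n_max`, the least win count `k_min` whose one-sided
#' binomial tail probability falls below `alpha` — the "significance line"
#' plotted over a cumulative-wins learning curve. `NA` where no win count
#' qualifies (small `n`).
#'
#' @param n_max Largest number of games.
#' @param alpha Significance level applied at each `n`.
#' @param p_chance Chance win probability.
#' @return A tibble with columns `n` and `k_min` (integer, possibly `NA`).
#' @examples
#' significance_boundary(5)      # all NA up to n = 4
#' significance_boundary(75)$k_min[75]
#' @export
significance_boundary <- function(n_max, alpha = 0.05, p_chance = 1 / 3) {
  stopifnot(n_max >= 1)
  k_min <- purrr::map_int(seq_len(n_max), function(n) {
    tails <- pbinom(0:n - 1, n, p_chance, lower.tail = FALSE)
    hit <- which(tails < alpha)
    if (length(hit) == 0L) NA_integer_ else as.integer(hit[1] - 1L)
  })
  tibble(n = seq_len(n_max), k_min = k_min)
}

#' Sequential significance along one session's learning curve
#'
#' After every game, tests the cumulative win count over *all preceding
#' games* with the exact one-sided binomial test, at the
#' Bonferroni-corrected level.
#'
#' @param session An `"rps_session"` tibble from [play_session()].
#' @param alpha Family-wise significance level.
#' @param m_comparisons Number of players tested simultaneously (default 10).
#' @param p_chance Chance win probability.
#' @return A tibble of class `"rps_learning_curve"`: `game_index`,
#'   `cumulative_wins`, `p_value`, `significant`; the first significant game
#'   index (or `NA`) is attached as attribute `"first_significant_game"` and
#'   returned by [first_significant_game()].
#' @examples
#' \donttest{
#' s <- play_session(reference_fixture(), strategy_always_follow(), seed = 1)
#' first_significant_game(learning_curve(s))
#' }
#' @export
learning_curve <- function(session, alpha = 0.05, m_comparisons = 10,
                           p_chance = 1 / 3) {
  if (nrow(session) == 0L) stop("empty session", call. = FALSE)
  bt <- binomial_tail(session$game_index, session$cumulative_wins,
                      p_chance = p_chance, alpha = alpha,
                      m_comparisons = m_comparisons)
  out <- tibble(game_index = session$game_index,
                cumulative_wins = session$cumulative_wins,
                p_value = bt$p_value,
                significant = bt$significant)
  first_sig <- which(out$significant)[1]
  attr(out, "first_significant_game") <-
    if (is.na(first_sig)) NA_integer_ else as.integer(first_sig)
  attr(out, "alpha_corrected") <- bonferroni(alpha, m_comparisons)
  attr(out, "p_chance") <- p_chance
  class(out) <- c("rps_learning_curve", class(out))
  out
}

#' @rdname learning_curve
#' @param curve An `"rps_learning_curve"` tibble.
#' @export
first_significant_game <- function(curve) {
  attr(curve, "first_significant_game")
}

#' Group-level t-tests on win fractions
#'
#' One-sample (against a chance constant, default 1/3), paired or unpaired
#' two-sided Student t-tests; the unpaired test uses the pooled-variance
#' (equal-variance) form with `n1 + n2 - 2` degrees of freedom unless
#' `var_equal = FALSE`.
#'
#' Zero-variance inputs, which arise in deterministic simulations (e.g.
#' every always-follow player winning the same number of games), are handled
#' explicitly: if the means also agree the result is `statistic = 0`,
#' `p_value = 1`; if the means differ, `p_value = 0` with a signed infinite
#' statistic and a warning, since the t statistic is undefined.
#'
#' @param x Numeric vector of win fractions (group A).
#' @param y Optional second group (paired or unpaired kinds).
#' @param mu Null value for the one-sample test (default chance, 1/3).
#' @param kind `"one_sample"`, `"paired"` or `"unpaired"`.
#' @param var_equal Pooled-variance Student t for the unpaired test
#'   (default `TRUE`); `FALSE` gives Welch.
#' @return A one-row tibble: `kind`, `mean_a`, `mean_b`, `estimate`
#'   (mean difference from the null), `statistic`, `df`, `p_value`.
#' @examples
#' rps_t_test(c(0.5, 0.6, 0.55, 0.62), mu = 1 / 3)
#' @export
rps_t_test <- function(x, y = NULL, mu = 1 / 3,
                       kind = c("one_sample", "paired", "unpaired"),
                       var_equal = TRUE) {
  kind <- match.arg(kind)
  if (kind != "one_sample" && is.null(y)) {
    stop("`y` is required for paired/unpaired tests", call. = FALSE)
  }
  if (length(x) < 2L || (kind != "one_sample" && length(y) < 2L)) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  diffs <- switch(kind,
    one_sample = x - mu,
    paired = x - y,
    unpaired = NULL)
  degenerate <- if (kind == "unpaired") {
    sd(x) == 0 && sd(y) == 0
  } else {
    sd(diffs) == 0
  }
  mean_b <- if (is.null(y)) mu else mean(y)
  estimate <- mean(x) - mean_b
  if (degenerate) {
    if (estimate == 0) {
      stat <- 0; p <- 1
    } else {
      warning("zero variance with unequal means: t is undefined; reporting p = 0")
      stat <- sign(estimate) * Inf; p <- 0
    }
    df <- switch(kind, one_sample = length(x) - 1L,
                 paired = length(x) - 1L,
                 unpaired = length(x) + length(y) - 2L)
  } else {
    ht <- switch(kind,
      one_sample = stats::t.test(x, mu = mu),
      paired = stats::t.test(x, y, paired = TRUE),
      unpaired = stats::t.test(x, y, var.equal = var_equal))
    stat <- unname(ht$statistic); df <- unname(ht$parameter)
    p <- ht$p.value
  }
  tibble(kind = kind, mean_a = mean(x), mean_b = mean_b,
         estimate = estimate, statistic = stat, df = as.numeric(df),
         p_value = p)
}
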