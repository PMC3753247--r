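#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-player results of a simulated condition
#'
#' @param x An `"rps_condition"` from [run_condition()].
#' @param ... Unused.
#' @return One row per player: wins `k` of `n` games, `win_fraction`, the
#'   exact binomial `p_value` and its Bonferroni-corrected `significant`
#'   flag.
#' @method tidy rps_condition
#' @export
tidy.rps_condition <- function(x, ...) {
  dplyr::mutate(x$players, condition = x$condition, .before = 1)
}

#' One-row summary of a simulated condition
#'
#' @param x An `"rps_condition"` from [run_condition()].
#' @param ... Unused.
#' @return A one-row tibble: mean win percentage, group t-test against
#'   chance (33%), and the count of individually significant players.
#' @method glance rps_condition
#' @export
glance.rps_condition <- function(x, ...) {
  tibble(
    condition = x$condition,
    n_players = nrow(x$players),
    n_games = x$n_games,
    mean_win_pct = 100 * mean(x$players$win_fraction),
    t_statistic = x$group$statistic,
    df = x$group$df,
    p_value = x$group$p_value,
    n_significant = sum(x$players$significant)
  )
}

#' @rdname tidy.rps_condition
#' @method tidy rps_study
#' @export
tidy.rps_study <- function(x, ...) {
  purrr::map(x$conditions, tidy) |> dplyr::bind_rows()
}

#' @rdname glance.rps_condition
#' @method glance rps_study
#' @export
glance.rps_study <- function(x, ...) {
  purrr::map(x$conditions, glance) |> dplyr::bind_rows()
}

#' Plot group and individual win percentages per condition
#'
#' Bars show each condition's mean win percentage, circles the individual
#' players; the dotted line marks chance (33.3%) and the dashed line the
#' ceiling set by the marker validity of the game set (e.g. 60% when 45 of
#' 75 games are valid).
#'
#' @param object An `"rps_study"` from [replicate_study()].
#' @param validity_ceiling Win percentage attainable by a perfect
#'   decoder-follower (default 60).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rps_study
#' @export
autoplot.rps_study <- function(object, validity_ceiling = 60, ...) {
  players <- tidy(object)
  means <- glance(object)
  players$condition <- factor(players$condition, levels = rps_condition_names)
  means$condition <- factor(means$condition, levels = rps_condition_names)
  ggplot2::ggplot(means, ggplot2::aes(x = .data$condition,
                                      y = .data$mean_win_pct)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_jitter(data = players,
                         ggplot2::aes(y = 100 * .data$win_fraction),
                         width = 0.1, shape = 1) +
    ggplot2::geom_hline(yintercept = 100 / 3, linetype = "dotted",
                        colour = "red") +
    ggplot2::geom_hline(yintercept = validity_ceiling, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "games won (%)") +
    ggplot2::theme_minimal()
}

#' Plot one learning curve against the significance boundary
#'
#' Cumulative wins per game, with the chance line (1/3 of games) and the
#' exact-binomial significance boundary at the curve's corrected alpha.
#'
#' @param object An `"rps_learning_curve"` from [learning_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rps_learning_curve
#' @export
autoplot.rps_learning_curve <- function(object, ...) {
  n_max <- max(object$game_index)
  boundary <- significance_boundary(n_max, alpha = 0.05,
                                    p_chance = attr(object, "p_chance"))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$game_index,
                                       y = .data$cumulative_wins)) +
    ggplot2::geom_step() +
    ggplot2::geom_line(data = boundary,
                       ggplot2::aes(x = .data$n, y = .data$k_min),
                       colour = "darkgreen", na.rm = TRUE) +
    ggplot2::geom_abline(slope = attr(object, "p_chance"), intercept = 0,
                         colour = "red") +
    ggplot2::labs(x = "game", y = "cumulative wins") +
    ggplot2::theme_minimal()
}

#' Learning curves for every player of a study or condition
#'
#' @param x An `"rps_study"` or `"rps_condition"`.
#' @param alpha Significance level for the boundary line.
#' @return A ggplot object: one panel per condition, one line per player,
#'   with the chance line and the per-n binomial significance boundary.
#' @export
plot_learning_curves <- function(x, alpha = 0.05) {
  sessions <- if (inherits(x, "rps_study")) {
    purrr::imap(x$conditions,
                ~ dplyr::mutate(.x$sessions, condition = .y)) |>
      dplyr::bind_rows()
  } else {
    dplyr::mutate(x$sessions, condition = x$condition)
  }
  sessions$condition <- factor(sessions$condition,
                               levels = rps_condition_names)
  boundary <- significance_boundary(max(sessions$game_index), alpha = alpha)
  ggplot2::ggplot(sessions, ggplot2::aes(x = .data$game_index,
                                         y = .data$cumulative_wins,
                                         group = .data$player)) +
    ggplot2::geom_step(alpha = 0.6) +
    ggplot2::geom_line(data = boundary, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$n, y = .data$k_min),
                       colour = "darkgreen", na.rm = TRUE) +
    ggplot2::geom_abline(slope = 1 / 3, intercept = 0, colour = "red") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "game", y = "cumulative wins") +
    ggplot2::theme_minimal()
}
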