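#' Tidy a GAMYE fit
#'
#' One row per monitored scalar parameter: posterior median, equal-tailed
#' interval, and convergence diagnostics.
#'
#' @param x A `gamye_fit`.
#' @param level Credible-interval mass (default 0.90).
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (posterior median), `conf.low`,
#'   `conf.high`, `rhat`, `ess`.
#' @export
tidy.gamye_fit <- function(x, level = 0.90, ...) {
  mat <- draws_matrix(x)
  summaries <- purrr::map_dfr(seq_len(ncol(mat)), function(j) {
    ci <- credible_interval(mat[, j], level)
    tibble::tibble(term = colnames(mat)[j], estimate = ci[["median"]],
                   conf.low = ci[["lower"]], conf.high = ci[["upper"]])
  })
  dplyr::left_join(
    summaries,
    dplyr::select(x$diagnostics, term = "parameter", "rhat", "ess"),
    by = "term"
  )
}

#' One-row summary of a GAMYE fit
#'
#' @param x A `gamye_fit`.
#' @param ... Unused.
#' @return Tibble with data size, sampler settings, and convergence summary.
#' @export
glance.gamye_fit <- function(x, ...) {
  tibble::tibble(
    species = x$dataset_info$species_label,
    model = if (is.null(x$phenology)) "gamye" else "gamye_phenology",
    n_records = x$dataset_info$n_records,
    n_routes = x$dataset_info$n_routes,
    n_strata = length(x$strata_levels),
    n_years = length(x$years),
    chains = x$mcmc$chains,
    draws = length(x$chain),
    max_rhat = attr(x$diagnostics, "max_rhat"),
    min_ess = attr(x$diagnostics, "min_ess"),
    converged = x$converged
  )
}

#' Plot annual abundance indices
#'
#' Posterior-median trajectories with credible-interval ribbons, one panel per
#' region, mirroring the standard survey-index figure.
#'
#' @param object An `annual_indices` tibble.
#' @param level Interval mass (default 0.90).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.annual_indices <- function(object, level = 0.90, ...) {
  summ <- summarize_indices(object, level = level)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$year, y = .data$index)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$region), scales = "free_y") +
    ggplot2::labs(
      x = "Year", y = "Annual abundance index (expected count per route)",
      title = paste0(attr(object, "species_label") %||% "", " (",
                     object$component[1], " component)")
    ) +
    ggplot2::theme_minimal()
}

#' Plot trend estimates
#'
#' Point (posterior median) and interval for the net percent change per region
#' and period.
#'
#' @param object A `trend_estimates` tibble from [summarize_trends()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trend_estimates <- function(object, ...) {
  dat <- dplyr::mutate(object,
                       period = paste0(.data$start_year, "-", .data$end_year))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$region, y = .data$net_change)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$net_change_lower,
                                          ymax = .data$net_change_upper)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$period)) +
    ggplot2::labs(x = NULL, y = "Net change (%)") +
    ggplot2::theme_minimal()
}

#' Plot decade-specific seasonal curves
#'
#' Posterior-median detection curves over the survey window, one line per
#' decade; drifting peaks are visible as horizontal displacement.
#'
#' @param fit A `gamye_fit` from [fit_gamye_phenology()].
#' @param level Interval mass for the ribbon (default 0.90).
#' @return A ggplot object.
#' @export
plot_decade_curves <- function(fit, level = 0.90) {
  curves <- decade_curves(fit)
  summ <- curves |>
    dplyr::group_by(.data$decade, .data$day) |>
    dplyr::summarise(
      lower = credible_interval(.data$effect, level)[["lower"]],
      upper = credible_interval(.data$effect, level)[["upper"]],
      effect = median(.data$effect),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$day, y = .data$effect,
                                     group = .data$decade)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(colour = factor(.data$decade))) +
    ggplot2::labs(x = "Day of year", y = "Seasonal effect (log scale)",
                  colour = "Decade") +
    ggplot2::theme_minimal()
}
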