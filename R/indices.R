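#' Annual abundance indices from a fitted model
#'
#' For each posterior draw, the stratum-year index on the count scale is
#'
#'   exp(mu_s + smooth_sy + gamma_sy + sd_obs^2/2 + sd_noise^2/2)
#'
#' the lognormal retransformation that integrates the observer and
#' overdispersion effects out, so indices represent expected counts on an
#' average route. The `smooth` component omits the year effects gamma,
#' isolating the long-term trajectory; `full` keeps them.
#'
#' @param fit A `gamye_fit`.
#' @param component `"full"` (default; includes year effects) or `"smooth"`.
#' @param basis Year basis; defaults to the one stored in the fit.
#' @return A tibble of class `annual_indices` with columns `region`
#'   (stratum id), `year`, `draw`, `index`, `component`.
#' @export
compute_indices <- function(fit, component = c("full", "smooth"), basis = NULL) {
  stopifnot(inherits(fit, "gamye_fit"))
  component <- match.arg(component)
  basis <- basis %||% fit$year_basis
  if (component == "smooth" && is.null(fit$draws$gamma)) {
    warning("year effects were disabled in this fit; 'smooth' equals 'full'",
            call. = FALSE)
  }
  n_draw <- length(fit$chain)
  n_s <- length(fit$strata_levels)
  n_y <- length(fit$years)

  # smooth_{draw, s, y} = sum_k beta[draw, s, k] * Xc[y, k], on the
  # year-centered basis used in fitting
  Xc <- sweep(basis$matrix, 2, fit$year_center %||% colMeans(basis$matrix))
  beta_flat <- matrix(fit$draws$beta, nrow = n_draw * n_s)  # (draw*s) x k
  smooth <- array(beta_flat %*% t(Xc), dim = c(n_draw, n_s, n_y))

  log_idx <- smooth +
    array(rep(fit$draws$mu, times = n_y), dim = c(n_draw, n_s, n_y)) +
    array(rep(fit$draws$sd_obs^2 / 2 + fit$draws$sd_noise^2 / 2, times = n_s * n_y),
          dim = c(n_draw, n_s, n_y))
  if (component == "full" && !is.null(fit$draws$gamma)) {
    log_idx <- log_idx + fit$draws$gamma
  }

  out <- tidyr::expand_grid(
    region = fit$strata_levels,
    year = fit$years,
    draw = seq_len(n_draw)
  )
  # array is [draw, s, y]; expand_grid above varies draw fastest, then year
  out$index <- as.vector(aperm(log_idx, c(1, 3, 2)))
  out$index <- exp(out$index)
  out$component <- component
  class(out) <- c("annual_indices", class(out))
  attr(out, "strata") <- fit$dataset_info$strata
  attr(out, "species_label") <- fit$dataset_info$species_label
  out
}

#' Area-weighted composite index
#'
#' Aggregates stratum indices to a regional/continental trajectory:
#' `composite_y = sum_s A_s * index_sy / sum_s A_s` per draw, weighting each
#' stratum by its area in km^2.
#'
#' @param indices An `annual_indices` tibble from [compute_indices()].
#' @param strata Stratum table with `stratum_id` and `area_km2`; defaults to
#'   the table carried on `indices`.
#' @return An `annual_indices` tibble with `region = "composite"`.
#' @export
composite_index <- function(indices, strata = attr(indices, "strata")) {
  stopifnot(is.data.frame(indices))
  if (is.null(strata)) stop("strata table with areas required", call. = FALSE)
  missing_area <- setdiff(unique(indices$region), strata$stratum_id)
  if (length(missing_area)) {
    stop("no area for stratum: ", paste(missing_area, collapse = ", "),
         call. = FALSE)
  }
  weights <- strata$area_km2[match(indices$region, strata$stratum_id)]
  out <- indices |>
    dplyr::mutate(.w = weights) |>
    dplyr::group_by(.data$year, .data$draw, .data$component) |>
    dplyr::summarise(index = sum(.data$.w * .data$index) / sum(.data$.w),
                     .groups = "drop") |>
    dplyr::mutate(region = "composite") |>
    dplyr::select("region", "year", "draw", "index", "component")
  class(out) <- c("annual_indices", class(out))
  attr(out, "species_label") <- attr(indices, "species_label")
  out
}

#' Endpoint trend: geometric mean annual rate between two years
#'
#' Per draw, `rate = 100 * ((I_y2 / I_y1)^(1 / (y2 - y1)) - 1)`, in percent
#' per year. Scale-invariant in the index series.
#'
#' @param indices A tibble with columns `year`, `draw`, `index` for a single
#'   region (e.g. a filtered `annual_indices` or a [composite_index()]).
#' @param y1,y2 Endpoint years, `y1 < y2`, both within the indexed years.
#' @return Numeric vector of annual rates, one per draw (ordered by draw).
#' @export
endpoint_trend <- function(indices, y1, y2) {
  if (y1 >= y2) stop("y1 must be earlier than y2", call. = FALSE)
  yrs <- unique(indices$year)
  if (!all(c(y1, y2) %in% yrs)) {
    stop("period [", y1, ", ", y2, "] outside modeled years [",
         min(yrs), ", ", max(yrs), "]", call. = FALSE)
  }
  if ("region" %in% names(indices) && dplyr::n_distinct(indices$region) > 1) {
    stop("endpoint_trend expects a single region; filter or composite first",
         call. = FALSE)
  }
  i1 <- dplyr::arrange(dplyr::filter(indices, .data$year == y1), .data$draw)
  i2 <- dplyr::arrange(dplyr::filter(indices, .data$year == y2), .data$draw)
  100 * ((i2$index / i1$index)^(1 / (y2 - y1)) - 1)
}

#' Compound net percent change from an annual rate
#'
#' `100 * ((1 + rate/100)^(y2 - y1) - 1)`: the exact inverse of
#' [endpoint_trend()]'s compounding, so a rate of -4.3 %/year over 1970--2019
#' (49 years) is a net change of about -88 %.
#'
#' @param rate Annual rate(s) in percent per year; must exceed -100.
#' @param y1,y2 Period endpoints, `y1 < y2`.
#' @return Net percent change over the period, same length as `rate`.
#' @export
#' @examples
#' trend_to_percent_change(-4.3, 1970, 2019)  # about -88
#' trend_to_percent_change(1.2, 1970, 2019)   # about  79
trend_to_percent_change <- function(rate, y1, y2) {
  if (y1 >= y2) stop("y1 must be earlier than y2", call. = FALSE)
  if (any(rate <= -100)) stop("rate must be > -100 % per year", call. = FALSE)
  100 * ((1 + rate / 100)^(y2 - y1) - 1)
}

#' Equal-tailed percentile credible interval
#'
#' Point estimate is the posterior median; interval bounds are the
#' `(1 - level)/2` and `(1 + level)/2` percentiles computed with linear
#' interpolation between order statistics (quantile type 7), the default
#' convention throughout the package (90% unless stated otherwise).
#'
#' @param draws Nonempty numeric vector of posterior draws.
#' @param level Interval mass, strictly between 0 and 1 (default 0.90).
#' @return Named numeric vector `c(lower, median, upper)`.
#' @export
credible_interval <- function(draws, level = 0.90) {
  if (!length(draws)) stop("draws must be nonempty", call. = FALSE)
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("level must be strictly between 0 and 1", call. = FALSE)
  }
  q <- quantile(draws, probs = c((1 - level) / 2, 0.5, (1 + level) / 2),
                names = FALSE, type = 7)
  c(lower = q[1], median = q[2], upper = q[3])
}

#' Summarize endpoint trends and net change over periods
#'
#' For each region and period, computes the per-draw annual rate and per-draw
#' net percent change (the compound identity holds exactly draw by draw), then
#' summarizes each with the posterior median and an equal-tailed credible
#' interval. Medians of the two summaries need not satisfy the compound
#' identity (medians of nonlinear transforms); the per-draw pairs always do.
#'
#' @param indices An `annual_indices` tibble (one or more regions).
#' @param periods List of length-2 numeric vectors `c(y1, y2)`.
#' @param level Credible-interval mass (default 0.90).
#' @return A tibble of class `trend_estimates`: one row per region x period
#'   with `region`, `start_year`, `end_year`, `component`, `annual_rate`,
#'   `annual_rate_lower`, `annual_rate_upper`, `net_change`,
#'   `net_change_lower`, `net_change_upper`, `level`.
#' @export
summarize_trends <- function(indices, periods, level = 0.90) {
  stopifnot(is.data.frame(indices))
  if (!is.list(periods)) periods <- list(periods)
  regions <- unique(indices$region)
  out <- purrr::map_dfr(regions, function(r) {
    sub <- dplyr::filter(indices, .data$region == r)
    purrr::map_dfr(periods, function(p) {
      rate <- endpoint_trend(sub, p[1], p[2])
      change <- trend_to_percent_change(rate, p[1], p[2])
      ci_r <- credible_interval(rate, level)
      ci_c <- credible_interval(change, level)
      tibble::tibble(
        region = r, start_year = p[1], end_year = p[2],
        component = sub$component[1],
        annual_rate = ci_r[["median"]],
        annual_rate_lower = ci_r[["lower"]],
        annual_rate_upper = ci_r[["upper"]],
        net_change = ci_c[["median"]],
        net_change_lower = ci_c[["lower"]],
        net_change_upper = ci_c[["upper"]],
        level = level
      )
    })
  })
  species <- attr(indices, "species_label")
  if (!is.null(species)) out <- dplyr::mutate(out, species_label = species,
                                              .before = 1)
  class(out) <- c("trend_estimates", class(out))
  out
}

#' Summarize annual indices for plotting or export
#'
#' @param indices An `annual_indices` tibble.
#' @param level Credible-interval mass (default 0.90).
#' @return Tibble with `region`, `year`, `component`, `index` (posterior
#'   median), `lower`, `upper`.
#' @export
summarize_indices <- function(indices, level = 0.90) {
  indices |>
    dplyr::group_by(.data$region, .data$year, .data$component) |>
    dplyr::summarise(
      lower = credible_interval(.data$index, level)[["lower"]],
      upper = credible_interval(.data$index, level)[["upper"]],
      index = median(.data$index),
      .groups = "drop"
    ) |>
    dplyr::select("region", "year", "component", "index", "lower", "upper")
}
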