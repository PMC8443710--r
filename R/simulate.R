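#' Configuration for the synthetic survey-data generator
#'
#' Defines a BBS-like study: strata of roadside routes, each surveyed once per
#' year on a day drawn from the permissible window, counts summed over stops,
#' observer turnover with first-year effects, and extra-Poisson dispersion on
#' the log scale. The generative log mean for route r in stratum s, year y is
#'
#'   mu_s + log(1 + trend/100) * (y - y0) + gamma_{s,y} + omega_r
#'     + eta * first_year + seasonal(day) + eps
#'
#' with gamma ~ N(0, year_effect_sd^2), omega ~ N(0, observer_sd^2) per
#' observer-route combination, eps ~ N(0, overdispersion_sd^2) per visit, and
#' counts Poisson given the log mean.
#'
#' @param n_strata Number of strata.
#' @param routes_per_stratum Routes in each stratum.
#' @param year_range Length-2 integer, first and last survey year.
#' @param mean_log_abundance Mean of the per-stratum intercepts mu_s
#'   (log expected route count in the first year).
#' @param stratum_sd SD of mu_s around `mean_log_abundance` (log scale).
#' @param annual_trend_pct True geometric trend, percent per year.
#' @param year_effect_sd SD of stratum-year effects (log scale).
#' @param observer_sd SD of observer-route effects (log scale).
#' @param first_year_effect Additive log-scale effect in an observer's first
#'   year on a route; typically negative (novice observers count fewer birds).
#' @param overdispersion_sd SD of per-visit extra-Poisson noise (log scale).
#' @param observer_turnover_prob Per-year probability a route's observer is
#'   replaced.
#' @param day_window Length-2 integer; survey day of year drawn uniformly in
#'   this inclusive window (default 145--190, late May to early July).
#' @param seasonal Optional [seasonal_truth()]; when present, a detection-scale
#'   seasonal curve is added to the log mean.
#' @param seed Integer RNG seed; the generator is fully reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_strata = 3,
                       routes_per_stratum = 8,
                       year_range = c(1970, 2019),
                       mean_log_abundance = 1.5,
                       stratum_sd = 0.3,
                       annual_trend_pct = -1,
                       year_effect_sd = 0.1,
                       observer_sd = 0.2,
                       first_year_effect = -0.1,
                       overdispersion_sd = 0.15,
                       observer_turnover_prob = 0.1,
                       day_window = c(145, 190),
                       seasonal = NULL,
                       seed = 1L) {
  cfg <- list(
    n_strata = as.integer(n_strata),
    routes_per_stratum = as.integer(routes_per_stratum),
    year_range = as.integer(year_range),
    mean_log_abundance = mean_log_abundance,
    stratum_sd = stratum_sd,
    annual_trend_pct = annual_trend_pct,
    year_effect_sd = year_effect_sd,
    observer_sd = observer_sd,
    first_year_effect = first_year_effect,
    overdispersion_sd = overdispersion_sd,
    observer_turnover_prob = observer_turnover_prob,
    day_window = as.integer(day_window),
    seasonal = seasonal,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  sds <- c("stratum_sd", "year_effect_sd", "observer_sd", "overdispersion_sd")
  for (f in sds) {
    if (cfg[[f]] < 0) stop("sim_config field '", f, "' must be >= 0", call. = FALSE)
  }
  if (cfg$year_range[1] >= cfg$year_range[2]) {
    stop("sim_config field 'year_range' must have start < end", call. = FALSE)
  }
  if (cfg$routes_per_stratum < 1) {
    stop("sim_config field 'routes_per_stratum' must be >= 1", call. = FALSE)
  }
  if (cfg$observer_turnover_prob < 0 || cfg$observer_turnover_prob > 1) {
    stop("sim_config field 'observer_turnover_prob' must be in [0,1]", call. = FALSE)
  }
  if (cfg$annual_trend_pct <= -100) {
    stop("sim_config field 'annual_trend_pct' must be > -100", call. = FALSE)
  }
  if (cfg$day_window[1] >= cfg$day_window[2]) {
    stop("sim_config field 'day_window' must have day_min < day_max", call. = FALSE)
  }
  if (!is.null(cfg$seasonal) && !inherits(cfg$seasonal, "seasonal_truth")) {
    stop("sim_config field 'seasonal' must be a seasonal_truth or NULL", call. = FALSE)
  }
  invisible(cfg)
}

#' True seasonal detection structure for the generator
#'
#' The seasonal term is a Gaussian bump on the log mean:
#' `peak_height * exp(-(day - peak_day)^2 / (2 * peak_width_sd^2))`, with the
#' peak day allowed to differ by decade so a drifting breeding season (and
#' hence drifting detectability within the fixed survey window) can be
#' simulated. Decades are `floor(year / 10) * 10`.
#'
#' @param peak_day_by_decade Named numeric: decade start year -> peak day of
#'   year, e.g. `c("1990" = 168, "2000" = 162)`. Years in decades without an
#'   entry use the nearest earlier entry (or the first entry).
#' @param peak_width_sd Width of the bump in days; must be positive.
#' @param peak_height Log-scale amplitude at the peak.
#' @return A list of class `seasonal_truth`.
#' @export
seasonal_truth <- function(peak_day_by_decade, peak_width_sd = 10,
                           peak_height = 0.5) {
  stopifnot(peak_width_sd > 0, length(peak_day_by_decade) >= 1)
  if (is.null(names(peak_day_by_decade)) || any(names(peak_day_by_decade) == "")) {
    stop("peak_day_by_decade must be named by decade start year", call. = FALSE)
  }
  structure(
    list(
      peak_day_by_decade = peak_day_by_decade,
      peak_width_sd = peak_width_sd,
      peak_height = peak_height
    ),
    class = "seasonal_truth"
  )
}

#' Decade of a calendar year
#'
#' @param year Integer vector.
#' @return `floor(year / 10) * 10`.
#' @export
year_decade <- function(year) as.integer(floor(year / 10) * 10)

seasonal_peak_for_year <- function(seasonal, year) {
  decades <- as.integer(names(seasonal$peak_day_by_decade))
  target <- year_decade(year)
  idx <- vapply(target, function(d) {
    earlier <- which(decades <= d)
    if (length(earlier)) earlier[which.max(decades[earlier])] else which.min(decades)
  }, integer(1))
  unname(seasonal$peak_day_by_decade[idx])
}

seasonal_log_effect <- function(seasonal, year, day) {
  peak <- seasonal_peak_for_year(seasonal, year)
  seasonal$peak_height * exp(-(day - peak)^2 / (2 * seasonal$peak_width_sd^2))
}

#' Simulate a BBS-like species dataset with known ground truth
#'
#' Generates route-level counts under the generative model documented in
#' [sim_config()]. Every dataset is reproducible from `config$seed` alone, and
#' always passes [screen_validity()] by construction (all runs valid, all
#' survey days inside the window).
#'
#' @param config A [sim_config()].
#' @return A list with `dataset` (a [species_dataset()]) and `truth`, a list
#'   holding `trajectories` (tibble stratum_id, year, true_index = expected
#'   count with observer/noise terms at zero), `annual_trend_pct`,
#'   `observer_effects` (tibble observer_id, route_id, effect), and
#'   `seasonal_peaks` (tibble decade, peak_day; NULL when no seasonal term).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  years <- seq(cfg$year_range[1], cfg$year_range[2])
  n_years <- length(years)
  strata_ids <- sprintf("S%02d", seq_len(cfg$n_strata))
  log_trend <- log1p(cfg$annual_trend_pct / 100)

  mu_s <- rnorm(cfg$n_strata, cfg$mean_log_abundance, cfg$stratum_sd)
  gamma <- matrix(rnorm(cfg$n_strata * n_years, 0, cfg$year_effect_sd),
                  cfg$n_strata, n_years)

  routes <- tidyr::expand_grid(
    stratum = seq_len(cfg$n_strata),
    route_in_stratum = seq_len(cfg$routes_per_stratum)
  ) |>
    dplyr::mutate(route_id = sprintf("%s-R%02d", strata_ids[.data$stratum],
                                     .data$route_in_stratum))

  # observer history per route: replacement with prob turnover each year
  obs_counter <- 0L
  observer_rows <- purrr::pmap_dfr(routes, function(stratum, route_in_stratum, route_id) {
    obs_idx <- integer(n_years)
    first <- logical(n_years)
    for (t in seq_len(n_years)) {
      new_obs <- t == 1L || runif(1) < cfg$observer_turnover_prob
      if (new_obs) {
        obs_counter <<- obs_counter + 1L
        obs_idx[t] <- obs_counter
        first[t] <- TRUE
      } else {
        obs_idx[t] <- obs_idx[t - 1L]
        first[t] <- FALSE
      }
    }
    tibble::tibble(
      stratum = stratum, route_id = route_id, year = years,
      observer_id = sprintf("O%04d", obs_idx), first_year = first
    )
  })

  # one omega per observer-route combination
  omega_tbl <- observer_rows |>
    dplyr::distinct(.data$observer_id, .data$route_id) |>
    dplyr::mutate(effect = rnorm(dplyr::n(), 0, cfg$observer_sd))

  visits <- observer_rows |>
    dplyr::left_join(omega_tbl, by = c("observer_id", "route_id")) |>
    dplyr::mutate(
      stratum_id = strata_ids[.data$stratum],
      day_of_year = as.integer(floor(runif(
        dplyr::n(), cfg$day_window[1], cfg$day_window[2] + 1L
      ))),
      year_index = match(.data$year, years),
      log_mu = mu_s[.data$stratum] + log_trend * (.data$year - years[1]) +
        gamma[cbind(.data$stratum, .data$year_index)] +
        .data$effect + cfg$first_year_effect * .data$first_year +
        rnorm(dplyr::n(), 0, cfg$overdispersion_sd)
    )
  if (!is.null(cfg$seasonal)) {
    visits <- dplyr::mutate(
      visits,
      log_mu = .data$log_mu +
        seasonal_log_effect(cfg$seasonal, .data$year, .data$day_of_year)
    )
  }
  visits <- dplyr::mutate(
    visits,
    count = rpois(dplyr::n(), exp(.data$log_mu)),
    valid = TRUE
  )

  records <- dplyr::select(
    visits, "route_id", "stratum_id", "year", "day_of_year",
    "observer_id", "first_year", "count", "valid"
  )
  strata <- tibble::tibble(
    stratum_id = strata_ids,
    region = sprintf("region-%02d", seq_len(cfg$n_strata)),
    bcr = sprintf("BCR-%02d", seq_len(cfg$n_strata)),
    area_km2 = round(runif(cfg$n_strata, 5e3, 5e4))
  )

  trajectories <- tidyr::expand_grid(stratum = seq_len(cfg$n_strata), year = years) |>
    dplyr::mutate(
      stratum_id = strata_ids[.data$stratum],
      true_index = exp(mu_s[.data$stratum] + log_trend * (.data$year - years[1]) +
                         gamma[cbind(.data$stratum, match(.data$year, years))])
    ) |>
    dplyr::select("stratum_id", "year", "true_index")

  seasonal_peaks <- NULL
  if (!is.null(cfg$seasonal)) {
    decades <- sort(unique(year_decade(years)))
    seasonal_peaks <- tibble::tibble(
      decade = decades,
      peak_day = seasonal_peak_for_year(
        cfg$seasonal, decades + 5L  # any year inside the decade
      )
    )
  }

  dataset <- species_dataset(records, strata, species_label = "synthetic",
                             year_range = cfg$year_range)
  truth <- list(
    trajectories = trajectories,
    annual_trend_pct = cfg$annual_trend_pct,
    stratum_intercepts = tibble::tibble(stratum_id = strata_ids, mu = mu_s),
    observer_effects = dplyr::select(omega_tbl, "observer_id", "route_id", "effect"),
    first_year_effect = cfg$first_year_effect,
    seasonal_peaks = seasonal_peaks,
    config = cfg
  )
  list(dataset = dataset, truth = truth)
}

#' Simulate a dataset with a drifting seasonal detection peak
#'
#' As [simulate_dataset()], but the seasonal peak day advances (or delays) by
#' a fixed number of days per decade starting from the first decade's peak,
#' emulating a progressive phenological shift of the breeding season relative
#' to the fixed survey window. Positive `shift_days_per_decade` moves the peak
#' earlier.
#'
#' @param config A [sim_config()] whose `seasonal` field is set; the first
#'   (earliest-decade) entry of `peak_day_by_decade` anchors the drift.
#' @param shift_days_per_decade Days the peak advances each decade.
#' @return As [simulate_dataset()]; `truth$seasonal_peaks` records the
#'   drifting peaks.
#' @export
simulate_phenology_shift <- function(config, shift_days_per_decade) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$seasonal)) {
    stop("config$seasonal must be set for simulate_phenology_shift", call. = FALSE)
  }
  years <- seq(config$year_range[1], config$year_range[2])
  decades <- sort(unique(year_decade(years)))
  base_decade <- as.integer(names(config$seasonal$peak_day_by_decade)[1])
  base_peak <- config$seasonal$peak_day_by_decade[[1]]
  peaks <- base_peak - shift_days_per_decade * (decades - base_decade) / 10
  config$seasonal$peak_day_by_decade <- setNames(peaks, decades)
  simulate_dataset(config)
}

#' Analytic mean count of the generative model
#'
#' Expected count for a route visit given the truth, integrating the lognormal
#' noise terms: `exp(log_mu_structural + (observer_sd^2 + overdispersion_sd^2)/2)`.
#' Used as the oracle for convergence-of-means checks.
#'
#' @param config A [sim_config()].
#' @param year Calendar year.
#' @param day Day of year (only used when `config$seasonal` is set).
#' @return Expected count for an average stratum/observer at that year and day.
#' @export
expected_mean_count <- function(config, year, day = NULL) {
  log_mu <- config$mean_log_abundance +
    log1p(config$annual_trend_pct / 100) * (year - config$year_range[1])
  if (!is.null(config$seasonal)) {
    if (is.null(day)) stop("day required when config has a seasonal term", call. = FALSE)
    log_mu <- log_mu + seasonal_log_effect(config$seasonal, year, day)
  }
  var_sum <- config$stratum_sd^2 + config$year_effect_sd^2 +
    config$observer_sd^2 + config$overdispersion_sd^2
  exp(log_mu + var_sum / 2)
}

#' Write a simulated run to disk
#'
#' Writes the counts and strata files in the package's delimited-text layout,
#' the truth tables, and a run manifest (JSON) echoing the configuration and
#' seed.
#'
#' @param sim Result of [simulate_dataset()] or [simulate_phenology_shift()].
#' @param dir Output directory, created if needed.
#' @return Invisible named list of the file paths written.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    counts = file.path(dir, "counts.csv"),
    strata = file.path(dir, "strata.csv"),
    trajectories = file.path(dir, "truth_trajectories.csv"),
    observers = file.path(dir, "truth_observers.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_dataset(sim$dataset, paths$counts, paths$strata)
  readr::write_csv(sim$truth$trajectories, paths$trajectories, progress = FALSE)
  readr::write_csv(sim$truth$observer_effects, paths$observers, progress = FALSE)
  if (!is.null(sim$truth$seasonal_peaks)) {
    paths$seasonal <- file.path(dir, "truth_seasonal_peaks.csv")
    readr::write_csv(sim$truth$seasonal_peaks, paths$seasonal, progress = FALSE)
  }
  cfg <- sim$truth$config
  cfg$seasonal <- if (is.null(cfg$seasonal)) NULL else unclass(cfg$seasonal)
  manifest <- list(
    generator = "gamye::simulate_dataset",
    config = unclass(cfg),
    n_records = nrow(sim$dataset$records)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
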