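# Independent oracles and shared fixtures for the test suite.

# de Boor recursion, written directly from the textbook definition so the
# package's splineDesign-based construction is checked against an independent
# implementation.
deboor_basis <- function(knots, x, degree) {
  n_basis <- length(knots) - degree - 1
  b0 <- function(i, t) {
    # order-1 (degree-0) basis; empty intervals vanish, the final nonempty
    # interval is right-closed
    if (knots[i] == knots[i + 1]) return(0)
    if (t >= knots[i] && t < knots[i + 1]) return(1)
    if (t == max(knots) && knots[i + 1] == max(knots)) return(1)
    0
  }
  brec <- function(i, d, t) {
    if (d == 0) return(b0(i, t))
    left <- 0
    if (knots[i + d] > knots[i]) {
      left <- (t - knots[i]) / (knots[i + d] - knots[i]) * brec(i, d - 1, t)
    }
    right <- 0
    if (knots[i + d + 1] > knots[i + 1]) {
      right <- (knots[i + d + 1] - t) / (knots[i + d + 1] - knots[i + 1]) *
        brec(i + 1, d - 1, t)
    }
    left + right
  }
  out <- matrix(0, length(x), n_basis)
  for (r in seq_along(x)) {
    for (i in seq_len(n_basis)) out[r, i] <- brec(i, degree, x[r])
  }
  out
}

# small hand-assembled survey-record tibble
toy_records <- function(...) {
  defaults <- tibble::tibble(
    route_id = "r1", stratum_id = "s1", year = 2000L, day_of_year = 160L,
    observer_id = "o1", first_year = FALSE, count = 1L, valid = TRUE
  )
  rows <- list(...)
  if (!length(rows)) return(defaults)
  purrr::map_dfr(rows, function(r) {
    out <- defaults
    for (nm in names(r)) out[[nm]] <- r[[nm]]
    out
  })
}

toy_strata <- function(ids, areas = rep(1000, length(ids))) {
  tibble::tibble(
    stratum_id = ids, region = paste0("reg-", ids), bcr = paste0("bcr-", ids),
    area_km2 = areas
  )
}

# hand-built gamye_fit with fully specified draws (no MCMC), for testing the
# summarization layer against hand arithmetic
manual_fit <- function(mu, beta, gamma = NULL, sd_obs = 0, sd_noise = 0,
                       years = 2000:2004, strata = c("A", "B"),
                       areas = c(1, 1), n_knots = 4,
                       alpha = NULL, day_window = c(145, 190),
                       day_knots = 5, decades = NULL) {
  n_draw <- dim(beta)[1]
  basis <- build_year_basis(years, n_knots = n_knots, degree = 3)
  day_basis <- if (!is.null(alpha)) {
    build_day_basis(seq(day_window[1], day_window[2]), n_knots = day_knots)
  }
  draws <- list(
    mu = mu, B = apply(beta, c(1, 3), mean), beta = beta,
    sd_B = rep(0, n_draw),
    omega = matrix(0, n_draw, 1),
    sd_obs = rep(sd_obs, n_draw), eta = rep(0, n_draw),
    sd_noise = rep(sd_noise, n_draw)
  )
  if (!is.null(gamma)) {
    draws$gamma <- gamma
    draws$sd_gamma <- matrix(0.1, n_draw, length(strata))
  }
  if (!is.null(alpha)) {
    draws$alpha <- alpha
    draws$sd_alpha <- rep(0.1, n_draw)
  }
  structure(list(
    draws = draws, chain = rep(1:2, length.out = n_draw),
    strata_levels = strata, years = years, obs_levels = "o|r",
    year_basis = basis, year_center = colMeans(basis$matrix),
    day_basis = day_basis,
    decades = decades %||% if (!is.null(alpha)) seq(2000, by = 10,
                                                    length.out = dim(alpha)[2]),
    decades_observed = if (!is.null(alpha)) rep(TRUE, dim(alpha)[2]),
    spec = gamye_spec(n_knots = n_knots),
    phenology = NULL,
    mcmc = mcmc_options(chains = 2, samples = ceiling(n_draw / 2)),
    dataset_info = list(species_label = "toy", n_records = 0, n_routes = 0,
                        strata = toy_strata(strata, areas)),
    engine = "manual",
    diagnostics = NULL, converged = TRUE
  ), class = "gamye_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one stratum per failure mode: too few observed routes; no route surveyed
# >= 5 years; no route with the species in >= 3 years; and one passing stratum
inclusion_toy <- function() {
  mk <- function(stratum, route, years, counts) {
    purrr::map2_dfr(years, counts, function(y, k) {
      toy_records(list(route_id = paste(stratum, route, sep = "-"),
                       stratum_id = stratum, year = as.integer(y),
                       count = as.integer(k)))
    })
  }
  recs <- dplyr::bind_rows(
    # PASS: 3 observed routes, route a surveyed 5 yrs, species in 3 yrs on a
    mk("pass", "a", 2000:2004, c(1, 2, 1, 0, 0)),
    mk("pass", "b", 2000:2001, c(1, 0)),
    mk("pass", "c", 2000, 1),
    # FAIL routes: species seen on only 2 routes
    mk("few_routes", "a", 2000:2004, c(1, 1, 1, 1, 1)),
    mk("few_routes", "b", 2000:2004, c(2, 0, 1, 1, 0)),
    mk("few_routes", "c", 2000:2004, c(0, 0, 0, 0, 0)),
    # FAIL 5-year: 3 observed routes but each surveyed 4 years
    mk("short_series", "a", 2000:2003, c(1, 1, 1, 0)),
    mk("short_series", "b", 2000:2003, c(0, 1, 2, 1)),
    mk("short_series", "c", 2000:2003, c(1, 0, 0, 1)),
    # FAIL 3-observed-years: routes long enough but species seen in <= 2 years
    mk("sparse_obs", "a", 2000:2005, c(1, 1, 0, 0, 0, 0)),
    mk("sparse_obs", "b", 2000:2005, c(0, 2, 0, 0, 0, 0)),
    mk("sparse_obs", "c", 2000:2005, c(0, 0, 1, 1, 0, 0))
  )
  species_dataset(
    recs,
    toy_strata(c("pass", "few_routes", "short_series", "sparse_obs")),
    year_range = c(2000, 2010)
  )
}

# session-level cache so expensive MCMC fits are shared across test files
fit_cache <- local({
  env <- new.env(parent = emptyenv())
  function(key, expr) {
    if (!exists(key, envir = env)) assign(key, force(expr), envir = env)
    get(key, envir = env)
  }
})

small_sim <- function(seed = 7, ...) {
  simulate_dataset(sim_config(
    n_strata = 2, routes_per_stratum = 6, year_range = c(2000, 2014),
    mean_log_abundance = 2, annual_trend_pct = -3, seed = seed, ...
  ))
}

small_fit <- function() {
  fit_cache("small_fit", {
    sim <- small_sim()
    fl <- apply_inclusion_filters(sim$dataset)
    suppressWarnings(fit_gamye(
      fl$dataset, gamye_spec(),
      mcmc_options(chains = 2, warmup = 400, samples = 300, seed = 5)
    ))
  })
}

small_phenology_fit <- function() {
  fit_cache("small_phen_fit", {
    sim <- small_sim()
    fl <- apply_inclusion_filters(sim$dataset)
    suppressWarnings(fit_gamye_phenology(
      fl$dataset, phenology_spec(),
      mcmc_options(chains = 2, warmup = 400, samples = 300, seed = 5)
    ))
  })
}
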