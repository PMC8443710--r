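#' GAMYE model specification
#'
#' Structure of the hierarchical Generalized Additive Model with Year Effects:
#' counts are overdispersed Poisson (Poisson-lognormal) with log mean
#'
#'   mu_s + sum_k beta_sk * X_yk + gamma_sy + omega_o + eta * first_year + eps
#'
#' where X is a B-spline basis over years, the stratum smooth coefficients
#' beta_sk are shrunk toward a continental mean smooth B_k
#' (beta_sk ~ N(B_k, sigma_B^2), pooled across knots), gamma_sy are
#' stratum-year effects with per-stratum sds, omega are observer effects, and
#' eps is count-level lognormal overdispersion.
#'
#' @param n_knots Year-smooth basis dimension; `NULL` (default) resolves to
#'   `ceiling(n_years / 4)` at fit time.
#' @param basis_degree Spline degree (default 3).
#' @param year_effects Include the stratum-year effects gamma (default TRUE).
#' @param observer_unit `"observer_route"` (default): one effect per
#'   observer-route combination, the unit at which inter-observer variability
#'   is observable in route-level data; or `"observer"`.
#' @param prior_scales Named list of prior scales on the log scale:
#'   `mu_sd` (stratum intercepts, default 10), `B_sd` (continental smooth
#'   coefficients, 2), `eta_sd` (first-year effect, 1), `sd_scale`
#'   (half-Normal scale for all variance-component sds, 1).
#' @return A list of class `gamye_spec`.
#' @export
gamye_spec <- function(n_knots = NULL, basis_degree = 3, year_effects = TRUE,
                       observer_unit = c("observer_route", "observer"),
                       prior_scales = list()) {
  defaults <- list(mu_sd = 10, B_sd = 2, eta_sd = 1, sd_scale = 1)
  bad <- setdiff(names(prior_scales), names(defaults))
  if (length(bad)) stop("unknown prior scale(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  defaults[names(prior_scales)] <- prior_scales
  if (any(unlist(defaults) <= 0)) stop("prior scales must be positive", call. = FALSE)
  if (!is.null(n_knots) && n_knots < 3) stop("n_knots must be >= 3", call. = FALSE)
  if (basis_degree < 1) stop("basis_degree must be >= 1", call. = FALSE)
  structure(
    list(n_knots = n_knots, basis_degree = basis_degree,
         year_effects = isTRUE(year_effects),
         observer_unit = match.arg(observer_unit),
         overdispersion_family = "lognormal",
         prior_scales = defaults),
    class = "gamye_spec"
  )
}

#' Phenology-corrected GAMYE specification
#'
#' Extends [gamye_spec()] with a survey-wide, decade-specific smooth of the
#' log mean over survey day of year. Each decade has its own B-spline curve
#' over the survey window, centered to mean zero over the day grid (so decade
#' mean abundance is carried by the year smooth and year effects, not the date
#' term). The decade curves are linked by a first-order random walk on the
#' coefficients, `alpha_dk ~ N(alpha_{d-1,k}, sigma_alpha^2)`, so each
#' decade's detection peak can lead or lag the preceding decade's.
#'
#' @param day_basis_knots Dimension of the day-of-year basis (default 5).
#' @param day_window Inclusive day-of-year window (default `c(145, 190)`).
#' @param walk_order Order of the across-decade random walk; only 1 is
#'   implemented.
#' @param alpha1_sd Prior sd of the first decade's coefficients (default 1).
#' @param gamye A [gamye_spec()] for the remaining model structure.
#' @return A list of class `phenology_spec`.
#' @export
phenology_spec <- function(day_basis_knots = 5, day_window = c(145, 190),
                           walk_order = 1, alpha1_sd = 1,
                           gamye = gamye_spec()) {
  if (day_basis_knots < 3) stop("day_basis_knots must be >= 3", call. = FALSE)
  if (day_window[1] >= day_window[2]) stop("day_window must have day_min < day_max",
                                           call. = FALSE)
  if (walk_order != 1) {
    stop("only walk_order = 1 (first-order random walk across decades) is implemented",
         call. = FALSE)
  }
  stopifnot(inherits(gamye, "gamye_spec"), alpha1_sd > 0)
  structure(
    list(day_basis_knots = as.integer(day_basis_knots),
         day_window = as.integer(day_window),
         walk_order = 1L, alpha1_sd = alpha1_sd, gamye = gamye),
    class = "phenology_spec"
  )
}

#' MCMC engine options
#'
#' @param chains Number of chains (>= 2, for split-R-hat diagnostics).
#' @param warmup Adaptation + burn-in iterations per chain.
#' @param samples Retained posterior draws per chain.
#' @param seed Integer seed; chain c runs on RNG seed `seed + c`.
#' @param thin Thinning interval (default 1).
#' @return A list of class `mcmc_options`.
#' @export
mcmc_options <- function(chains = 2, warmup = 500, samples = 500, seed = 1,
                         thin = 1) {
  if (chains < 2) stop("chains must be >= 2 for convergence diagnostics", call. = FALSE)
  if (samples < 1) stop("samples must be >= 1", call. = FALSE)
  structure(
    list(chains = as.integer(chains), warmup = as.integer(warmup),
         samples = as.integer(samples), seed = as.integer(seed),
         thin = as.integer(thin)),
    class = "mcmc_options"
  )
}

# ---- JAGS model code -------------------------------------------------------

jags_model_code <- function(spec, phenology = NULL) {
  ps <- spec$prior_scales
  year_term <- if (spec$year_effects) " + gam[strat[i], yr[i]]" else ""
  day_term <- if (!is.null(phenology)) " + inprod(alpha[dec[i],], Xday[i,])" else ""
  gamma_block <- if (spec$year_effects) sprintf("
    for (y in 1:n_years) { gam[s, y] ~ dnorm(0, tau_gamma[s]) }
    sd_gamma[s] ~ dnorm(0, %g) T(0,)
    tau_gamma[s] <- pow(sd_gamma[s], -2)", 1 / ps$sd_scale^2) else ""
  phen_block <- if (!is.null(phenology)) sprintf("
  for (k in 1:n_day_knots) {
    alpha[1, k] ~ dnorm(0, %g)
    for (d in 2:n_decades) { alpha[d, k] ~ dnorm(alpha[d - 1, k], tau_alpha) }
  }
  sd_alpha ~ dnorm(0, %g) T(0,)
  tau_alpha <- pow(sd_alpha, -2)",
    1 / phenology$alpha1_sd^2, 1 / ps$sd_scale^2) else ""

  sprintf("
model {
  for (i in 1:n_obs) {
    count[i] ~ dpois(lambda[i])
    log(lambda[i]) <- mu[strat[i]] + inprod(beta[strat[i],], Xyear[i,])%s + omega[obs[i]] + eta * first_year[i]%s + eps[i]
    eps[i] ~ dnorm(0, tau_eps)
  }
  for (s in 1:n_strata) {
    mu[s] ~ dnorm(0, %g)
    for (k in 1:n_knots) { beta[s, k] ~ dnorm(B[k], tau_B) }%s
  }
  for (k in 1:n_knots) { B[k] ~ dnorm(0, %g) }
  for (o in 1:n_observers) { omega[o] ~ dnorm(0, tau_omega) }
  eta ~ dnorm(0, %g)
  sd_B ~ dnorm(0, %g) T(0,)
  tau_B <- pow(sd_B, -2)
  sd_obs ~ dnorm(0, %g) T(0,)
  tau_omega <- pow(sd_obs, -2)
  sd_noise ~ dnorm(0, %g) T(0,)
  tau_eps <- pow(sd_noise, -2)%s
}",
    year_term, day_term, 1 / ps$mu_sd^2, gamma_block, 1 / ps$B_sd^2,
    1 / ps$eta_sd^2, 1 / ps$sd_scale^2, 1 / ps$sd_scale^2, 1 / ps$sd_scale^2,
    phen_block)
}

# ---- fitting ---------------------------------------------------------------

#' Fit the GAMYE model
#'
#' Samples the posterior of the hierarchical GAMYE (see [gamye_spec()]) with
#' JAGS. The dataset should already have passed [apply_inclusion_filters()].
#' After sampling, convergence is checked with [check_convergence()]; a fit
#' whose maximum split-R-hat exceeds 1.05 is returned flagged
#' (`converged = FALSE`) with a warning, never silently.
#'
#' @param dataset A [species_dataset()].
#' @param spec A [gamye_spec()].
#' @param mcmc An [mcmc_options()].
#' @param quiet Suppress JAGS progress output (default TRUE).
#' @return An object of class `gamye_fit`: posterior draw arrays indexed
#'   `[draw, ...]` with a `chain` vector, the year basis, index maps for
#'   strata/years/observers, the spec and options, and diagnostics.
#' @export
fit_gamye <- function(dataset, spec = gamye_spec(), mcmc = mcmc_options(),
                      quiet = TRUE) {
  fit_gamye_engine(dataset, spec, mcmc, phenology = NULL, quiet = quiet)
}

fit_gamye_engine <- function(dataset, spec, mcmc, phenology = NULL, quiet = TRUE) {
  stopifnot(inherits(dataset, "species_dataset"), inherits(spec, "gamye_spec"),
            inherits(mcmc, "mcmc_options"))
  recs <- dataset$records
  if (!nrow(recs)) stop("dataset has no records", call. = FALSE)
  if (any(recs$count > 0) == FALSE) {
    stop("all counts are zero; dataset should not have passed inclusion filters",
         call. = FALSE)
  }

  years <- seq(dataset$year_range[1], dataset$year_range[2])
  strata_levels <- sort(unique(recs$stratum_id))
  obs_key <- if (spec$observer_unit == "observer_route") {
    paste(recs$observer_id, recs$route_id, sep = "|")
  } else {
    recs$observer_id
  }
  obs_levels <- sort(unique(obs_key))

  n_knots <- spec$n_knots %||% max(ceiling(length(years) / 4), spec$basis_degree + 1)
  basis <- build_year_basis(years, n_knots = n_knots, degree = spec$basis_degree)
  # Identifiable parameterization of the smooth. The raw basis rows sum to 1,
  # so the coefficient constant-direction is confounded with the stratum
  # intercepts. We (a) center the basis columns over the modeled years, making
  # the smooth a mean-zero departure and mu_s the period-mean log abundance,
  # and (b) sample in the (K-1)-dimensional coefficient space orthogonal to
  # the constant vector (which is the null space of the centered basis),
  # mapping draws back to the full K coefficients afterwards.
  year_center <- colMeans(basis$matrix)
  Xc <- sweep(basis$matrix, 2, year_center)
  Q <- smooth_null_projector(n_knots)
  Xz <- Xc %*% Q

  data <- list(
    count = as.integer(recs$count),
    strat = match(recs$stratum_id, strata_levels),
    obs = match(obs_key, obs_levels),
    first_year = as.integer(recs$first_year),
    Xyear = Xz[match(recs$year, years), , drop = FALSE],
    n_obs = nrow(recs),
    n_strata = length(strata_levels),
    n_knots = n_knots - 1L,
    n_observers = length(obs_levels)
  )
  monitors <- c("mu", "B", "beta", "sd_B", "omega", "sd_obs", "eta", "sd_noise")
  if (spec$year_effects) {
    data$yr <- match(recs$year, years)
    data$n_years <- length(years)
    monitors <- c(monitors, "gam", "sd_gamma")
  }

  day_basis <- NULL
  decades <- NULL
  if (!is.null(phenology)) {
    if (anyNA(recs$day_of_year)) {
      stop("phenology model requires day_of_year on every record", call. = FALSE)
    }
    grid <- seq(phenology$day_window[1], phenology$day_window[2])
    day_basis <- build_day_basis(grid, n_knots = phenology$day_basis_knots,
                                 degree = spec$basis_degree)
    decades <- sort(unique(year_decade(years)))
    # evaluate at record days, then center columns over the daily grid so every
    # decade curve integrates to zero over the window
    day_at_records <- evaluate_basis(day_basis, pmin(pmax(recs$day_of_year,
                                                          phenology$day_window[1]),
                                                     phenology$day_window[2]))
    grid_means <- colMeans(day_basis$matrix)
    data$Xday <- sweep(day_at_records, 2, grid_means)
    data$dec <- match(year_decade(recs$year), decades)
    data$n_decades <- length(decades)
    data$n_day_knots <- phenology$day_basis_knots
    monitors <- c(monitors, "alpha", "sd_alpha")
  }

  inits <- lapply(seq_len(mcmc$chains), function(c) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (mcmc$seed + c) %% .Machine$integer.max)
  })
  run_jags <- function() {
    model <- rjags::jags.model(
      textConnection(jags_model_code(spec, phenology)),
      data = data, inits = inits, n.chains = mcmc$chains,
      n.adapt = max(mcmc$warmup %/% 2, 100), quiet = quiet
    )
    update(model, max(mcmc$warmup - max(mcmc$warmup %/% 2, 100), 0),
           progress.bar = "none")
    rjags::coda.samples(model, monitors, n.iter = mcmc$samples * mcmc$thin,
                        thin = mcmc$thin, progress.bar = "none")
  }
  samples <- if (quiet) suppressWarnings(run_jags()) else run_jags()

  draws <- structure_draws(samples, spec, phenology,
                           n_strata = length(strata_levels),
                           n_knots = n_knots, projector = Q,
                           n_years = length(years),
                           n_observers = length(obs_levels),
                           n_decades = length(decades),
                           n_day_knots = phenology$day_basis_knots %||% 0L)
  chain <- rep(seq_len(mcmc$chains), each = mcmc$samples)

  decades_observed <- if (!is.null(decades)) {
    decades %in% year_decade(recs$year)
  } else NULL

  fit <- structure(
    list(
      draws = draws, chain = chain,
      strata_levels = strata_levels, years = years, obs_levels = obs_levels,
      year_basis = basis, year_center = year_center,
      day_basis = day_basis, decades = decades,
      decades_observed = decades_observed,
      spec = spec, phenology = phenology, mcmc = mcmc,
      dataset_info = list(
        species_label = dataset$species_label,
        n_records = nrow(recs),
        n_routes = dplyr::n_distinct(recs$route_id),
        strata = dataset$strata
      ),
      engine = paste0("JAGS/rjags ", as.character(utils::packageVersion("rjags")))
    ),
    class = "gamye_fit"
  )
  diag <- check_convergence(fit)
  fit$diagnostics <- diag
  fit$converged <- isTRUE(attr(diag, "pass"))
  if (!fit$converged) {
    warning("convergence check failed (max split-R-hat ",
            round(attr(diag, "max_rhat"), 3),
            " > 1.05); fit flagged non-converged", call. = FALSE)
  }
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# orthonormal basis of the coefficient space orthogonal to the constant
# vector; deterministic in n_knots
smooth_null_projector <- function(n_knots) {
  qr.Q(qr(matrix(1, n_knots, 1)), complete = TRUE)[, -1, drop = FALSE]
}

# column extractor tolerant of coda's bracket-dropping for single-element nodes
make_grab <- function(mat) {
  function(name, dims) {
    if (length(dims) == 0) return(as.numeric(mat[, name]))
    idx <- expand.grid(lapply(dims, seq_len))
    cols <- paste0(name, "[", do.call(paste, c(idx, sep = ",")), "]")
    absent <- setdiff(cols, colnames(mat))
    if (length(absent)) {
      if (length(cols) == 1 && name %in% colnames(mat)) {
        cols <- name
      } else {
        stop("missing sampler column(s): ", paste(absent, collapse = ", "),
             call. = FALSE)
      }
    }
    array(mat[, cols], dim = c(nrow(mat), dims))
  }
}

# reshape coda output into [draw, ...] arrays; smooth coefficients sampled in
# the reduced space are mapped back to the full basis via the projector
structure_draws <- function(samples, spec, phenology, n_strata, n_knots,
                            n_years, n_observers, n_decades, n_day_knots,
                            projector) {
  mat <- do.call(rbind, lapply(samples, as.matrix))
  grab <- make_grab(mat)
  k_id <- n_knots - 1L
  theta <- grab("beta", c(n_strata, k_id))        # [draw, s, k-1]
  Theta <- grab("B", k_id)                        # [draw, k-1]
  n_draw <- nrow(mat)
  beta <- array(
    matrix(theta, nrow = n_draw * n_strata) %*% t(projector),
    dim = c(n_draw, n_strata, n_knots)
  )
  draws <- list(
    mu = grab("mu", n_strata),
    B = Theta %*% t(projector),
    beta = beta,
    sd_B = grab("sd_B", integer(0)),
    omega = grab("omega", n_observers),
    sd_obs = grab("sd_obs", integer(0)),
    eta = grab("eta", integer(0)),
    sd_noise = grab("sd_noise", integer(0))
  )
  if (spec$year_effects) {
    draws$gamma <- grab("gam", c(n_strata, n_years))
    draws$sd_gamma <- grab("sd_gamma", n_strata)
  }
  if (!is.null(phenology)) {
    draws$alpha <- grab("alpha", c(n_decades, n_day_knots))
    draws$sd_alpha <- grab("sd_alpha", integer(0))
  }
  draws
}

#' Fit the phenology-corrected GAMYE
#'
#' As [fit_gamye()], plus a survey-wide decade-specific smooth of the log mean
#' over survey day of year (see [phenology_spec()]). Decades present in the
#' modeled year range but absent from the data still receive coefficients from
#' the across-decade random-walk prior; they are flagged in
#' `fit$decades_observed`.
#'
#' @inheritParams fit_gamye
#' @param spec A [phenology_spec()].
#' @return A `gamye_fit` whose draws include the decade-day coefficients
#'   `alpha` and walk sd `sd_alpha`.
#' @export
fit_gamye_phenology <- function(dataset, spec = phenology_spec(),
                                mcmc = mcmc_options(), quiet = TRUE) {
  stopifnot(inherits(spec, "phenology_spec"))
  fit_gamye_engine(dataset, spec$gamye, mcmc, phenology = spec, quiet = quiet)
}

#' @export
print.gamye_fit <- function(x, ...) {
  cat("<gamye_fit>", if (!is.null(x$phenology)) "(phenology-corrected)", "\n")
  cat("  species: ", x$dataset_info$species_label,
      " | records: ", x$dataset_info$n_records,
      " | strata: ", length(x$strata_levels),
      " | years: ", x$years[1], "-", x$years[length(x$years)], "\n", sep = "")
  cat("  draws: ", length(x$chain), " (", x$mcmc$chains, " chains x ",
      x$mcmc$samples, ")\n", sep = "")
  cat("  converged: ", x$converged,
      " (max split R-hat ", round(attr(x$diagnostics, "max_rhat"), 3), ")\n",
      sep = "")
  invisible(x)
}

#' Log mean of one survey record under one posterior draw
#'
#' Deterministic composition of the GAMYE terms: stratum intercept, stratum
#' year-smooth (evaluated on the basis centered over the modeled years, the
#' parameterization used in fitting), year effect, observer effect, first-year
#' effect, and (when the draw carries decade-day coefficients) the centered
#' seasonal term. Exposed for transparency and testing; index and trend
#' summaries use the same arithmetic internally.
#'
#' @param record One-row data frame (or list) with `stratum_id`, `year`,
#'   `observer_id`, `route_id`, `first_year`, and `day_of_year` for phenology
#'   draws.
#' @param draw A single posterior draw as a list: `mu` (named by stratum),
#'   `beta` (strata x knots matrix, rownames = strata), `gamma` (strata x
#'   years matrix, dimnames set; optional), `omega` (named by observer unit),
#'   `eta` (scalar), and optionally `alpha` (decades x day-knots,
#'   rownames = decades).
#' @param basis The [build_year_basis()] used in the fit.
#' @param day_basis Optional [build_day_basis()] for the seasonal term.
#' @param observer_unit `"observer_route"` or `"observer"` (must match the fit).
#' @return The log mean (numeric scalar), excluding the overdispersion noise.
#' @export
gamye_log_mean <- function(record, draw, basis, day_basis = NULL,
                           observer_unit = "observer_route") {
  s <- as.character(record$stratum_id)
  if (!s %in% names(draw$mu)) stop("unknown stratum: ", s, call. = FALSE)
  okey <- if (observer_unit == "observer_route") {
    paste(record$observer_id, record$route_id, sep = "|")
  } else {
    as.character(record$observer_id)
  }
  if (!okey %in% names(draw$omega)) stop("unknown observer: ", okey, call. = FALSE)
  xb <- evaluate_basis(basis, record$year)[1, ] - colMeans(basis$matrix)
  out <- draw$mu[[s]] + sum(draw$beta[s, ] * xb) +
    draw$omega[[okey]] + draw$eta * as.numeric(record$first_year)
  if (!is.null(draw$gamma)) {
    out <- out + draw$gamma[s, as.character(record$year)]
  }
  if (!is.null(draw$alpha)) {
    if (is.null(day_basis)) stop("day_basis required for a seasonal draw", call. = FALSE)
    d <- as.character(year_decade(record$year))
    if (!d %in% rownames(draw$alpha)) stop("unknown decade: ", d, call. = FALSE)
    xd <- evaluate_basis(day_basis, record$day_of_year)[1, ] -
      colMeans(day_basis$matrix)
    out <- out + sum(draw$alpha[d, ] * xd)
  }
  unname(out)
}

#' Extract one structured draw from a fit
#'
#' @param fit A `gamye_fit`.
#' @param i Draw index.
#' @return A named-list draw suitable for [gamye_log_mean()].
#' @export
get_draw <- function(fit, i) {
  stopifnot(inherits(fit, "gamye_fit"), i >= 1, i <= length(fit$chain))
  d <- list(
    mu = setNames(fit$draws$mu[i, ], fit$strata_levels),
    beta = matrix(fit$draws$beta[i, , ], nrow = length(fit$strata_levels),
                  dimnames = list(fit$strata_levels, NULL)),
    omega = setNames(fit$draws$omega[i, ], fit$obs_levels),
    eta = fit$draws$eta[i],
    sd_obs = fit$draws$sd_obs[i],
    sd_noise = fit$draws$sd_noise[i]
  )
  if (!is.null(fit$draws$gamma)) {
    d$gamma <- matrix(fit$draws$gamma[i, , ], nrow = length(fit$strata_levels),
                      dimnames = list(fit$strata_levels, as.character(fit$years)))
  }
  if (!is.null(fit$draws$alpha)) {
    d$alpha <- matrix(fit$draws$alpha[i, , ], nrow = length(fit$decades),
                      dimnames = list(as.character(fit$decades), NULL))
    d$sd_alpha <- fit$draws$sd_alpha[i]
  }
  d
}
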