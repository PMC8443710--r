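#' Read and validate a pipeline run configuration
#'
#' The pipeline is driven by a single YAML file so multi-stage runs leave an
#' auditable record. Exactly one of `simulate` (a [sim_config()] field list)
#' or `input` (paths `counts`, `strata`) must be present. Optional blocks:
#' `model` ([gamye_spec()] fields), `phenology` ([phenology_spec()] fields),
#' `mcmc` ([mcmc_options()] fields), `periods` (list of `[y1, y2]`), `level`,
#' `component`, `species_label`, `window`, `year_range`.
#'
#' @param path YAML file path, or a list already in config shape.
#' @param overrides Named list merged over the file contents (command-line
#'   overrides).
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg[names(overrides)] <- overrides
  known <- c("seed", "output_dir", "species_label", "simulate", "input",
             "model", "phenology", "mcmc", "periods", "level", "component",
             "window", "year_range", "allow_nonconverged")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  has_sim <- !is.null(cfg$simulate)
  has_input <- !is.null(cfg$input)
  if (has_sim == has_input) {
    stop("config must contain exactly one of 'simulate' or 'input'", call. = FALSE)
  }
  if (has_input && !all(c("counts", "strata") %in% names(cfg$input))) {
    stop("config field 'input' needs 'counts' and 'strata' paths", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% "gamye-run"
  cfg$level <- cfg$level %||% 0.90
  cfg$component <- cfg$component %||% "smooth"
  cfg$window <- cfg$window %||% c(145, 190)
  cfg$allow_nonconverged <- isTRUE(cfg$allow_nonconverged)
  structure(cfg, class = "run_config")
}

config_dataset <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    if (!is.null(sim_args$seasonal)) {
      sim_args$seasonal <- do.call(seasonal_truth, sim_args$seasonal)
    }
    sim <- simulate_dataset(do.call(sim_config, sim_args))
    sim$dataset
  } else {
    read_dataset(cfg$input$counts, cfg$input$strata,
                 species_label = cfg$species_label %||% "species",
                 window = cfg$window,
                 year_range = cfg$year_range)
  }
}

# long-term (full modeled range) and short-term (final decade, clamped to the
# modeled range for short series)
default_periods <- function(year_range) {
  lt <- c(year_range[1], year_range[2])
  st <- c(max(year_range[1], year_range[2] - 10), year_range[2])
  unique(list(lt, st))
}

write_manifest <- function(cfg, dir, stage, extra = list()) {
  manifest <- c(list(stage = stage, config = unclass(cfg),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                extra)
  jsonlite::write_json(manifest, file.path(dir, paste0("manifest-", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
}

#' Pipeline stage: simulate
#'
#' Generates the configured synthetic dataset, writes the counts/strata files,
#' truth tables, and a run manifest under `output_dir/data`.
#'
#' @param cfg A [read_run_config()] result (or path to one).
#' @return Invisible list of written paths.
#' @export
run_simulate <- function(cfg) {
  cfg <- as_run_config(cfg)
  if (is.null(cfg$simulate)) stop("config has no 'simulate' block", call. = FALSE)
  sim_args <- cfg$simulate
  sim_args$seed <- sim_args$seed %||% cfg$seed
  if (!is.null(sim_args$seasonal)) {
    sim_args$seasonal <- do.call(seasonal_truth, sim_args$seasonal)
  }
  sim <- simulate_dataset(do.call(sim_config, sim_args))
  dir <- file.path(cfg$output_dir, "data")
  paths <- write_simulation(sim, dir)
  write_manifest(cfg, dir, "simulate", list(n_records = nrow(sim$dataset$records)))
  invisible(paths)
}

as_run_config <- function(cfg) {
  if (inherits(cfg, "run_config")) cfg else read_run_config(cfg)
}

#' Pipeline stage: fit
#'
#' Loads (or simulates) the dataset, applies the inclusion filters, fits the
#' requested model(s), and persists the posterior draws, diagnostics table,
#' and manifest under `output_dir/fit-<model>`. Fails on a non-converged fit
#' unless `allow_nonconverged` is set in the config.
#'
#' @param cfg A [read_run_config()] result (or path).
#' @param model `"gamye"`, `"phenology"`, or both.
#' @return Invisible named list of fit directories.
#' @export
run_fit <- function(cfg, model = "gamye") {
  cfg <- as_run_config(cfg)
  stopifnot(all(model %in% c("gamye", "phenology")))
  dataset <- config_dataset(cfg)
  filtered <- apply_inclusion_filters(dataset)
  mcmc <- do.call(mcmc_options, c(cfg$mcmc %||% list(),
                                  if (is.null(cfg$mcmc$seed)) list(seed = cfg$seed)))
  spec <- do.call(gamye_spec, cfg$model %||% list())
  out <- list()
  for (m in model) {
    fit <- if (m == "phenology") {
      if (anyNA(filtered$dataset$records$day_of_year)) {
        stop("phenology model requires day_of_year on every record", call. = FALSE)
      }
      pspec <- do.call(phenology_spec, c(cfg$phenology %||% list(),
                                         list(gamye = spec)))
      fit_gamye_phenology(filtered$dataset, pspec, mcmc)
    } else {
      fit_gamye(filtered$dataset, spec, mcmc)
    }
    if (!fit$converged && !cfg$allow_nonconverged) {
      stop("fit '", m, "' failed convergence diagnostics (max split-R-hat ",
           round(attr(fit$diagnostics, "max_rhat"), 3),
           "); rerun with more iterations or set allow_nonconverged", call. = FALSE)
    }
    dir <- file.path(cfg$output_dir, paste0("fit-", m))
    write_fit(fit, dir)
    readr::write_csv(fit$diagnostics, file.path(dir, "diagnostics.csv"),
                     progress = FALSE)
    write_manifest(cfg, dir, paste0("fit-", m),
                   list(engine = fit$engine, converged = fit$converged))
    out[[m]] <- dir
  }
  invisible(out)
}

#' Pipeline stage: trends
#'
#' Reads a persisted fit, computes stratum and composite annual indices and
#' endpoint trends for the configured periods, and writes `indices.csv` and
#' `trends.csv` under `output_dir/trends`.
#'
#' @param cfg A [read_run_config()] result (or path).
#' @param model Which persisted fit to summarize (default `"gamye"`).
#' @return Invisible list with the trends and indices tibbles.
#' @export
run_trends <- function(cfg, model = "gamye") {
  cfg <- as_run_config(cfg)
  fit <- read_fit(file.path(cfg$output_dir, paste0("fit-", model)))
  periods <- cfg$periods %||% default_periods(range(fit$years))
  periods <- lapply(periods, as.numeric)
  indices <- compute_indices(fit, component = cfg$component)
  all_idx <- dplyr::bind_rows(indices, composite_index(indices))
  class(all_idx) <- class(indices)
  attr(all_idx, "species_label") <- attr(indices, "species_label")
  trends <- summarize_trends(all_idx, periods, level = cfg$level)
  dir <- file.path(cfg$output_dir, "trends")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(trends, file.path(dir, "trends.csv"), progress = FALSE)
  readr::write_csv(summarize_indices(all_idx, level = cfg$level),
                   file.path(dir, "indices.csv"), progress = FALSE)
  write_manifest(cfg, dir, "trends")
  invisible(list(trends = trends, indices = all_idx))
}

#' Pipeline stage: phenology check
#'
#' Reads the persisted standard and phenology-corrected fits, writes the
#' decade-peak table and the standard-vs-corrected trend comparison (95%
#' interval on the difference) under `output_dir/phenology`.
#'
#' @param cfg A [read_run_config()] result (or path).
#' @param period Comparison period; default the full modeled range.
#' @return Invisible list with `peaks` and `comparison`.
#' @export
run_phenology_check <- function(cfg, period = NULL) {
  cfg <- as_run_config(cfg)
  std_dir <- file.path(cfg$output_dir, "fit-gamye")
  cor_dir <- file.path(cfg$output_dir, "fit-phenology")
  for (d in c(std_dir, cor_dir)) {
    if (!dir.exists(d)) {
      stop("missing persisted fit at '", d, "'; run run_fit(cfg, model = c(\"gamye\", \"phenology\")) first",
           call. = FALSE)
    }
  }
  standard <- read_fit(std_dir)
  corrected <- read_fit(cor_dir)
  period <- period %||% range(corrected$years)
  peaks <- estimate_decade_peaks(corrected)
  cmp <- compare_trends(standard, corrected, period, level = 0.95)
  dir <- file.path(cfg$output_dir, "phenology")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(peaks, file.path(dir, "decade_peaks.csv"), progress = FALSE)
  readr::write_csv(cmp$trends, file.path(dir, "trend_comparison.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(period = period, level = cmp$level,
         difference = as.list(cmp$difference)),
    file.path(dir, "trend_difference.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  write_manifest(cfg, dir, "phenology")
  invisible(list(peaks = peaks, comparison = cmp))
}

# ---- fit persistence (delimited text + JSON, no binary formats) ------------

#' Persist a fit as a draw table plus JSON metadata
#'
#' Draws go to `draws.csv` (one row per draw, a `chain` column, one column per
#' scalar parameter named like `beta[2,3]`); everything needed to rebuild the
#' fit goes to `meta.json`.
#'
#' @param fit A `gamye_fit`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "gamye_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mat <- draws_matrix(fit)
  draws_tbl <- tibble::as_tibble(mat, .name_repair = "minimal")
  draws_tbl <- dplyr::bind_cols(tibble::tibble(chain = fit$chain), draws_tbl)
  readr::write_csv(draws_tbl, file.path(dir, "draws.csv"), progress = FALSE)
  meta <- list(
    strata_levels = fit$strata_levels,
    years = fit$years,
    obs_levels = fit$obs_levels,
    decades = fit$decades,
    decades_observed = fit$decades_observed,
    spec = unclass(fit$spec),
    phenology = if (!is.null(fit$phenology)) {
      p <- unclass(fit$phenology)
      p$gamye <- NULL
      p
    },
    mcmc = unclass(fit$mcmc),
    basis = list(n_knots = ncol(fit$year_basis$matrix),
                 degree = fit$year_basis$degree),
    dataset_info = list(
      species_label = fit$dataset_info$species_label,
      n_records = fit$dataset_info$n_records,
      n_routes = fit$dataset_info$n_routes,
      strata = fit$dataset_info$strata
    ),
    engine = fit$engine,
    converged = fit$converged
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Rebuild a fit from [write_fit()] output
#'
#' @param dir Directory containing `draws.csv` and `meta.json`.
#' @return A `gamye_fit` (diagnostics recomputed from the stored draws).
#' @export
read_fit <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  draws_tbl <- readr::read_csv(file.path(dir, "draws.csv"),
                               show_col_types = FALSE, progress = FALSE)
  chain <- draws_tbl$chain
  mat <- as.matrix(draws_tbl[, -1])
  spec <- structure(meta$spec, class = "gamye_spec")
  spec$n_knots <- meta$basis$n_knots
  phen <- NULL
  if (!is.null(meta$phenology) && length(meta$phenology)) {
    phen <- phenology_spec(day_basis_knots = meta$phenology$day_basis_knots,
                           day_window = meta$phenology$day_window,
                           walk_order = meta$phenology$walk_order,
                           alpha1_sd = meta$phenology$alpha1_sd,
                           gamye = spec)
  }
  years <- meta$years
  basis <- build_year_basis(years, n_knots = meta$basis$n_knots,
                            degree = meta$basis$degree)
  day_basis <- NULL
  if (!is.null(phen)) {
    day_basis <- build_day_basis(seq(phen$day_window[1], phen$day_window[2]),
                                 n_knots = phen$day_basis_knots,
                                 degree = spec$basis_degree)
  }
  n_s <- length(meta$strata_levels)
  grab <- make_grab(mat)
  draws <- list(
    mu = grab("mu", n_s),
    B = grab("B", meta$basis$n_knots),
    beta = grab("beta", c(n_s, meta$basis$n_knots)),
    sd_B = grab("sd_B", integer(0)),
    omega = grab("omega", length(meta$obs_levels)),
    sd_obs = grab("sd_obs", integer(0)),
    eta = grab("eta", integer(0)),
    sd_noise = grab("sd_noise", integer(0))
  )
  if (isTRUE(spec$year_effects)) {
    draws$gamma <- grab("gamma", c(n_s, length(years)))
    draws$sd_gamma <- grab("sd_gamma", n_s)
  }
  if (!is.null(phen)) {
    draws$alpha <- grab("alpha", c(length(meta$decades), phen$day_basis_knots))
    draws$sd_alpha <- grab("sd_alpha", integer(0))
  }
  fit <- structure(
    list(
      draws = draws, chain = chain,
      strata_levels = meta$strata_levels, years = years,
      obs_levels = meta$obs_levels,
      year_basis = basis, year_center = colMeans(basis$matrix),
      day_basis = day_basis,
      decades = meta$decades, decades_observed = meta$decades_observed,
      spec = spec, phenology = phen,
      mcmc = structure(meta$mcmc, class = "mcmc_options"),
      dataset_info = list(
        species_label = meta$dataset_info$species_label,
        n_records = meta$dataset_info$n_records,
        n_routes = meta$dataset_info$n_routes,
        strata = tibble::as_tibble(meta$dataset_info$strata)
      ),
      engine = meta$engine
    ),
    class = "gamye_fit"
  )
  fit$diagnostics <- check_convergence(fit)
  fit$converged <- isTRUE(attr(fit$diagnostics, "pass"))
  fit
}
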