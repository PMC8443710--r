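#' Default column mapping for count files
#'
#' Count files are UTF-8 delimited text with one row per route visit. The
#' dialect maps the canonical field names used throughout the package to the
#' column names actually present in the file, so differently laid-out deposits
#' parse without code changes.
#'
#' @param ... Named overrides, e.g. `count = "SpeciesTotal"`.
#' @return Named character vector mapping canonical names to file columns.
#' @export
#' @examples
#' count_dialect(route_id = "Route", count = "SpeciesTotal")
count_dialect <- function(...) {
  dialect <- c(
    route_id = "route_id", stratum_id = "stratum_id", year = "year",
    day_of_year = "day_of_year", observer_id = "observer_id",
    first_year = "first_year", count = "count", valid = "valid"
  )
  overrides <- c(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(dialect))
    if (length(bad)) {
      stop("unknown dialect field(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    dialect[names(overrides)] <- overrides
  }
  dialect
}

#' Read route-level survey counts from delimited text
#'
#' Reads one record per route visit: route and stratum identifiers, calendar
#' year, day of year, observer identifier, first-year-observer flag, the count
#' summed over all stops, and a protocol-validity flag. Rows violating the
#' record invariants (negative or non-integer count, day of year outside
#' 1--366, missing required fields) are rejected; their line numbers are
#' reported in the `problems` attribute and a warning.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Column-name map from [count_dialect()].
#' @param delim Field delimiter (default comma).
#' @return A tibble of survey records with canonical columns `route_id`,
#'   `stratum_id`, `year`, `day_of_year`, `observer_id`, `first_year`
#'   (logical), `count` (integer), `valid` (logical). Rejected rows are
#'   attached as the `problems` attribute (tibble of row numbers and reasons).
#' @export
read_counts <- function(path, dialect = count_dialect(), delim = ",") {
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  missing_cols <- setdiff(unname(dialect), names(raw))
  if (length(missing_cols)) {
    stop("counts file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, unname(dialect)]
  names(raw) <- names(dialect)
  parsed <- dplyr::mutate(
    raw,
    .row = dplyr::row_number(),
    year = suppressWarnings(as.integer(.data$year)),
    day_of_year = suppressWarnings(as.integer(.data$day_of_year)),
    count = suppressWarnings(as.numeric(.data$count)),
    first_year = parse_flag(.data$first_year),
    valid = parse_flag(.data$valid)
  )
  problems <- record_problems(parsed)
  keep <- !parsed$.row %in% problems$row
  records <- dplyr::select(
    dplyr::mutate(parsed[keep, ], count = as.integer(.data$count)),
    -".row"
  )
  if (nrow(problems)) {
    warning(nrow(problems), " row(s) rejected; see attr(, 'problems')", call. = FALSE)
  }
  attr(records, "problems") <- problems
  records
}

# 0/1, TRUE/FALSE, T/F and yes/no all appear in the wild
parse_flag <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t", "yes")] <- TRUE
  out[x %in% c("0", "false", "f", "no")] <- FALSE
  out
}

record_problems <- function(parsed) {
  checks <- list(
    `unparsable or missing year` = is.na(parsed$year),
    `unparsable count` = is.na(parsed$count),
    `negative or non-integer count` = !is.na(parsed$count) &
      (parsed$count < 0 | parsed$count != floor(parsed$count)),
    `day_of_year outside 1-366` = is.na(parsed$day_of_year) |
      parsed$day_of_year < 1 | parsed$day_of_year > 366,
    `missing route or stratum id` = is.na(parsed$route_id) | is.na(parsed$stratum_id),
    `unparsable first_year/valid flag` = is.na(parsed$first_year) | is.na(parsed$valid)
  )
  purrr::map_dfr(names(checks), function(reason) {
    tibble::tibble(row = parsed$.row[checks[[reason]]], reason = reason)
  })
}

#' Read the stratum table
#'
#' @param path Delimited text with header columns `stratum_id`, `region`,
#'   `bcr`, `area_km2`.
#' @param delim Field delimiter.
#' @return Tibble with one row per stratum; errors on duplicate ids or
#'   non-positive areas.
#' @export
read_strata <- function(path, delim = ",") {
  if (!file.exists(path)) stop("strata file not found: ", path, call. = FALSE)
  strata <- readr::read_delim(
    path, delim = delim, progress = FALSE,
    col_types = readr::cols(
      stratum_id = "c", region = "c", bcr = "c", area_km2 = "d"
    )
  )
  validate_strata(strata)
  strata
}

validate_strata <- function(strata) {
  required <- c("stratum_id", "region", "bcr", "area_km2")
  missing_cols <- setdiff(required, names(strata))
  if (length(missing_cols)) {
    stop("strata table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(strata$stratum_id)) {
    stop("duplicate stratum_id in strata table", call. = FALSE)
  }
  if (any(!is.finite(strata$area_km2) | strata$area_km2 <= 0)) {
    stop("stratum areas must be positive", call. = FALSE)
  }
  invisible(strata)
}

#' Screen records for protocol validity and survey window
#'
#' Drops runs flagged invalid (collected outside permissible dates, times of
#' day, or weather) and any record whose day of year falls outside the
#' permissible survey window. The default window, day of year 145--190,
#' corresponds to the late-May-to-early-July roadside survey season.
#'
#' @param records Tibble of survey records (see [read_counts()]).
#' @param window Length-2 numeric, `c(day_min, day_max)`, inclusive.
#' @return The surviving records, with the number of dropped records attached
#'   as attribute `dropped`.
#' @export
screen_validity <- function(records, window = c(145, 190)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  kept <- dplyr::filter(
    records,
    .data$valid,
    .data$day_of_year >= window[1],
    .data$day_of_year <= window[2]
  )
  attr(kept, "problems") <- NULL
  attr(kept, "dropped") <- nrow(records) - nrow(kept)
  kept
}

#' Sum stop-level counts to one record per route and year
#'
#' Roadside surveys record counts at each of ~50 stops along a route;
#' abundance analyses use the route total, one count per species per route
#' per year.
#'
#' @param stop_level Tibble with columns `route_id`, `year`, `stop`, `count`,
#'   plus any per-visit columns (`stratum_id`, `day_of_year`, `observer_id`,
#'   `first_year`, `valid`) which must be constant within a route-year and are
#'   carried through.
#' @return Tibble with one row per route-year, `count` summed over stops.
#' @export
aggregate_stops <- function(stop_level) {
  stopifnot(all(c("route_id", "year", "stop", "count") %in% names(stop_level)))
  dup <- dplyr::count(stop_level, .data$route_id, .data$year, .data$stop) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("duplicate (route, year, stop) triple(s): ",
         paste(sprintf("(%s, %s, %s)", dup$route_id, dup$year, dup$stop),
               collapse = "; "),
         call. = FALSE)
  }
  carry <- intersect(
    c("stratum_id", "day_of_year", "observer_id", "first_year", "valid"),
    names(stop_level)
  )
  stop_level |>
    dplyr::group_by(.data$route_id, .data$year) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(carry), dplyr::first),
      count = as.integer(sum(.data$count)),
      .groups = "drop"
    )
}

#' Bundle records and strata into a species dataset
#'
#' The unit of model fitting: screened survey records for one species plus
#' the stratum table, a species label, and the modeled year range.
#'
#' @param records Tibble of survey records, already passed through
#'   [screen_validity()]; at most one record per route-year.
#' @param strata Stratum table (see [read_strata()]).
#' @param species_label Character label carried into outputs.
#' @param year_range Length-2 integer, first and last modeled year. Defaults
#'   to the record range. Records outside it are dropped.
#' @return An object of class `species_dataset`: a list with elements
#'   `records`, `strata`, `species_label`, `year_range`.
#' @export
species_dataset <- function(records, strata, species_label = "species",
                            year_range = range(records$year)) {
  validate_strata(strata)
  stopifnot(length(year_range) == 2, year_range[1] < year_range[2])
  records <- dplyr::filter(records, .data$year >= year_range[1],
                           .data$year <= year_range[2])
  orphan <- setdiff(unique(records$stratum_id), strata$stratum_id)
  if (length(orphan)) {
    stop("record stratum_id(s) absent from strata table: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  dup <- dplyr::count(records, .data$route_id, .data$year) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("more than one record per route-year; aggregate stops first",
         call. = FALSE)
  }
  structure(
    list(
      records = tibble::as_tibble(records),
      strata = dplyr::filter(strata, .data$stratum_id %in% unique(records$stratum_id) |
                               nrow(records) == 0),
      species_label = species_label,
      year_range = as.integer(year_range)
    ),
    class = "species_dataset"
  )
}

#' @export
print.species_dataset <- function(x, ...) {
  cat("<species_dataset> ", x$species_label, "\n", sep = "")
  cat("  years: ", x$year_range[1], "-", x$year_range[2], "\n", sep = "")
  cat("  records: ", nrow(x$records),
      " | routes: ", dplyr::n_distinct(x$records$route_id),
      " | strata: ", dplyr::n_distinct(x$records$stratum_id), "\n", sep = "")
  invisible(x)
}

#' Apply minimum-data inclusion filters
#'
#' A stratum enters the model only if, within the modeled year range, it has
#' (1) at least three routes on which the species was observed (any count
#' greater than zero), (2) at least one such route surveyed in five or more
#' distinct years, and (3) at least one route on which the species was
#' observed in three or more distinct years. Strata failing any criterion are
#' dropped, with the failing criteria recorded in the filter report.
#'
#' @param dataset A [species_dataset()] whose records passed
#'   [screen_validity()].
#' @param min_routes Minimum routes with the species observed (default 3).
#' @param min_years_surveyed Minimum distinct surveyed years on at least one
#'   observed route (default 5).
#' @param min_years_observed Minimum distinct years with nonzero counts on at
#'   least one route (default 3).
#' @return A list with `dataset` (the filtered `species_dataset`) and
#'   `report`, a tibble with one row per input stratum: logical columns
#'   `enough_routes`, `enough_years_surveyed`, `enough_years_observed`,
#'   `kept`, plus attributes `routes_kept` and `records_dropped`.
#'   Errors if no stratum survives.
#' @export
apply_inclusion_filters <- function(dataset, min_routes = 3,
                                    min_years_surveyed = 5,
                                    min_years_observed = 3) {
  stopifnot(inherits(dataset, "species_dataset"))
  recs <- dataset$records

  route_stats <- recs |>
    dplyr::group_by(.data$stratum_id, .data$route_id) |>
    dplyr::summarise(
      observed = any(.data$count > 0),
      years_surveyed = dplyr::n_distinct(.data$year),
      years_observed = dplyr::n_distinct(.data$year[.data$count > 0]),
      .groups = "drop"
    )

  report <- route_stats |>
    dplyr::group_by(.data$stratum_id) |>
    dplyr::summarise(
      enough_routes = sum(.data$observed) >= min_routes,
      enough_years_surveyed =
        any(.data$observed & .data$years_surveyed >= min_years_surveyed),
      enough_years_observed =
        any(.data$years_observed >= min_years_observed),
      .groups = "drop"
    ) |>
    dplyr::mutate(kept = .data$enough_routes & .data$enough_years_surveyed &
                    .data$enough_years_observed)

  kept_ids <- report$stratum_id[report$kept]
  if (!length(kept_ids)) {
    stop("no modelable strata: every stratum fails the minimum-data criteria",
         call. = FALSE)
  }
  surviving <- dplyr::filter(recs, .data$stratum_id %in% kept_ids)
  out <- dataset
  out$records <- surviving
  out$strata <- dplyr::filter(dataset$strata, .data$stratum_id %in% kept_ids)

  attr(report, "routes_kept") <- dplyr::n_distinct(surviving$route_id)
  attr(report, "records_dropped") <- nrow(recs) - nrow(surviving)
  list(dataset = out, report = report)
}

#' Write a species dataset to delimited text
#'
#' @param dataset A [species_dataset()].
#' @param counts_path,strata_path Output file paths.
#' @return `dataset`, invisibly.
#' @export
write_dataset <- function(dataset, counts_path, strata_path) {
  stopifnot(inherits(dataset, "species_dataset"))
  recs <- dplyr::mutate(dataset$records,
                        first_year = as.integer(.data$first_year),
                        valid = as.integer(.data$valid))
  readr::write_csv(recs, counts_path, progress = FALSE)
  readr::write_csv(dataset$strata, strata_path, progress = FALSE)
  invisible(dataset)
}

#' Read a species dataset from delimited text
#'
#' Convenience inverse of [write_dataset()]: reads, screens, and bundles.
#'
#' @inheritParams read_counts
#' @param counts_path,strata_path Input file paths.
#' @param species_label Label for the dataset.
#' @param window Survey-day screening window passed to [screen_validity()].
#' @param year_range Modeled year range; default is the record range.
#' @return A [species_dataset()].
#' @export
read_dataset <- function(counts_path, strata_path, species_label = "species",
                         dialect = count_dialect(), window = c(145, 190),
                         year_range = NULL) {
  records <- read_counts(counts_path, dialect = dialect)
  records <- screen_validity(records, window = window)
  strata <- read_strata(strata_path)
  if (is.null(year_range)) year_range <- range(records$year)
  species_dataset(records, strata, species_label = species_label,
                  year_range = year_range)
}
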