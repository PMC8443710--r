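#' B-spline basis over the modeled years
#'
#' Builds the design matrix for the long-term smooth: a B-spline basis of the
#' given degree with evenly spaced interior knots over the (rescaled) year
#' range and coincident boundary knots, so the rows form a partition of unity
#' and every entry lies in \[0, 1\].
#'
#' @param years Ordered integer vector of years to evaluate at.
#' @param n_knots Basis dimension (number of columns); default one basis
#'   function per ~4 years, `ceiling(n_years / 4)`, floored at `degree + 1`.
#' @param degree Spline degree (default 3, cubic).
#' @return A list of class `year_basis`: `years`, `matrix`
#'   (`length(years)` x `n_knots`), `knots` (the full knot vector on the
#'   original year scale), `degree`.
#' @export
#' @examples
#' b <- build_year_basis(1970:2019, n_knots = 13)
#' range(rowSums(b$matrix))  # partition of unity
build_year_basis <- function(years,
                             n_knots = max(ceiling(length(years) / 4), degree + 1),
                             degree = 3) {
  stopifnot(length(years) >= 2, !is.unsorted(years), degree >= 1)
  if (n_knots < degree + 1) {
    stop("n_knots must be at least degree + 1 (= ", degree + 1, ")", call. = FALSE)
  }
  if (n_knots > length(years)) {
    stop("too few years (", length(years), ") for ", n_knots,
         " basis functions; feasible maximum is ", length(years), call. = FALSE)
  }
  bs_basis(as.numeric(years), n_knots, degree, label = "year_basis")
}

#' B-spline basis over the survey-day window
#'
#' Same construction as [build_year_basis()] but over a day-of-year grid
#' inside the permissible survey window; used by the phenology-corrected
#' model's decade-specific date smooths.
#'
#' @param days Ordered integer grid of days of year (e.g. `145:190`).
#' @param n_knots Basis dimension; must be at least `degree + 1` and at most
#'   the grid size.
#' @param degree Spline degree (default 3).
#' @return A `year_basis` list evaluated over `days`.
#' @export
build_day_basis <- function(days, n_knots = 5, degree = 3) {
  stopifnot(length(days) >= 2, !is.unsorted(days), degree >= 1)
  if (n_knots < 3) stop("day basis needs at least 3 knots", call. = FALSE)
  if (n_knots < degree + 1) {
    stop("n_knots must be at least degree + 1 (= ", degree + 1, ")", call. = FALSE)
  }
  if (n_knots > length(days)) {
    stop("too few grid points (", length(days), ") for ", n_knots,
         " basis functions; feasible maximum is ", length(days), call. = FALSE)
  }
  bs_basis(as.numeric(days), n_knots, degree, label = "day_basis")
}

# shared constructor: coincident boundary knots + evenly spaced interior knots
bs_basis <- function(x, n_knots, degree, label) {
  lo <- min(x)
  hi <- max(x)
  n_interior <- n_knots - degree - 1
  interior <- if (n_interior > 0) {
    seq(lo, hi, length.out = n_interior + 2)[-c(1, n_interior + 2)]
  } else {
    numeric(0)
  }
  knots <- c(rep(lo, degree + 1), interior, rep(hi, degree + 1))
  m <- splines::splineDesign(knots, x, ord = degree + 1)
  colnames(m) <- paste0("k", seq_len(ncol(m)))
  structure(
    list(x = x, years = x, matrix = m, knots = knots, degree = degree),
    class = c(label, "year_basis")
  )
}

#' Evaluate a basis at new points
#'
#' @param basis A `year_basis` from [build_year_basis()] or
#'   [build_day_basis()].
#' @param x Points inside the basis range.
#' @return Matrix `length(x)` x `n_knots`.
#' @export
evaluate_basis <- function(basis, x) {
  stopifnot(inherits(basis, "year_basis"))
  rng <- range(basis$x)
  if (any(x < rng[1] | x > rng[2])) {
    stop("evaluation points outside basis range [", rng[1], ", ", rng[2], "]",
         call. = FALSE)
  }
  splines::splineDesign(basis$knots, as.numeric(x), ord = basis$degree + 1)
}

# basis columns centered over the evaluation grid, so any coefficient vector
# yields a curve with mean zero over that grid (phenology identifiability)
center_basis_matrix <- function(basis) {
  sweep(basis$matrix, 2, colMeans(basis$matrix))
}
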