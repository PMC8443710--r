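#' Decade-specific seasonal curves from a phenology fit
#'
#' Evaluates each decade's centered day-of-year smooth on a day grid, per
#' posterior draw: `s_d(day) = sum_k alpha_dk * (D(day,k) - meanGrid D(.,k))`.
#'
#' @param fit A `gamye_fit` from [fit_gamye_phenology()].
#' @param day_grid Integer grid of days; defaults to the fit's survey window.
#' @return Tibble with `decade`, `day`, `draw`, `effect` (log scale).
#' @export
decade_curves <- function(fit, day_grid = NULL) {
  stopifnot(inherits(fit, "gamye_fit"))
  if (is.null(fit$draws$alpha)) {
    stop("fit has no seasonal term; use fit_gamye_phenology()", call. = FALSE)
  }
  day_grid <- day_grid %||% fit$day_basis$x
  Dc <- sweep(evaluate_basis(fit$day_basis, day_grid), 2,
              colMeans(fit$day_basis$matrix))
  n_draw <- length(fit$chain)
  n_dec <- length(fit$decades)
  alpha_flat <- matrix(fit$draws$alpha, nrow = n_draw * n_dec)  # (draw*dec) x k
  curves <- array(alpha_flat %*% t(Dc), dim = c(n_draw, n_dec, length(day_grid)))
  out <- tidyr::expand_grid(
    decade = fit$decades, day = as.numeric(day_grid), draw = seq_len(n_draw)
  )
  out$effect <- as.vector(aperm(curves, c(1, 3, 2)))
  out
}

#' Posterior decade peaks and lead/lag shifts
#'
#' For each draw and decade, the peak day is the argmax of the decade's
#' seasonal curve over the day grid; the shift is that decade's peak minus the
#' preceding decade's, so negative shifts mean the peak leads (comes earlier).
#' Summaries are posterior medians with equal-tailed intervals. A decade whose
#' posterior-median curve has amplitude (max minus min) below `min_amplitude`
#' on the log scale is flagged undefined: the argmax of an essentially flat
#' curve is a grid-edge artifact, not a peak.
#'
#' @param fit A `gamye_fit` from [fit_gamye_phenology()].
#' @param day_grid Integer day grid; defaults to the fit's survey window.
#' @param level Credible-interval mass (default 0.90).
#' @param min_amplitude Log-scale amplitude below which the peak is reported
#'   undefined (default 0.01).
#' @return Tibble with one row per decade: `decade`, `peak_day`,
#'   `peak_day_lower`, `peak_day_upper`, `shift_vs_previous`, `shift_lower`,
#'   `shift_upper`, `amplitude`, `peak_defined`, `decade_observed`.
#' @export
estimate_decade_peaks <- function(fit, day_grid = NULL, level = 0.90,
                                  min_amplitude = 0.01) {
  day_grid <- day_grid %||% fit$day_basis$x
  curves <- decade_curves(fit, day_grid)
  n_draw <- length(fit$chain)

  peaks <- curves |>
    dplyr::group_by(.data$decade, .data$draw) |>
    dplyr::summarise(peak = .data$day[which.max(.data$effect)], .groups = "drop")

  med_amp <- curves |>
    dplyr::group_by(.data$decade, .data$day) |>
    dplyr::summarise(med = median(.data$effect), .groups = "drop") |>
    dplyr::group_by(.data$decade) |>
    dplyr::summarise(amplitude = max(.data$med) - min(.data$med), .groups = "drop")

  peak_wide <- peaks |>
    tidyr::pivot_wider(names_from = "decade", values_from = "peak") |>
    dplyr::arrange(.data$draw)
  decs <- fit$decades

  out <- purrr::map_dfr(seq_along(decs), function(j) {
    pd <- peak_wide[[as.character(decs[j])]]
    ci <- credible_interval(pd, level)
    if (j > 1) {
      shift <- pd - peak_wide[[as.character(decs[j - 1])]]
      cs <- credible_interval(shift, level)
    } else {
      cs <- c(lower = NA_real_, median = NA_real_, upper = NA_real_)
    }
    tibble::tibble(
      decade = decs[j],
      peak_day = ci[["median"]], peak_day_lower = ci[["lower"]],
      peak_day_upper = ci[["upper"]],
      shift_vs_previous = cs[["median"]], shift_lower = cs[["lower"]],
      shift_upper = cs[["upper"]]
    )
  })
  out <- dplyr::left_join(out, med_amp, by = "decade") |>
    dplyr::mutate(
      peak_defined = .data$amplitude >= min_amplitude,
      decade_observed = fit$decades_observed
    )
  out$peak_day[!out$peak_defined] <- NA_real_
  out$peak_day_lower[!out$peak_defined] <- NA_real_
  out$peak_day_upper[!out$peak_defined] <- NA_real_
  out
}

#' Compare standard and phenology-corrected trend estimates
#'
#' Computes each model's composite endpoint annual trend per draw (smooth
#' component by default, the standard choice for trend estimation) and the
#' posterior of their difference (corrected minus standard), draws paired by
#' index. The comparison interval defaults to 95%, the convention for model
#' contrasts; trends themselves are also reported at that level.
#'
#' @param standard A `gamye_fit` from [fit_gamye()].
#' @param corrected A `gamye_fit` from [fit_gamye_phenology()] on the same
#'   dataset.
#' @param period Length-2 numeric `c(y1, y2)`.
#' @param level Interval mass (default 0.95).
#' @param component Index component for the trend (default `"smooth"`).
#' @return A list with `trends` (tibble: model, annual rate median/interval)
#'   and `difference` (named vector lower/median/upper of corrected - standard
#'   annual rate, %/year), plus `level` and `period`.
#' @export
compare_trends <- function(standard, corrected, period, level = 0.95,
                           component = "smooth") {
  stopifnot(inherits(standard, "gamye_fit"), inherits(corrected, "gamye_fit"))
  if (!identical(standard$years, corrected$years)) {
    stop("fits cover different year ranges; refit on the same dataset",
         call. = FALSE)
  }
  rate_of <- function(fit) {
    idx <- composite_index(compute_indices(fit, component = component))
    endpoint_trend(idx, period[1], period[2])
  }
  r_std <- rate_of(standard)
  r_cor <- rate_of(corrected)
  n <- min(length(r_std), length(r_cor))
  diff_draws <- r_cor[seq_len(n)] - r_std[seq_len(n)]
  trends <- dplyr::bind_rows(
    tibble::tibble(model = "standard", !!!as.list(credible_interval(r_std, level))),
    tibble::tibble(model = "corrected", !!!as.list(credible_interval(r_cor, level)))
  )
  list(
    trends = trends,
    difference = credible_interval(diff_draws, level),
    level = level,
    period = period
  )
}
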