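test_that("indices reduce to exp(0) = 1 when all parameters are zero", {
  fit <- manual_fit(mu = matrix(0, 2, 2), beta = array(0, c(2, 2, 4)),
                    gamma = array(0, c(2, 2, 5)))
  idx <- compute_indices(fit, "full")
  expect_true(all(idx$index == 1))
})

test_that("indices match hand computation for a known single draw", {
  years <- 2000:2004
  basis <- build_year_basis(years, n_knots = 4)
  beta <- array(0, c(2, 2, 4))
  beta[1, 1, ] <- c(0.3, -0.2, 0.1, 0.25)   # draw 1, stratum A
  beta[1, 2, ] <- c(-0.1, 0.2, 0.0, -0.15)  # draw 1, stratum B
  beta[2, , ] <- beta[1, , ]
  mu <- matrix(c(1, 1, 0.5, 0.5), 2, 2)     # columns = strata
  gamma <- array(0, c(2, 2, 5))
  gamma[, 1, 3] <- 0.2                       # stratum A, year 2002
  fit <- manual_fit(mu = mu, beta = beta, gamma = gamma,
                    sd_obs = 0.2, sd_noise = 0.1)

  idx <- compute_indices(fit, "full")
  xc <- sweep(basis$matrix, 2, colMeans(basis$matrix))
  for (s in 1:2) {
    for (y in seq_along(years)) {
      expected <- exp(mu[1, s] + sum(beta[1, s, ] * xc[y, ]) + gamma[1, s, y] +
                        0.2^2 / 2 + 0.1^2 / 2)
      got <- idx$index[idx$region == c("A", "B")[s] &
                         idx$year == years[y] & idx$draw == 1]
      expect_equal(got, expected, tolerance = 1e-12)
    }
  }
})

test_that("full and smooth components differ exactly where gamma is nonzero", {
  gamma <- array(0, c(2, 2, 5))
  gamma[, 2, 4] <- 0.5
  fit <- manual_fit(mu = matrix(0, 2, 2), beta = array(0, c(2, 2, 4)),
                    gamma = gamma)
  full <- compute_indices(fit, "full")
  smooth <- compute_indices(fit, "smooth")
  diff_rows <- full$index != smooth$index
  expect_true(all(full$region[diff_rows] == "B" & full$year[diff_rows] == 2003))
  expect_equal(sum(diff_rows), 2)  # both draws
})

test_that("composite index is the area-weighted stratum mean", {
  fit <- manual_fit(mu = matrix(c(log(2), log(2), log(4), log(4)), 2, 2),
                    beta = array(0, c(2, 2, 4)), areas = c(1, 1))
  idx <- compute_indices(fit, "full")
  comp <- composite_index(idx)
  expect_true(all(abs(comp$index - 3) < 1e-12))  # equal areas: (2 + 4) / 2

  # three strata, areas 1,2,3, indices 1,1,4 -> (1 + 2 + 12) / 6 = 2.5
  fit3 <- manual_fit(mu = matrix(log(c(1, 1, 1, 1, 4, 4)), 2, 3),
                     beta = array(0, c(2, 3, 4)),
                     strata = c("A", "B", "C"), areas = c(1, 2, 3))
  comp3 <- composite_index(compute_indices(fit3, "full"))
  expect_true(all(abs(comp3$index - 2.5) < 1e-12))

  # single stratum: composite equals the stratum index; requesting the smooth
  # component without year effects falls back to full with a warning
  fit1 <- manual_fit(mu = matrix(0.7, 2, 1), beta = array(0, c(2, 1, 4)),
                     strata = "A", areas = 5)
  expect_warning(idx1 <- compute_indices(fit1, "smooth"),
                 "'smooth' equals 'full'")
  comp1 <- composite_index(idx1)
  expect_equal(comp1$index, idx1$index)

  bad <- idx
  attr(bad, "strata") <- toy_strata("A")
  expect_error(composite_index(bad), "no area for stratum: B")
})

test_that("composite is monotone in each stratum index", {
  fit <- manual_fit(mu = matrix(c(0, 0, 0, 0.4), 2, 2),
                    beta = array(0, c(2, 2, 4)), areas = c(2, 3))
  comp <- composite_index(compute_indices(fit, "full"))
  # draw 2 raises stratum B only; every composite value must increase
  c1 <- comp$index[comp$draw == 1]
  c2 <- comp$index[comp$draw == 2]
  expect_true(all(c2 > c1))
})

test_that("endpoint trend follows the compound-growth closed form", {
  flat <- tibble::tibble(year = rep(c(2000, 2010), each = 2),
                         draw = rep(1:2, 2), index = 5)
  expect_equal(endpoint_trend(flat, 2000, 2010), c(0, 0))

  doubling <- tibble::tibble(year = rep(c(2000, 2010), each = 1), draw = 1,
                             index = c(1, 2))
  expect_equal(endpoint_trend(doubling, 2000, 2010), 100 * (2^0.1 - 1),
               tolerance = 1e-12)

  scaled <- dplyr::mutate(doubling, index = index * 17.3)
  expect_equal(endpoint_trend(scaled, 2000, 2010),
               endpoint_trend(doubling, 2000, 2010), tolerance = 1e-12)

  expect_error(endpoint_trend(doubling, 2010, 2000), "earlier")
  expect_error(endpoint_trend(doubling, 1990, 2010), "outside modeled years")
})

test_that("rate-to-change compounding matches the printed long-term pairs", {
  expect_equal(round(trend_to_percent_change(-4.3, 1970, 2019)), -88)
  expect_equal(round(trend_to_percent_change(1.2, 1970, 2019)), 79)
  expect_equal(trend_to_percent_change(0, 1970, 2019), 0)
  expect_error(trend_to_percent_change(-100, 2000, 2010), "-100")
})

test_that("endpoint trend and percent change are exact inverses per draw", {
  withr::local_seed(3)
  idx <- tibble::tibble(
    year = rep(c(1970, 2019), each = 50), draw = rep(1:50, 2),
    index = exp(rnorm(100, 1, 0.5))
  )
  rate <- endpoint_trend(idx, 1970, 2019)
  change <- trend_to_percent_change(rate, 1970, 2019)
  i1 <- idx$index[idx$year == 1970][order(idx$draw[idx$year == 1970])]
  i2 <- idx$index[idx$year == 2019][order(idx$draw[idx$year == 2019])]
  expect_equal(change, 100 * (i2 / i1 - 1), tolerance = 1e-10)
})

test_that("credible intervals follow the type-7 percentile rule", {
  ci <- credible_interval(1:100, 0.90)
  # oracle: sort-based linear interpolation between order statistics
  expect_equal(unname(ci), c(1 + 0.05 * 99, 1 + 0.5 * 99, 1 + 0.95 * 99))
  expect_equal(unname(credible_interval(rep(4.2, 10), 0.9)), c(4.2, 4.2, 4.2))
  expect_lte(credible_interval(rnorm(50), 0.5)[["lower"]],
             credible_interval(rnorm(50), 0.5)[["median"]])
  expect_error(credible_interval(numeric(0)), "nonempty")
  expect_error(credible_interval(1:10, 1), "strictly between")
  expect_error(credible_interval(1:10, 0), "strictly between")
  near_zero <- credible_interval(1:101, 1e-9)
  expect_equal(unname(near_zero[1]), 51, tolerance = 1e-6)
  expect_equal(unname(near_zero[3]), 51, tolerance = 1e-6)
})

test_that("summarize_trends reports per-draw compound pairs", {
  # degenerate one-draw posterior: summaries equal that draw's values
  one <- tibble::tibble(region = "composite", year = rep(2000:2004, 1),
                        draw = 1, index = exp(0.1 * (0:4)), component = "smooth")
  tr <- summarize_trends(one, list(c(2000, 2004)), level = 0.9)
  expect_equal(tr$annual_rate, 100 * (exp(0.1) - 1), tolerance = 1e-10)
  expect_equal(tr$annual_rate, tr$annual_rate_lower)
  expect_equal(tr$net_change, 100 * (exp(0.4) - 1), tolerance = 1e-10)

  # multi-draw: medians of rate and change need not satisfy the compound
  # identity, but each draw pair does
  withr::local_seed(11)
  idx <- tibble::tibble(
    region = "composite",
    year = rep(c(2000, 2010), each = 40), draw = rep(1:40, 2),
    index = exp(rnorm(80)), component = "smooth"
  )
  tr2 <- summarize_trends(idx, list(c(2000, 2010)), level = 0.9)
  rate_draws <- endpoint_trend(idx, 2000, 2010)
  expect_equal(tr2$net_change,
               median(trend_to_percent_change(rate_draws, 2000, 2010)),
               tolerance = 1e-10)
  # identity on medians would generally fail:
  expect_false(isTRUE(all.equal(
    tr2$net_change, trend_to_percent_change(tr2$annual_rate, 2000, 2010),
    tolerance = 1e-12
  )))
})
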