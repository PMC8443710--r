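test_that("gamye_log_mean composes the model terms exactly", {
  years <- 2000:2009
  basis <- build_year_basis(years, n_knots = 4)
  rec <- list(stratum_id = "A", year = 2003L, observer_id = "o1",
              route_id = "r1", first_year = FALSE, day_of_year = 160L)
  zero_draw <- list(
    mu = c(A = 0), beta = matrix(0, 1, 4, dimnames = list("A", NULL)),
    gamma = matrix(0, 1, 10, dimnames = list("A", as.character(years))),
    omega = c(`o1|r1` = 0), eta = 0
  )
  expect_equal(gamye_log_mean(rec, zero_draw, basis), 0)

  # flipping first_year changes the value by exactly eta
  draw <- zero_draw
  draw$eta <- -0.25
  rec_fy <- rec
  rec_fy$first_year <- TRUE
  expect_equal(gamye_log_mean(rec_fy, draw, basis) -
                 gamye_log_mean(rec, draw, basis), -0.25)

  # hand-built toy draw: mu + beta . (x - colmeans) + gamma + omega
  draw2 <- list(
    mu = c(A = 1.5),
    beta = matrix(c(0.2, -0.1, 0.4, 0.3), 1, 4, dimnames = list("A", NULL)),
    gamma = matrix(seq(0.01, 0.10, by = 0.01), 1, 10,
                   dimnames = list("A", as.character(years))),
    omega = c(`o1|r1` = -0.3), eta = 0.1
  )
  xc <- evaluate_basis(basis, 2003)[1, ] - colMeans(basis$matrix)
  by_hand <- 1.5 + sum(draw2$beta[1, ] * xc) + 0.04 - 0.3
  expect_equal(gamye_log_mean(rec, draw2, basis), by_hand, tolerance = 1e-12)

  expect_error(gamye_log_mean(list(stratum_id = "Z", year = 2003,
                                   observer_id = "o1", route_id = "r1",
                                   first_year = FALSE),
                              draw2, basis), "unknown stratum")
  rec_bad_obs <- rec
  rec_bad_obs$observer_id <- "nobody"
  expect_error(gamye_log_mean(rec_bad_obs, draw2, basis), "unknown observer")
})

test_that("split R-hat and ESS behave on constructed chains", {
  withr::local_seed(42)
  n <- 500
  # well-mixed: iid draws in both chains
  good <- matrix(rnorm(2 * n), ncol = 1)
  chain <- rep(1:2, each = n)
  d_good <- check_convergence(good, chain = chain)
  expect_true(attr(d_good, "pass"))
  expect_lt(d_good$rhat, 1.05)
  expect_gt(d_good$ess, 0.5 * 2 * n)

  # adversarial: one chain offset by 3 sd -> fail
  bad <- matrix(c(rnorm(n), rnorm(n, mean = 3)), ncol = 1)
  d_bad <- check_convergence(bad, chain = chain)
  expect_false(attr(d_bad, "pass"))
  expect_gt(d_bad$rhat, 1.5)

  # within-chain drift is caught by the split (plain two-chain R-hat misses it)
  drift <- matrix(c(seq(-3, 3, length.out = n), seq(-3, 3, length.out = n)),
                  ncol = 1)
  d_drift <- check_convergence(drift, chain = chain)
  expect_gt(d_drift$rhat, 1.5)

  # identical constant chains: R-hat undefined, flagged degenerate, not passed
  const <- matrix(rep(1, 2 * n), ncol = 1)
  d_const <- check_convergence(const, chain = chain)
  expect_true(d_const$degenerate)
  expect_false(attr(d_const, "pass"))

  expect_error(check_convergence(good, chain = rep(1, 2 * n)),
               "at least 2 chains")
})

test_that("split R-hat matches a direct evaluation of the formula", {
  withr::local_seed(7)
  x <- c(rnorm(100), rnorm(100, 0.5))
  chain <- rep(1:2, each = 100)
  got <- check_convergence(matrix(x, ncol = 1), chain = chain)$rhat
  # direct: 4 half-chains of length 50
  halves <- list(x[1:50], x[51:100], x[101:150], x[151:200])
  n <- 50
  W <- mean(sapply(halves, var))
  B <- n * var(sapply(halves, mean))
  expect_equal(got, sqrt(((n - 1) / n * W + B / n) / W), tolerance = 1e-12)
})

test_that("a small fit returns structured draws with valid dimensions", {
  fit <- small_fit()
  n_draw <- length(fit$chain)
  expect_equal(n_draw, 600)
  expect_equal(dim(fit$draws$beta),
               c(n_draw, length(fit$strata_levels), ncol(fit$year_basis$matrix)))
  expect_equal(dim(fit$draws$gamma),
               c(n_draw, length(fit$strata_levels), length(fit$years)))
  expect_true(all(fit$draws$sd_obs > 0))
  expect_true(all(fit$draws$sd_noise > 0))
  expect_true(all(fit$draws$sd_gamma > 0))
  # every stratum smooth coefficient vector is orthogonal to the constant
  # (the identifiable parameterization)
  sums <- apply(fit$draws$beta, c(1, 2), sum)
  expect_lt(max(abs(sums)), 1e-8)
  expect_s3_class(glance(fit), "tbl_df")
  expect_equal(glance(fit)$draws, 600)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high") %in% names(td)))
})

test_that("reproducibility: same seed gives identical draws", {
  sim <- small_sim(seed = 31)
  fl <- apply_inclusion_filters(sim$dataset)
  mc <- mcmc_options(chains = 2, warmup = 150, samples = 50, seed = 77)
  f1 <- suppressWarnings(fit_gamye(fl$dataset, gamye_spec(), mc))
  f2 <- suppressWarnings(fit_gamye(fl$dataset, gamye_spec(), mc))
  expect_identical(f1$draws$mu, f2$draws$mu)
  expect_identical(f1$draws$beta, f2$draws$beta)
})

test_that("a single observer everywhere drives sd_obs toward zero", {
  sim <- small_sim(seed = 13, observer_sd = 0, observer_turnover_prob = 0)
  ds <- sim$dataset
  ds$records$observer_id <- "only_one"
  ds$records$first_year <- FALSE
  fl <- apply_inclusion_filters(ds)
  fit <- suppressWarnings(fit_gamye(
    fl$dataset, gamye_spec(observer_unit = "observer"),
    mcmc_options(chains = 2, warmup = 300, samples = 200, seed = 3)
  ))
  # with one observer the effect is unidentified from the intercept and the
  # half-Normal shrinkage keeps its sd near the prior's lower range
  expect_lt(median(fit$draws$sd_obs), 0.5)
})

test_that("degenerate datasets are rejected with clear errors", {
  sim <- small_sim(seed = 41)
  ds <- sim$dataset
  ds$records$count <- 0L
  expect_error(apply_inclusion_filters(ds), "no modelable strata")
  ds2 <- sim$dataset
  ds2$records <- ds2$records[0, ]
  expect_error(fit_gamye(ds2, gamye_spec(), mcmc_options()), "no records")
  expect_error(mcmc_options(chains = 1), "chains")
  expect_error(gamye_spec(prior_scales = list(nonsense = 1)), "unknown prior")
  expect_error(phenology_spec(walk_order = 2), "walk_order")
})
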