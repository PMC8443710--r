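#' Convergence diagnostics: split R-hat and effective sample size
#'
#' Computes the split-chain potential scale reduction factor (each chain is
#' halved, so within-chain drift also inflates R-hat) and an effective sample
#' size based on chain-averaged autocorrelations with Geyer initial-monotone
#' truncation, for every monitored scalar parameter. A fit passes when the
#' maximum finite split-R-hat is at most 1.05. Parameters with zero posterior
#' variance (e.g. constant chains) have undefined R-hat and are flagged
#' `degenerate` rather than passed.
#'
#' @param fit A `gamye_fit`, or a numeric matrix of draws (rows = iterations,
#'   stacked by chain) accompanied by `chain`.
#' @param chain Integer vector assigning each row to a chain (only when `fit`
#'   is a matrix).
#' @return A tibble with columns `parameter`, `mean`, `sd`, `rhat`, `ess`,
#'   `degenerate`; attributes `pass` (logical), `max_rhat`, `min_ess`.
#' @export
check_convergence <- function(fit, chain = NULL) {
  if (inherits(fit, "gamye_fit")) {
    mat <- draws_matrix(fit)
    chain <- fit$chain
  } else {
    mat <- as.matrix(fit)
    if (is.null(chain)) stop("chain vector required for matrix input", call. = FALSE)
  }
  if (length(unique(chain)) < 2) {
    stop("convergence diagnostics need at least 2 chains", call. = FALSE)
  }
  res <- purrr::map_dfr(seq_len(ncol(mat)), function(j) {
    x <- split(mat[, j], chain)
    tibble::tibble(
      parameter = colnames(mat)[j],
      mean = mean(mat[, j]),
      sd = sd(mat[, j]),
      rhat = split_rhat(x),
      ess = ess_mean(x)
    )
  })
  res$degenerate <- !is.finite(res$rhat)
  pass <- all(!res$degenerate) && max(res$rhat) <= 1.05
  attr(res, "pass") <- pass
  attr(res, "max_rhat") <- suppressWarnings(max(res$rhat[is.finite(res$rhat)], -Inf))
  attr(res, "min_ess") <- suppressWarnings(min(res$ess[is.finite(res$ess)], Inf))
  res
}

# flatten the structured draw arrays into a named matrix (one column per scalar)
draws_matrix <- function(fit) {
  pieces <- purrr::imap(fit$draws, function(a, name) {
    if (is.null(dim(a))) {
      m <- matrix(a, ncol = 1, dimnames = list(NULL, name))
    } else {
      dims <- dim(a)[-1]
      idx <- expand.grid(lapply(dims, seq_len))
      m <- matrix(a, nrow = dim(a)[1])
      colnames(m) <- paste0(name, "[", do.call(paste, c(idx, sep = ",")), "]")
    }
    m
  })
  do.call(cbind, pieces)
}

# split each chain in half; classic potential scale reduction on the halves
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2
    if (n < 2) return(list(x))
    list(x[seq_len(n)], x[(length(x) - n + 1):length(x)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(x) x[seq_len(n)])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

# effective sample size for the mean, chain-averaged autocorrelations,
# truncated where successive paired sums turn negative (Geyer)
ess_mean <- function(chains) {
  n <- min(lengths(chains))
  chains <- lapply(chains, function(x) x[seq_len(n)])
  m <- length(chains)
  vars <- vapply(chains, var, numeric(1))
  W <- mean(vars)
  means <- vapply(chains, mean, numeric(1))
  B <- n * var(means)
  var_plus <- (n - 1) / n * W + B / n
  if (!is.finite(var_plus) || var_plus <= 0) return(NA_real_)
  max_lag <- min(n - 1, 200)
  rho <- numeric(max_lag)
  for (t in seq_len(max_lag)) {
    acov_t <- mean(vapply(chains, function(x) {
      mean((x[seq_len(n - t)] - mean(x)) * (x[(t + 1):n] - mean(x)))
    }, numeric(1)))
    rho[t] <- 1 - (W - acov_t) / var_plus
  }
  # sum paired autocorrelations until a pair goes negative
  tau <- 1
  t <- 1
  while (t + 1 <= max_lag) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  max(m * n / tau, 1)
}
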