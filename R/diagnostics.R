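#' Split-Rhat convergence diagnostic
#'
#' Potential scale reduction computed on chains split in half, so
#' within-chain drift is detected even for a single chain.
#'
#' @param x Numeric vector of draws (all chains stacked).
#' @param chain Integer chain id per draw.
#' @return Rhat (>= 1; `NA` if the draws are constant).
#' @export
split_rhat <- function(x, chain) {
  splits <- .split_chains(x, chain)
  m <- length(splits)
  n <- min(lengths(splits))
  splits <- lapply(splits, function(s) s[seq_len(n)])
  means <- vapply(splits, mean, 0)
  vars <- vapply(splits, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS combining split chains (Geyer initial
#' monotone positive-pair truncation).
#'
#' @inheritParams split_rhat
#' @return Estimated effective sample size.
#' @export
ess_draws <- function(x, chain) {
  splits <- .split_chains(x, chain)
  m <- length(splits)
  n <- min(lengths(splits))
  splits <- lapply(splits, function(s) s[seq_len(n)])
  vars <- vapply(splits, stats::var, 0)
  means <- vapply(splits, mean, 0)
  W <- mean(vars)
  var_plus <- (n - 1) / n * W + stats::var(means)
  if (W == 0 || !is.finite(var_plus) || var_plus == 0) return(NA_real_)
  max_lag <- n - 2L
  acov <- sapply(splits, function(s) {
    a <- stats::acf(s, lag.max = max_lag, plot = FALSE,
                    demean = TRUE, type = "covariance")$acf[, 1, 1]
    a
  })
  rho <- 1 - (W - rowMeans(acov)[-1]) / var_plus
  # Geyer: sum of adjacent pairs must stay positive and non-increasing
  tau <- 1
  prev_pair <- Inf
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    prev_pair <- pair
    tau <- tau + 2 * pair
    t <- t + 2
  }
  m * n / tau
}

.split_chains <- function(x, chain) {
  out <- list()
  for (id in unique(chain)) {
    s <- x[chain == id]
    h <- length(s) %/% 2L
    out <- c(out, list(s[seq_len(h)], s[(h + 1L):(2L * h)]))
  }
  out
}
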