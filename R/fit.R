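#' MCMC settings
#'
#' Defaults follow the analysis protocol: 4 chains of 6000 iterations with
#' 3000 warmup and thinning 10, retaining 1200 draws in total.
#'
#' @param chains Number of chains.
#' @param iterations Total iterations per chain (including warmup).
#' @param warmup Warmup iterations discarded per chain.
#' @param thin Thinning interval applied after warmup.
#' @param seed Integer RNG seed.
#' @return `mcmc_settings` list.
#' @export
mcmc_settings <- function(chains = 4, iterations = 6000, warmup = 3000,
                          thin = 10, seed = 1) {
  stopifnot(chains >= 1, iterations > warmup, warmup >= 0, thin >= 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' Fit a Gaussian hierarchical model by blocked Gibbs sampling
#'
#' Samples the posterior of fixed effects, variance components and
#' random-effect levels for `y = X b + sum_k Z_k u_k + e` with
#' `u_k ~ N(0, sigma2_k K_k)`. Priors: `b ~ N(0, (10 sd(y))^2)`,
#' half-Student-t(3, 0, 2.5 sd(y)) on every standard deviation (random
#' effects and residual), implemented with inverse-gamma scale-mixture
#' auxiliaries so all variance updates stay conjugate; an ancillary
#' log-scale Metropolis rescaling of each `(sigma_k, u_k)` block keeps
#' mixing healthy when a component is near zero. Split-Rhat and effective
#' sample sizes are attached for every fixed effect and variance component.
#'
#' @param data Data frame.
#' @param spec A [model_spec()].
#' @param settings An [mcmc_settings()].
#' @param prior Optional overrides: list with any of `beta_sd`, `sd_scale`,
#'   `resid_scale`, `nu`.
#' @return A `ds_fit` object: posterior draws (`$draws$beta`,
#'   `$draws$sigma2`, `$draws$u`), chain ids, `$diagnostics`
#'   (rhat/ess per parameter), `$converged`, the design and settings.
#' @export
fit_hmm <- function(data, spec, settings = mcmc_settings(), prior = list()) {
  design <- build_design(data, spec)
  fit_hmm_design(design, settings, prior)
}

#' @rdname fit_hmm
#' @param design A prebuilt `ds_design` (see [build_design()]); useful when
#'   refitting the same structure many times.
#' @export
fit_hmm_design <- function(design, settings = mcmc_settings(),
                           prior = list()) {
  stopifnot(inherits(design, "ds_design"), inherits(settings, "mcmc_settings"))
  y <- design$y
  sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1
  beta_sd <- prior$beta_sd %||% (10 * sdy)
  sd_scale <- prior$sd_scale %||% (2.5 * sdy)
  resid_scale <- prior$resid_scale %||% (2.5 * sdy)
  nu <- prior$nu %||% 3

  K <- length(design$re)
  re_index <- lapply(design$re, `[[`, "index")
  re_kinv <- lapply(design$re, function(re) {
    if (is.null(re$K)) NULL else .stable_inverse(re$K)
  })

  n_keep <- (settings$iterations - settings$warmup) %/% settings$thin
  set.seed(settings$seed)
  # chain-dispersed variance inits around the phenotypic variance
  disp <- exp(seq(-1.5, 1.5, length.out = max(settings$chains, 2)))
  chains <- vector("list", settings$chains)
  for (ch in seq_len(settings$chains)) {
    init <- rep(sdy^2 * disp[ch] / (K + 1), K + 1)
    chains[[ch]] <- .gibbs_lmm_cpp(y, design$X, re_index, re_kinv,
                                   settings$iterations, settings$warmup,
                                   settings$thin, beta_sd^2, nu,
                                   sd_scale, resid_scale, init, 0.5)
  }

  p <- ncol(design$X)
  beta <- do.call(rbind, lapply(chains, `[[`, "beta"))
  colnames(beta) <- colnames(design$X)
  sigma2 <- do.call(rbind, lapply(chains, `[[`, "sigma2"))
  re_names <- vapply(design$re, `[[`, "", "name")
  colnames(sigma2) <- c(re_names, "residual")
  u <- lapply(seq_len(K), function(k) {
    m <- do.call(rbind, lapply(chains, function(c) c$u[[k]]))
    colnames(m) <- design$re[[k]]$levels
    m
  })
  names(u) <- re_names
  chain_id <- rep(seq_len(settings$chains), each = n_keep)

  mon <- cbind(beta, sigma2)
  diag_tab <- data.frame(
    parameter = colnames(mon),
    rhat = apply(mon, 2, function(x) split_rhat(x, chain_id)),
    ess = apply(mon, 2, function(x) ess_draws(x, chain_id)),
    row.names = NULL
  )
  converged <- all(diag_tab$rhat < 1.01, na.rm = TRUE) &&
    all(diag_tab$ess > 400, na.rm = TRUE)
  if (!converged)
    warning("fit flagged as non-converged (Rhat >= 1.01 or ESS <= 400)")

  structure(list(draws = list(beta = beta, sigma2 = sigma2, u = u),
                 chain = chain_id, design = design, settings = settings,
                 diagnostics = diag_tab, converged = converged,
                 accept = lapply(chains, `[[`, "accept")),
            class = "ds_fit")
}

# Inverse via symmetric eigendecomposition with an eigenvalue floor, so
# PSD-projected similarity matrices (smallest eigenvalues ~1e-8) stay usable
# as random-effect covariances.
.stable_inverse <- function(K, floor = 1e-6) {
  e <- eigen(K, symmetric = TRUE)
  v <- pmax(e$values, floor * max(e$values))
  M <- e$vectors %*% ((1 / v) * t(e$vectors))
  (M + t(M)) / 2
}

#' @export
print.ds_fit <- function(x, ...) {
  cat(sprintf("Gaussian hierarchical fit: %d obs, %d fixed, %d random terms\n",
              x$design$n, ncol(x$draws$beta), length(x$draws$u)))
  cat(sprintf("%d draws (%d chains); converged: %s\n",
              nrow(x$draws$beta), x$settings$chains, x$converged))
  cat("posterior medians of variance components:\n")
  print(round(apply(x$draws$sigma2, 2, stats::median), 5))
  invisible(x)
}

#' Refuse to proceed on a non-converged fit
#'
#' Convergence gate used by the summarising functions: any Rhat >= 1.01 or
#' ESS <= 400 blocks summarisation unless explicitly allowed.
#'
#' @param fit A `ds_fit`.
#' @param allow_unconverged Set TRUE to bypass (e.g. for diagnostics).
#' @export
check_convergence <- function(fit, allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "ds_fit"))
  if (!fit$converged && !allow_unconverged)
    stop("model has not converged (Rhat >= 1.01 or ESS <= 400); ",
         "inspect fit$diagnostics or pass allow_unconverged = TRUE")
  invisible(fit)
}

#' Per-draw linear predictors
#'
#' @param fit A `ds_fit`.
#' @param fixed_only Only the fixed-effect (population-level) predictor.
#' @param zero_groups Optional character vector of fixed-effect partition
#'   tags whose coefficients are zeroed (used by [partition_fixed()]).
#' @return Matrix draws x observations.
#' @export
linear_predictor <- function(fit, fixed_only = FALSE, zero_groups = NULL) {
  beta <- fit$draws$beta
  if (!is.null(zero_groups)) {
    drop <- fit$design$col_group %in% zero_groups
    beta[, drop] <- 0
  }
  eta <- beta %*% t(fit$design$X)
  if (!fixed_only) {
    for (k in seq_along(fit$draws$u)) {
      idx <- fit$design$re[[k]]$index
      eta <- eta + fit$draws$u[[k]][, idx, drop = FALSE]
    }
  }
  eta
}

#' Posterior individual trophic position (random intercept + intercept)
#'
#' For each requested individual, the posterior median of the population
#' intercept plus that individual's random intercept — the "modelled
#' trophic position" used as the maternal (or paternal) covariate
#' downstream. Levels present in the model but without observations shrink
#' to the population intercept.
#'
#' @param fit A `ds_fit` containing an i.i.d. individual-intercept term.
#' @param ids Individuals to extract; default all levels of `term`.
#' @param term Name of the individual random term (default "individual").
#' @return Named numeric vector of posterior medians.
#' @export
extract_individual_tp <- function(fit, ids = NULL, term = "individual") {
  stopifnot(inherits(fit, "ds_fit"))
  u <- fit$draws$u[[term]]
  if (is.null(u)) stop("no random term named '", term, "' in fit")
  if (is.null(ids)) ids <- colnames(u)
  unknown <- setdiff(ids, colnames(u))
  if (length(unknown))
    stop("unknown id(s): ", paste(unknown, collapse = ", "))
  vals <- fit$draws$beta[, "(Intercept)"] + u[, ids, drop = FALSE]
  stats::setNames(apply(vals, 2, stats::median), ids)
}

#' Pointwise Gaussian log-likelihood matrix
#'
#' log N(y_i | eta_i^(s), sigma2_R^(s)) for every draw s and observation i;
#' the input to PSIS-LOO.
#'
#' @param fit A `ds_fit`.
#' @return Matrix draws x observations.
#' @export
pointwise_loglik <- function(fit) {
  eta <- linear_predictor(fit)
  s2 <- fit$draws$sigma2[, "residual"]
  y <- fit$design$y
  if (ncol(eta) != length(y)) stop("dimension mismatch")
  -0.5 * log(2 * pi * s2) -
    0.5 * sweep(eta, 2, y)^2 / s2
}
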