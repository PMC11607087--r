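#' Equal-tail credible interval
#'
#' @param x Draws.
#' @param level Interval mass (default 0.89: the 5.5th to 94.5th
#'   percentile).
#' @return Numeric `c(low, high)`.
#' @export
eti <- function(x, level = 0.89) {
  a <- (1 - level) / 2
  stats::quantile(x, c(a, 1 - a), names = FALSE)
}

.summarise_component <- function(draws, level = 0.89) {
  ci <- apply(draws, 2, eti, level = level)
  data.frame(component = colnames(draws),
             median = apply(draws, 2, stats::median),
             mean = colMeans(draws),
             ci_low = ci[1, ], ci_high = ci[2, ],
             inconclusive = ci[1, ] < 0.001,
             row.names = NULL)
}

#' Posterior variance decomposition
#'
#' Per draw: the fixed-effect contribution is the variance of the
#' population-level (fixed-only) linear predictor across observations —
#' optionally partitioned into tagged groups by the semi-partial approach
#' of [partition_fixed()] — each random component contributes its sigma^2,
#' and the residual its sigma^2_R. Total phenotypic variance V_P is their
#' sum; proportions are component / V_P, summarised with 89% equal-tail
#' intervals. A component whose lower interval limit falls below 0.001
#' (0.1%) is flagged inconclusive.
#'
#' @param fit A converged `ds_fit`.
#' @param groups Optional named list tagging fixed-effect partition groups,
#'   e.g. `list(social_learning = "sl", age = "age")` where values are the
#'   `group` tags used in the [fe_term()] definitions. Untagged non-intercept
#'   columns form an `other_fixed` component.
#' @param allow_unconverged Bypass the convergence gate.
#' @param level Credible-interval mass.
#' @return `ds_decomp`: `$draws` (per-draw component variances incl. `V_P`),
#'   `$proportions` (per-draw proportions of `V_P`), `$summary`
#'   (median/mean/CI/inconclusive per proportion).
#' @export
decompose_variance <- function(fit, groups = NULL, allow_unconverged = FALSE,
                               level = 0.89) {
  check_convergence(fit, allow_unconverged)
  eta_fixed <- linear_predictor(fit, fixed_only = TRUE)
  v_fixed <- apply(eta_fixed, 1, stats::var)
  if (is.null(groups)) {
    fixed_draws <- matrix(v_fixed, ncol = 1,
                          dimnames = list(NULL, "V_fixed"))
  } else {
    fixed_draws <- partition_fixed(fit, groups, v_fixed = v_fixed)
  }
  s2 <- fit$draws$sigma2
  re_cols <- setdiff(colnames(s2), "residual")
  comp <- cbind(fixed_draws,
                s2[, re_cols, drop = FALSE],
                V_residual = s2[, "residual"])
  if (length(re_cols))
    colnames(comp)[seq_along(re_cols) + ncol(fixed_draws)] <-
      paste0("V_", re_cols)
  vp <- rowSums(comp)
  prop <- comp / vp
  structure(list(draws = cbind(comp, V_P = vp),
                 proportions = prop,
                 summary = .summarise_component(prop, level)),
            class = "ds_decomp")
}

#' @export
print.ds_decomp <- function(x, digits = 3, ...) {
  cat("posterior variance decomposition (proportions of V_P):\n")
  print(cbind(x$summary[1], round(x$summary[2:5], digits),
              x$summary[6]), row.names = FALSE)
  invisible(x)
}

#' Semi-partial partition of the fixed-effect variance
#'
#' Following the commonality-style partition of Stoffel et al.'s
#' repeatability framework adapted to a Bayesian setting: per draw, each
#' group's raw contribution is V_fixed(full predictor) minus V_fixed with
#' that group's coefficients zeroed; raw contributions are rescaled to sum
#' exactly to V_fixed so the groups are additive.
#'
#' @param fit A `ds_fit`.
#' @param groups Named list mapping output component names to the `group`
#'   tags of the fixed terms they pool, e.g.
#'   `list(V_SL = "sl", V_Age = "age")`.
#' @param v_fixed Optional precomputed per-draw fixed variance.
#' @return Matrix draws x groups of variance contributions (same scale as
#'   V_fixed, not proportions).
#' @export
partition_fixed <- function(fit, groups, v_fixed = NULL) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  tags <- fit$design$col_group
  for (g in names(groups))
    if (!any(tags %in% groups[[g]], na.rm = TRUE))
      stop("group '", g, "' covers no fixed-effect columns")
  leftover <- setdiff(stats::na.omit(unique(tags)), unlist(groups))
  if (length(leftover)) groups <- c(groups, list(other_fixed = leftover))
  if (is.null(v_fixed))
    v_fixed <- apply(linear_predictor(fit, fixed_only = TRUE), 1, stats::var)
  raw <- sapply(names(groups), function(g) {
    eta <- linear_predictor(fit, fixed_only = TRUE,
                            zero_groups = groups[[g]])
    v_fixed - apply(eta, 1, stats::var)
  })
  tot <- rowSums(raw)
  scale <- ifelse(abs(tot) > 1e-12, v_fixed / tot, NA_real_)
  out <- raw * scale
  # draws where nothing is attributable: split the (0) fixed variance evenly
  flat <- !is.finite(scale)
  if (any(flat)) out[flat, ] <- v_fixed[flat] / length(groups)
  colnames(out) <- names(groups)
  out
}

#' Repeatability (intraclass correlation) of the basic model
#'
#' Among-individual variance divided by total phenotypic variance,
#' per draw: `V_I / (V_Age + V_I + V_R)`. Both the variant including the
#' fixed-effect (age) variance in the denominator and the variant without
#' it are returned.
#'
#' @param fit `ds_fit` of the basic model (individual intercept, age
#'   polynomial, residual).
#' @param term Name of the individual random term.
#' @param allow_unconverged Bypass the convergence gate.
#' @return List with per-draw vectors `with_fixed`, `without_fixed` and a
#'   `summary` data frame (89% equal-tail intervals).
#' @export
repeatability <- function(fit, term = "individual",
                          allow_unconverged = FALSE) {
  check_convergence(fit, allow_unconverged)
  s2 <- fit$draws$sigma2
  if (!term %in% colnames(s2)) stop("no random term named '", term, "'")
  v_i <- s2[, term]
  v_r <- s2[, "residual"]
  v_fix <- apply(linear_predictor(fit, fixed_only = TRUE), 1, stats::var)
  with_fixed <- v_i / (v_fix + v_i + v_r)
  without_fixed <- v_i / (v_i + v_r)
  draws <- cbind(with_fixed = with_fixed, without_fixed = without_fixed)
  list(with_fixed = with_fixed, without_fixed = without_fixed,
       summary = .summarise_component(draws))
}

#' Nakagawa's marginal and conditional R2
#'
#' Marginal R2 = V_fixed / V_P; conditional R2 = (V_fixed + sum of random
#' components) / V_P, per draw, where V_P additionally includes the
#' residual variance.
#'
#' @param fit A `ds_fit`.
#' @param allow_unconverged Bypass the convergence gate.
#' @return List with per-draw vectors `marginal`, `conditional` and a
#'   `summary` data frame.
#' @export
nakagawa_r2 <- function(fit, allow_unconverged = FALSE) {
  check_convergence(fit, allow_unconverged)
  v_fix <- apply(linear_predictor(fit, fixed_only = TRUE), 1, stats::var)
  s2 <- fit$draws$sigma2
  re_cols <- setdiff(colnames(s2), "residual")
  v_rand <- if (length(re_cols))
    rowSums(s2[, re_cols, drop = FALSE]) else 0
  vp <- v_fix + v_rand + s2[, "residual"]
  draws <- cbind(marginal = v_fix / vp,
                 conditional = (v_fix + v_rand) / vp)
  list(marginal = draws[, 1], conditional = draws[, 2],
       summary = .summarise_component(draws))
}
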