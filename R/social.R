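#' Build a mother-offspring pair table
#'
#' Joins each offspring hair sample to its mother's (and optionally
#' father's) modelled trophic position.
#'
#' @param samples Isotope table with `trophic_position` (see
#'   [read_isotope_table()]).
#' @param maternal_tp Named vector of maternal trophic positions (names =
#'   mother ids), e.g. from [extract_individual_tp()].
#' @param paternal_tp Optional named vector for fathers.
#' @return Data frame: `offspring_id`, `offspring_tp`, `maternal_tp`,
#'   `paternal_tp` (`NA` when unknown), `years_since_separation`, `sex`.
#'   Samples whose mother has no entry in `maternal_tp` are dropped.
#' @export
build_pair_table <- function(samples, maternal_tp, paternal_tp = NULL) {
  stopifnot(!is.null(samples$trophic_position))
  keep <- samples$mother_id %in% names(maternal_tp)
  s <- samples[keep, , drop = FALSE]
  out <- data.frame(
    offspring_id = s$bear_id,
    offspring_tp = s$trophic_position,
    maternal_tp = unname(maternal_tp[s$mother_id]),
    paternal_tp = if (is.null(paternal_tp)) NA_real_ else
      unname(paternal_tp[match(s$father_id, names(paternal_tp))]),
    years_since_separation = s$years_since_separation,
    sex = s$sex,
    stringsAsFactors = FALSE
  )
  out
}

#' Windowed mother-offspring Pearson correlation
#'
#' Pearson correlation between offspring and maternal trophic position for
#' samples whose years-since-separation lie in a closed window, with
#' df = n - 2 and a two-sided p-value from the t transform. All samples in
#' the window enter as pairs (repeated measures included); set
#' `average_within_individual = TRUE` for the sensitivity variant that
#' first averages each offspring's samples.
#'
#' @param pairs Pair table (see [build_pair_table()]).
#' @param window `c(lo, hi)` in years since separation, closed; `hi` may be
#'   `Inf`.
#' @param average_within_individual Average repeated samples per offspring
#'   before correlating.
#' @return List: `r`, `df`, `p`, `n`, `window`.
#' @export
windowed_correlation <- function(pairs, window = c(1, 2),
                                 average_within_individual = FALSE) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  w <- pairs[!is.na(pairs$years_since_separation) &
               pairs$years_since_separation >= window[1] &
               pairs$years_since_separation <= window[2], , drop = FALSE]
  if (average_within_individual && nrow(w)) {
    w <- do.call(rbind, lapply(split(w, w$offspring_id), function(d) {
      d$offspring_tp[1] <- mean(d$offspring_tp)
      d[1, , drop = FALSE]
    }))
  }
  n <- nrow(w)
  if (n < 3L) stop("need >= 3 pairs in window [",
                   window[1], ", ", window[2], "]")
  if (stats::sd(w$offspring_tp) == 0 || stats::sd(w$maternal_tp) == 0)
    stop("zero variance in window")
  r <- stats::cor(w$offspring_tp, w$maternal_tp)
  df <- n - 2L
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * stats::pt(-abs(tval), df), n = n,
       window = window)
}

#' Correlation profile over successive separation windows
#'
#' @param pairs Pair table.
#' @param windows List of `c(lo, hi)` windows; defaults to years 1-2, 3-4
#'   and 5 onwards.
#' @return Data frame with one row per window.
#' @export
correlation_profile <- function(pairs,
                                windows = list(c(1, 2), c(3, 4),
                                               c(5, Inf))) {
  do.call(rbind, lapply(windows, function(w) {
    ct <- windowed_correlation(pairs, w)
    data.frame(window = paste0(w[1], "-", ifelse(is.finite(w[2]), w[2], "")),
               lo = w[1], hi = w[2], r = ct$r, df = ct$df, p = ct$p,
               n = ct$n)
  }))
}

#' Is the social-learning effect sex-specific?
#'
#' Fits three mixed models to offspring trophic position in the first two
#' years after separation — maternal TP x sex interaction, maternal TP +
#' sex, maternal TP only — each with an individual random intercept for
#' repeated measures, and compares them by PSIS-LOO. The simplest model
#' within 4 elpd of the best is chosen; its marginal R2 quantifies the
#' variance explained by maternal trophic position.
#'
#' @param pairs Pair table with both sexes present.
#' @param window Closed years-since-separation window (default years 1-2).
#' @param settings [mcmc_settings()].
#' @return List: `comparison` (elpd table), `chosen`, `marginal_r2`
#'   (posterior median for the chosen model), `pearson` (pooled
#'   correlation), `fits`.
#' @export
sex_model_comparison <- function(pairs, window = c(1, 2),
                                 settings = mcmc_settings()) {
  w <- pairs[!is.na(pairs$years_since_separation) &
               pairs$years_since_separation >= window[1] &
               pairs$years_since_separation <= window[2], , drop = FALSE]
  if (length(unique(w$sex)) < 2L)
    stop("both sexes must be present in the window")
  ind <- re_term("individual", "offspring_id")
  specs <- list(
    maternal_x_sex = model_spec("offspring_tp", fixed = list(
      fe_term("maternal_tp", group = "sl"),
      fe_factor("sex", group = "sex"),
      fe_slope_by_factor("maternal_tp", "sex", group = "sex")),
      random = list(ind)),
    maternal_plus_sex = model_spec("offspring_tp", fixed = list(
      fe_term("maternal_tp", group = "sl"),
      fe_factor("sex", group = "sex")),
      random = list(ind)),
    maternal_only = model_spec("offspring_tp", fixed = list(
      fe_term("maternal_tp", group = "sl")),
      random = list(ind))
  )
  fits <- lapply(specs, function(sp) fit_hmm(w, sp, settings))
  loos <- lapply(fits, function(f) loo_elpd(pointwise_loglik(f)))
  tab <- compare_loo(loos)
  # prefer the simplest model within 4 elpd of the best
  simplicity <- c(maternal_only = 1, maternal_plus_sex = 2,
                  maternal_x_sex = 3)
  adequate <- tab$model[tab$elpd_diff > -4]
  chosen <- adequate[which.min(simplicity[adequate])]
  r2 <- nakagawa_r2(fits[[chosen]], allow_unconverged = TRUE)
  list(comparison = tab, chosen = chosen,
       marginal_r2 = stats::median(r2$marginal),
       pearson = windowed_correlation(w, window),
       fits = fits)
}

#' Paternal effect on offspring trophic position
#'
#' Mixed model of offspring TP in the first two years after separation on
#' the father's modelled trophic position (individual random intercept),
#' compared by PSIS-LOO to an intercept-only model, with the pooled
#' Pearson correlation.
#'
#' @param pairs Pair table with `paternal_tp` for known fathers.
#' @param window Closed years-since-separation window.
#' @param settings [mcmc_settings()].
#' @return List: `explained_variance` (posterior median marginal R2), `r`,
#'   `df`, `p`, `comparison` (loo table vs the null model), `n`,
#'   `n_fathers`.
#' @export
paternal_effect <- function(pairs, window = c(1, 2),
                            settings = mcmc_settings()) {
  w <- pairs[!is.na(pairs$paternal_tp) &
               !is.na(pairs$years_since_separation) &
               pairs$years_since_separation >= window[1] &
               pairs$years_since_separation <= window[2], , drop = FALSE]
  if (nrow(w) < 3L) stop("need >= 3 offspring with known fathers")
  n_fathers <- length(unique(w$paternal_tp))
  if (n_fathers < 3L)
    stop("need >= 3 distinct fathers")
  if (stats::sd(w$paternal_tp) == 0) stop("zero variance in paternal TP")
  ind <- re_term("individual", "offspring_id")
  fit_pat <- fit_hmm(w, model_spec("offspring_tp",
                                   fixed = list(fe_term("paternal_tp")),
                                   random = list(ind)), settings)
  fit_null <- fit_hmm(w, model_spec("offspring_tp", random = list(ind)),
                      settings)
  tab <- compare_loo(list(paternal = loo_elpd(pointwise_loglik(fit_pat)),
                          null = loo_elpd(pointwise_loglik(fit_null))))
  r2 <- nakagawa_r2(fit_pat, allow_unconverged = TRUE)
  ct <- {
    r <- stats::cor(w$offspring_tp, w$paternal_tp)
    df <- nrow(w) - 2L
    tv <- r * sqrt(df / (1 - r^2))
    list(r = r, df = df, p = 2 * stats::pt(-abs(tv), df))
  }
  list(explained_variance = stats::median(r2$marginal),
       r = ct$r, df = ct$df, p = ct$p, comparison = tab,
       n = nrow(w), n_fathers = n_fathers)
}
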