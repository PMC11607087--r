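#' Summarise a baseline consumer's d15N samples
#'
#' Computes the arithmetic mean and sample standard deviation (n - 1
#' denominator) of delta-15-N values measured on a strict-herbivore baseline
#' (here: moose hair), against which consumer trophic positions are expressed.
#'
#' @param d15n Numeric vector of baseline d15N values (per mil vs AIR).
#' @return An object of class `baseline_stats`: a list with elements
#'   `mean_d15n`, `sd_d15n` (`NA` when n = 1) and `n`.
#' @examples
#' baseline_summary(c(1.0, 3.0))
#' @export
baseline_summary <- function(d15n) {
  if (length(d15n) == 0L) stop("no baseline samples")
  if (!is.numeric(d15n) || !all(is.finite(d15n)))
    stop("baseline d15N values must be finite numbers")
  out <- list(
    mean_d15n = mean(d15n),
    sd_d15n = if (length(d15n) > 1L) stats::sd(d15n) else NA_real_,
    n = length(d15n)
  )
  class(out) <- "baseline_stats"
  out
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat(sprintf("baseline d15N: mean %.3f, sd %s, n = %d\n",
              x$mean_d15n,
              if (is.na(x$sd_d15n)) "NA" else sprintf("%.3f", x$sd_d15n),
              x$n))
  invisible(x)
}

#' Trophic-position configuration
#'
#' @param tef Trophic enrichment factor: per-mil increase of d15N per trophic
#'   level. Default 3.4.
#' @param lambda Trophic position of the baseline consumer (2 = strict
#'   herbivore). Default 2.
#' @return A list of class `trophic_config`.
#' @export
trophic_config <- function(tef = 3.4, lambda = 2) {
  stopifnot(is.numeric(tef), length(tef) == 1L, is.finite(tef), tef > 0,
            is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            lambda >= 1)
  structure(list(tef = tef, lambda = lambda), class = "trophic_config")
}

#' Convert d15N to trophic position
#'
#' TP = (d15N_consumer - mean d15N_baseline) / TEF + lambda. A consumer with
#' the baseline's mean signature sits exactly at `lambda`; each TEF of
#' enrichment adds one trophic level. No range constraint is applied.
#'
#' @param d15n Numeric vector of consumer d15N values (per mil).
#' @param baseline A `baseline_stats` object (see [baseline_summary()]).
#' @param config A `trophic_config` object.
#' @return Numeric vector of trophic positions (dimensionless).
#' @examples
#' b <- baseline_summary(c(1.0, 2.6))  # mean 1.8
#' trophic_position(5.2, b)            # one TEF above baseline -> 3
#' @export
trophic_position <- function(d15n, baseline, config = trophic_config()) {
  if (!inherits(baseline, "baseline_stats"))
    stop("`baseline` must come from baseline_summary()")
  if (!inherits(config, "trophic_config")) stop("invalid trophic config")
  if (!is.numeric(d15n) || !all(is.finite(d15n)))
    stop("d15N values must be finite")
  (d15n - baseline$mean_d15n) / config$tef + config$lambda
}

.isotope_required_cols <- c("bear_id", "year", "d15n", "age",
                            "years_since_separation", "mother_id",
                            "father_id", "sex")

#' Read and validate an isotope-sample table
#'
#' One row per hair sample: an annual diet record with covariates. Validation
#' enforces finite d15N, age >= 1, `age >= years_since_separation` when both
#' present, sex in \{female, male\} and uniqueness of (bear_id, year). Rows
#' failing a check are reported with their line numbers.
#'
#' @param path CSV file (comma-delimited, header). Required columns:
#'   `bear_id, year, d15n, age, years_since_separation, mother_id, father_id,
#'   sex`. Empty `father_id` means unknown; empty `years_since_separation`
#'   marks a dependent offspring sample.
#' @param baseline Optional `baseline_stats`; when given, a
#'   `trophic_position` column is appended at ingest.
#' @param config `trophic_config` used when `baseline` is supplied.
#' @return A `data.frame` of validated samples.
#' @export
read_isotope_table <- function(path, baseline = NULL,
                               config = trophic_config()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_isotope_table(df)
  if (!is.null(baseline))
    df$trophic_position <- trophic_position(df$d15n, baseline, config)
  df
}

#' Validate an in-memory isotope-sample table
#'
#' @param df Data frame with the columns documented in
#'   [read_isotope_table()].
#' @return `df`, invisibly, if valid; otherwise an error naming offending
#'   rows.
#' @export
validate_isotope_table <- function(df) {
  missing_cols <- setdiff(.isotope_required_cols, names(df))
  if (length(missing_cols))
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  bad <- function(idx, what) {
    if (any(idx))
      stop(sprintf("%s in row(s): %s", what,
                   paste(which(idx), collapse = ", ")))
  }
  bad(!is.finite(df$d15n), "non-finite d15n")
  bad(!is.finite(df$age) | df$age < 1, "age must be >= 1")
  tss <- df$years_since_separation
  have_tss <- !is.na(tss)
  bad(have_tss & tss < 1, "years_since_separation must be >= 1 when present")
  bad(have_tss & df$age < tss, "age < years_since_separation")
  bad(!(df$sex %in% c("female", "male")), "sex must be 'female' or 'male'")
  key <- paste(df$bear_id, df$year, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup & duplicated(key)))
    stop("duplicate (bear_id, year) pair(s) in row(s): ",
         paste(which(duplicated(key)), collapse = ", "))
  invisible(df)
}

#' Write an isotope table augmented with trophic positions
#'
#' @param df Validated isotope table.
#' @param path Output CSV path.
#' @param baseline `baseline_stats`; used to (re)compute the
#'   `trophic_position` column if absent.
#' @param config `trophic_config`.
#' @export
write_isotope_table <- function(df, path, baseline = NULL,
                                config = trophic_config()) {
  if (is.null(df$trophic_position)) {
    if (is.null(baseline)) stop("need a baseline to compute trophic_position")
    df$trophic_position <- trophic_position(df$d15n, baseline, config)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
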