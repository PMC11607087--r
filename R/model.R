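#' Fixed-effect term
#'
#' Continuous covariates are centred and divided by their standard
#' deviation before entering the design; `poly = 2` adds the square of the
#' scaled covariate as a second column.
#'
#' @param var Column name in the data.
#' @param poly 1 (linear) or 2 (adds quadratic of the scaled covariate).
#' @param scale Centre/scale by SD (default TRUE).
#' @param group Optional tag used by [partition_fixed()] to pool terms
#'   (e.g. "age", "social_learning").
#' @return A `fe_term` description.
#' @export
fe_term <- function(var, poly = 1, scale = TRUE, group = NULL) {
  stopifnot(poly %in% 1:2)
  structure(list(var = var, poly = poly, scale = scale, group = group,
                 type = "main"), class = "fe_term")
}

#' Interaction of two (scaled) covariates
#'
#' The column is the elementwise product of the two scaled parent
#' covariates (each centred/scaled with its own mean and SD).
#'
#' @param var1,var2 Covariate column names.
#' @param square_second Use the square of the second scaled covariate
#'   (quadratic interaction).
#' @inheritParams fe_term
#' @export
fe_interaction <- function(var1, var2, scale = TRUE, group = NULL,
                           square_second = FALSE) {
  structure(list(var = c(var1, var2), scale = scale, group = group,
                 square_second = square_second,
                 type = "interaction"), class = "fe_term")
}

#' Categorical fixed effect (treatment contrasts)
#'
#' @param var Column name (character/factor).
#' @inheritParams fe_term
#' @export
fe_factor <- function(var, group = NULL) {
  structure(list(var = var, group = group, type = "factor"),
            class = "fe_term")
}

#' Interaction of a scaled covariate with a two-level factor
#'
#' @param var Continuous covariate name.
#' @param factor_var Factor column name.
#' @inheritParams fe_term
#' @export
fe_slope_by_factor <- function(var, factor_var, group = NULL) {
  structure(list(var = c(var, factor_var), group = group,
                 type = "slope_by_factor"), class = "fe_term")
}

#' Random-effect term
#'
#' `u ~ N(0, sigma^2 K)` with `K` the supplied covariance (identity if
#' `cov = NULL`, i.e. an i.i.d. intercept per level of `group_var`).
#'
#' @param name Term label (must be unique within a model).
#' @param group_var Grouping column in the data.
#' @param cov Optional covariance/similarity/relationship matrix whose
#'   dimnames cover all levels of `group_var`. Must be positive
#'   semi-definite (project with [nearest_psd()] first if needed).
#' @export
re_term <- function(name, group_var, cov = NULL) {
  structure(list(name = name, group_var = group_var, cov = cov),
            class = "re_term")
}

#' Gaussian hierarchical model specification
#'
#' @param response Response column name.
#' @param fixed List of [fe_term()] / [fe_interaction()] /
#'   [fe_factor()] / [fe_slope_by_factor()] objects. An intercept is always
#'   included.
#' @param random List of [re_term()] objects.
#' @return A `model_spec`.
#' @export
model_spec <- function(response, fixed = list(), random = list()) {
  stopifnot(is.character(response), length(response) == 1L)
  if (length(random)) {
    nms <- vapply(random, `[[`, "", "name")
    if (anyDuplicated(nms))
      stop("duplicated random-term names: ",
           paste(nms[duplicated(nms)], collapse = ", "))
  }
  structure(list(response = response, fixed = fixed, random = random),
            class = "model_spec")
}

.scaled <- function(x, var) {
  if (!is.numeric(x)) stop("covariate ", var, " must be numeric")
  if (anyNA(x))
    stop("missing covariate ", var, " in row(s): ",
         paste(which(is.na(x)), collapse = ", "))
  s <- stats::sd(x)
  if (s == 0) stop("zero variance covariate: ", var)
  (x - mean(x)) / s
}

#' Build design matrices and grouping indices for a model
#'
#' @param data Data frame containing the response, covariates and grouping
#'   columns.
#' @param spec A [model_spec()].
#' @return A list of class `ds_design`: `y`; `X` (fixed design, intercept
#'   first); `col_group` (partition tag per column, `NA` for intercept);
#'   `re` — per random term: `name`, `levels`, `index` (row to level), `K`
#'   (covariance or `NULL`).
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  y <- data[[spec$response]]
  if (is.null(y)) stop("response column not found: ", spec$response)
  if (anyNA(y) || !is.numeric(y)) stop("response must be complete numeric")
  n <- nrow(data)
  cols <- list(`(Intercept)` = rep(1, n))
  col_group <- c(NA_character_)
  for (tm in spec$fixed) {
    if (tm$type == "main") {
      x <- data[[tm$var]]
      if (is.null(x)) stop("covariate not found: ", tm$var)
      xs <- if (tm$scale) .scaled(x, tm$var) else x
      cols[[tm$var]] <- xs
      col_group <- c(col_group, tm$group %||% NA_character_)
      if (tm$poly == 2L) {
        cols[[paste0(tm$var, "_sq")]] <- xs^2
        col_group <- c(col_group, tm$group %||% NA_character_)
      }
    } else if (tm$type == "interaction") {
      x1 <- data[[tm$var[1]]]; x2 <- data[[tm$var[2]]]
      if (is.null(x1) || is.null(x2))
        stop("covariate not found: ", paste(tm$var, collapse = ", "))
      s1 <- if (tm$scale) .scaled(x1, tm$var[1]) else x1
      s2 <- if (tm$scale) .scaled(x2, tm$var[2]) else x2
      if (isTRUE(tm$square_second)) {
        cols[[paste0(tm$var[1], ":", tm$var[2], "_sq")]] <- s1 * s2^2
      } else {
        cols[[paste(tm$var, collapse = ":")]] <- s1 * s2
      }
      col_group <- c(col_group, tm$group %||% NA_character_)
    } else if (tm$type == "factor") {
      f <- factor(data[[tm$var]])
      if (anyNA(f)) stop("missing factor ", tm$var)
      for (lv in levels(f)[-1]) {
        cols[[paste0(tm$var, lv)]] <- as.numeric(f == lv)
        col_group <- c(col_group, tm$group %||% NA_character_)
      }
    } else if (tm$type == "slope_by_factor") {
      xs <- .scaled(data[[tm$var[1]]], tm$var[1])
      f <- factor(data[[tm$var[2]]])
      for (lv in levels(f)[-1]) {
        cols[[paste0(tm$var[1], ":", tm$var[2], lv)]] <-
          xs * as.numeric(f == lv)
        col_group <- c(col_group, tm$group %||% NA_character_)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  re <- lapply(spec$random, function(tm) {
    g <- as.character(data[[tm$group_var]])
    if (is.null(data[[tm$group_var]]) || anyNA(g))
      stop("grouping column missing or incomplete: ", tm$group_var)
    if (is.null(tm$cov)) {
      levels <- sort(unique(g))
      K <- NULL
    } else {
      K <- tm$cov
      levels <- rownames(K)
      if (is.null(levels)) stop("covariance for ", tm$name, " needs dimnames")
      miss <- setdiff(unique(g), levels)
      if (length(miss))
        stop("levels of ", tm$group_var, " missing from covariance of ",
             tm$name, ": ", paste(miss, collapse = ", "))
      ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8)
        stop("covariance for term '", tm$name,
             "' is not positive semi-definite; project with nearest_psd()")
    }
    list(name = tm$name, levels = levels, index = match(g, levels), K = K)
  })
  structure(list(y = y, X = X, col_group = col_group, re = re, n = n),
            class = "ds_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
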