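#' Simpson diversity index
#'
#' 1 - sum(p_i^2) over habitat class proportions.
#'
#' @param p Nonnegative class fractions summing to 1 (tolerance 1e-6).
#' @return Diversity in \[0, 1).
#' @export
simpson_diversity <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0))
    stop("proportions must be finite and nonnegative")
  if (abs(sum(p) - 1) > 1e-6) stop("proportions must sum to 1")
  1 - sum(p^2)
}

#' Validate a home-range feature table
#'
#' Columns: `bear_id`, `centroid_x_km`, `centroid_y_km`, `prop_mature`,
#' `prop_disturbed`, `simpson_diversity`.
#'
#' @param df Data frame of per-individual home-range features.
#' @return `df` invisibly.
#' @export
validate_home_ranges <- function(df) {
  need <- c("bear_id", "centroid_x_km", "centroid_y_km", "prop_mature",
            "prop_disturbed", "simpson_diversity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$bear_id)) stop("duplicated bear_id")
  if (any(!is.finite(df$centroid_x_km) | !is.finite(df$centroid_y_km)))
    stop("non-finite centroid coordinates")
  if (any(df$prop_mature < 0 | df$prop_disturbed < 0 |
          df$prop_mature + df$prop_disturbed > 1 + 1e-9))
    stop("prop_mature + prop_disturbed must lie in [0, 1]")
  invisible(df)
}

#' Read a home-range CSV
#' @param path CSV path with the columns of [validate_home_ranges()].
#' @export
read_home_ranges <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_home_ranges(df)
  df
}

.similarity_from_distance <- function(D, ids, kind, psd = TRUE) {
  mx <- max(D)
  if (mx <= 0) stop("all pairwise distances are zero")
  S <- 1 - D / mx
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  if (psd) S <- nearest_psd(S)
  attr(S, "kind") <- kind
  S
}

#' Environmental-similarity matrix from home-range habitat features
#'
#' Each of `prop_mature`, `prop_disturbed` and `simpson_diversity` is
#' centred and scaled to unit SD (equal weight per feature); pairwise
#' Euclidean distance in that 3-D space is mapped to similarity
#' 1 - d/max(d) (identical ranges -> 1, the most dissimilar pair -> 0) and
#' projected to the nearest positive semi-definite matrix so it can serve
#' as a random-effect covariance.
#'
#' @param features Home-range feature table (see [validate_home_ranges()]).
#' @param psd Project to PSD (default TRUE).
#' @return Symmetric similarity matrix with `bear_id` dimnames,
#'   `attr(,"kind") == "environment"`.
#' @export
env_similarity <- function(features, psd = TRUE) {
  validate_home_ranges(features)
  if (nrow(features) < 2L) stop("need >= 2 individuals")
  cols <- c("prop_mature", "prop_disturbed", "simpson_diversity")
  for (cl in cols)
    if (stats::sd(features[[cl]]) == 0)
      stop("zero-variance feature: ", cl)
  Z <- scale(as.matrix(features[cols]))
  D <- as.matrix(stats::dist(Z))
  .similarity_from_distance(D, features$bear_id, "environment", psd)
}

#' Spatial distance matrix and derived similarity
#'
#' Euclidean distances between home-range centroids (planar km), plus the
#' same 1 - d/max(d) similarity transform used for the environmental matrix
#' so the spatial model variant is structurally parallel.
#'
#' @param features Home-range feature table.
#' @param psd Project similarity to PSD.
#' @return List with `distance` (km matrix), `similarity`
#'   (`attr(,"kind") == "spatial"`), and `summary` (min/median/max of the
#'   pairwise distances).
#' @export
spatial_similarity <- function(features, psd = TRUE) {
  validate_home_ranges(features)
  if (nrow(features) < 2L) stop("need >= 2 individuals")
  xy <- as.matrix(features[c("centroid_x_km", "centroid_y_km")])
  D <- as.matrix(stats::dist(xy))
  dimnames(D) <- list(features$bear_id, features$bear_id)
  off <- D[lower.tri(D)]
  list(distance = D,
       similarity = .similarity_from_distance(D, features$bear_id,
                                              "spatial", psd),
       summary = c(min = min(off), median = stats::median(off),
                   max = max(off), n_pairs = length(off)))
}

#' Nearest positive semi-definite matrix with unit diagonal
#'
#' Eigenvalues below `eps` are clipped to `eps`, the matrix is
#' reconstructed, and the diagonal rescaled to 1 (correlation-like). A
#' matrix already PSD is returned unchanged (up to 1e-12).
#'
#' @param m Symmetric matrix.
#' @param eps Eigenvalue floor (default 1e-8).
#' @return PSD matrix, same dimnames.
#' @export
nearest_psd <- function(m, eps = 1e-8) {
  if (!isSymmetric(unname(m), tol = 1e-10)) stop("matrix must be symmetric")
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= eps) return(m)
  for (i in 1:5) {
    v <- pmax(e$values, eps)
    out <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(out))
    out <- out / tcrossprod(d)
    e <- eigen(out, symmetric = TRUE)
    if (min(e$values) >= -eps) break
  }
  dimnames(out) <- dimnames(m)
  out
}

#' Write / read a labelled square matrix as CSV
#'
#' @param m Matrix with id dimnames.
#' @param path CSV path (ids as header and first column).
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(id = "character"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  storage.mode(m) <- "double"
  m
}
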