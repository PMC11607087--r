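#' Persist posterior draws as a long-format CSV
#'
#' One row per (parameter, chain, draw): fixed effects, variance
#' components, and optionally random-effect levels.
#'
#' @param fit A `ds_fit`.
#' @param path Output CSV.
#' @param include_levels Also write per-level random-effect draws
#'   (default FALSE; they dominate the file size).
#' @export
write_draws_csv <- function(fit, path, include_levels = FALSE) {
  stopifnot(inherits(fit, "ds_fit"))
  long <- function(m, prefix = "") {
    data.frame(parameter = rep(paste0(prefix, colnames(m)),
                               each = nrow(m)),
               chain = rep(fit$chain, ncol(m)),
               draw = rep(seq_len(nrow(m)), ncol(m)),
               value = as.vector(m))
  }
  out <- rbind(long(fit$draws$beta), long(fit$draws$sigma2, "sigma2_"))
  if (include_levels)
    for (nm in names(fit$draws$u))
      out <- rbind(out, long(fit$draws$u[[nm]], paste0(nm, ".")))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Persist convergence diagnostics as JSON
#'
#' @param fit A `ds_fit`.
#' @param path Output JSON path.
#' @export
write_diagnostics_json <- function(fit, path) {
  stopifnot(inherits(fit, "ds_fit"))
  jsonlite::write_json(
    list(converged = fit$converged,
         settings = unclass(fit$settings),
         parameters = fit$diagnostics),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
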