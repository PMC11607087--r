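#' Run the end-to-end analysis
#'
#' Orchestrates ingest (or simulation), trophic-position conversion,
#' similarity/relationship matrices, the population model for maternal
#' trophic positions, the basic repeatability model, the hybrid animal
#' model and its variance decomposition, windowed mother-offspring
#' correlations, and (optionally) the pedigree-permutation test — writing
#' tables and a run manifest under `out_dir`.
#'
#' @param config A list or path to a YAML file. Either a `simulate` block
#'   (overrides for [sim_config()]) or an `inputs` block with paths
#'   `samples`, `baseline`, `pedigree`, `home_ranges`. Optional keys:
#'   `seed` (default 1), `variant` ("env" or "spatial"), `reduced`
#'   ("full", "no_env", "no_env_no_maternal", "no_social"), `mcmc`
#'   (chains/iterations/warmup/thin), `n_perm` (default 0 = skip),
#'   `allow_unconverged` (default TRUE: summaries are produced but the
#'   convergence flag is recorded in the manifest).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the fitted objects and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  variant <- config$variant %||% "env"
  reduced <- config$reduced %||% "full"
  stopifnot(variant %in% c("env", "spatial"),
            reduced %in% c("full", "no_env", "no_env_no_maternal",
                           "no_social"))
  allow_unconv <- config$allow_unconverged %||% TRUE
  mc <- config$mcmc %||% list()
  settings <- mcmc_settings(chains = mc$chains %||% 4,
                            iterations = mc$iterations %||% 6000,
                            warmup = mc$warmup %||% 3000,
                            thin = mc$thin %||% 10, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  # ---- stage: ingest ----
  if (!is.null(config$simulate)) {
    say("stage ingest: simulating dataset (seed %d)", seed)
    sc <- do.call(sim_config, config$simulate)
    dat <- simulate_dataset(sc, seed)
    samples <- dat$samples
    baseline <- baseline_summary(dat$baseline)
    ped <- dat$pedigree
    hr <- dat$home_ranges
    daughters <- dat$ids$daughters
    mothers <- dat$ids$mothers
  } else {
    inp <- config$inputs
    for (k in c("samples", "baseline", "pedigree", "home_ranges"))
      if (is.null(inp[[k]]))
        stop("config$inputs$", k, " is required (stage: ingest)")
    say("stage ingest: reading input tables")
    baseline <- baseline_summary(
      utils::read.csv(inp$baseline)$d15n)
    samples <- read_isotope_table(inp$samples, baseline)
    ped <- read_pedigree(inp$pedigree)
    hr <- read_home_ranges(inp$home_ranges)
    dat <- NULL
    mothers <- unique(stats::na.omit(samples$mother_id))
    daughters <- unique(samples$bear_id[samples$sex == "female" &
                                          !is.na(samples$mother_id)])
  }
  write_isotope_table(samples, file.path(out_dir, "samples_tp.csv"))

  # ---- stage: matrices ----
  say("stage matrices: A over %d phenotyped daughters", length(daughters))
  A <- phenotyped_amatrix(ped, daughters)
  hr_d <- hr[hr$bear_id %in% daughters, , drop = FALSE]
  if (variant == "env") {
    K_env <- env_similarity(hr_d)
    env_name <- "env"
  } else {
    K_env <- spatial_similarity(hr_d)$similarity
    env_name <- "spatial"
  }
  write_matrix_csv(A, file.path(out_dir, "relationship_matrix.csv"))
  write_matrix_csv(K_env, file.path(out_dir,
                                    paste0(env_name, "_similarity.csv")))

  # ---- stage: maternal trophic position ----
  use_true_mat <- identical(config$maternal_tp, "true") && !is.null(dat)
  if (use_true_mat) {
    say("stage maternal_tp: using generator's latent maternal values")
    mat_tp <- dat$ledger$maternal_tp
  } else {
    say("stage maternal_tp: population model on %d mother samples",
        sum(samples$bear_id %in% mothers))
    mrows <- samples[samples$bear_id %in% mothers, , drop = FALSE]
    mfit <- suppressWarnings(fit_hmm(mrows, basic_model_spec(), settings))
    mat_tp <- extract_individual_tp(mfit)
  }
  utils::write.csv(data.frame(mother_id = names(mat_tp),
                              maternal_tp = unname(mat_tp)),
                   file.path(out_dir, "maternal_tp.csv"), row.names = FALSE)

  d <- samples[samples$bear_id %in% daughters, , drop = FALSE]
  d$maternal_tp <- unname(mat_tp[d$mother_id])
  if (anyNA(d$maternal_tp))
    stop("daughters with unknown maternal trophic position (stage: join)")

  # ---- stage: models ----
  say("stage fit: basic + animal model (variant %s, %s)", variant, reduced)
  res <- fit_specialization_models(
    d, A,
    K_env = if (reduced %in% c("no_env", "no_env_no_maternal")) NULL
            else K_env,
    env_name = env_name, settings = settings,
    allow_unconverged = allow_unconv,
    include_social = reduced != "no_social",
    include_maternal = reduced != "no_env_no_maternal")
  utils::write.csv(res$decomp$summary,
                   file.path(out_dir, "variance_decomposition.csv"),
                   row.names = FALSE)
  utils::write.csv(res$repeatability$summary,
                   file.path(out_dir, "repeatability.csv"),
                   row.names = FALSE)
  utils::write.csv(res$animal_fit$diagnostics,
                   file.path(out_dir, "diagnostics.csv"), row.names = FALSE)

  # ---- stage: social learning ----
  social <- NULL
  if (reduced != "no_social") {
    say("stage social: windowed mother-offspring correlations")
    pairs <- build_pair_table(d, mat_tp)
    social <- tryCatch(correlation_profile(pairs), error = function(e) {
      say("  skipped: %s", conditionMessage(e)); NULL
    })
    if (!is.null(social))
      utils::write.csv(social, file.path(out_dir, "correlation_profile.csv"),
                       row.names = FALSE)
  }

  # ---- stage: permutation power ----
  perm <- NULL
  n_perm <- config$n_perm %||% 0
  if (n_perm > 0) {
    say("stage power: %d pedigree permutations", n_perm)
    perm <- permutation_test(d, ped, n_perm = n_perm, seed = seed)
    utils::write.csv(data.frame(perm = seq_along(perm$null),
                                genetic_proportion = perm$null),
                     file.path(out_dir, "permutation_null.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dietspec")),
    seed = seed, variant = variant, reduced = reduced,
    mcmc = unclass(settings),
    n_samples = nrow(d), n_daughters = length(daughters),
    converged = res$animal_fit$converged,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config = config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(models = res, social = social, permutation = perm,
                 maternal_tp = mat_tp, manifest = manifest))
}
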