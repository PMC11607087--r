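#' Simulation configuration
#'
#' Defaults emulate the study population: 33 mothers with 1-6 daughters
#' each (median 2), 1-11 repeated annual trophic-position measures per
#' individual (median 3), philopatric settlement of daughters with a
#' median natal dispersal of 8.56 km, spatially autocorrelated habitat,
#' and variance components whose shares of the phenotypic variance match
#' the field estimates (additive genetic 3%, maternal 11%, environmental
#' similarity 5%, permanent individual 9%, social learning ~13%, residual
#' remainder). The social-learning effect of the maternal phenotype decays
#' linearly to zero `t_star` years after separation.
#'
#' @param n_mothers Number of founder mothers.
#' @param n_sires Founder sire pool (allows paternal half-sibs).
#' @param daughter_dist Probabilities for 1-6 daughters per mother.
#' @param target_daughters Optional exact total number of daughters.
#' @param obs_dist Probabilities for 1-11 annual samples per individual.
#' @param target_obs Optional exact total number of daughter samples.
#' @param sigma2_a,sigma2_m,sigma2_e,sigma2_i,sigma2_r Variance components
#'   (additive genetic, maternal, environmental-similarity, permanent
#'   individual, residual) on the trophic-position scale.
#' @param beta_sl Social-learning slope at separation (effect of the
#'   maternal deviation on the offspring phenotype at t = 0).
#' @param t_star Years since separation at which the social-learning
#'   effect has decayed to zero.
#' @param decay "linear" (to zero at `t_star`) or "exponential"
#'   (e-folding time `t_star`).
#' @param grand_mean Population mean trophic position.
#' @param dispersal_median_km Median daughter-mother centroid distance.
#' @param dispersal_sdlog Log-scale SD of the lognormal dispersal kernel.
#' @param extent_km Side of the square study area over which mother
#'   centroids scatter.
#' @param spatial_range_km e-folding range of habitat-field spatial
#'   autocorrelation.
#' @param include_sons Also generate male offspring (sampled only in their
#'   first years of independence).
#' @param sex_interaction Additive shift of the social-learning slope for
#'   sons (0 = transmission identical across sexes).
#' @param moose_mean,moose_sd,moose_n Baseline (moose hair) d15N
#'   distribution.
#' @param tef,lambda Trophic enrichment factor and baseline trophic level
#'   used to back-compute d15N from simulated trophic positions.
#' @return `sim_config` list.
#' @export
sim_config <- function(n_mothers = 33, n_sires = 15,
                       daughter_dist = c(0.30, 0.30, 0.20, 0.10, 0.06, 0.04),
                       target_daughters = NULL,
                       obs_dist = c(0.24, 0.22, 0.18, 0.12, 0.08, 0.06,
                                    0.04, 0.03, 0.015, 0.01, 0.005),
                       target_obs = NULL,
                       sigma2_a = 0.0012, sigma2_m = 0.0044,
                       sigma2_e = 0.0020, sigma2_i = 0.0036,
                       sigma2_r = 0.0236,
                       beta_sl = 1.6, t_star = 5, decay = "linear",
                       grand_mean = 2.9,
                       dispersal_median_km = 8.56, dispersal_sdlog = 0.6,
                       extent_km = 120, spatial_range_km = 20,
                       include_sons = FALSE, sex_interaction = 0,
                       moose_mean = 1.8, moose_sd = 1.26, moose_n = 21,
                       tef = 3.4, lambda = 2) {
  stopifnot(n_mothers >= 1, n_sires >= 1,
            all(daughter_dist >= 0), abs(sum(daughter_dist) - 1) < 1e-6,
            all(obs_dist >= 0), abs(sum(obs_dist) - 1) < 1e-6,
            sigma2_a >= 0, sigma2_m >= 0, sigma2_e >= 0, sigma2_i >= 0,
            sigma2_r >= 0, t_star > 0,
            decay %in% c("linear", "exponential"))
  as.list(environment())
}

# draw per-unit counts from `probs` (support 1..length), optionally nudged
# to an exact total while staying inside the support
.draw_counts <- function(n_units, probs, target = NULL) {
  k <- length(probs)
  cnt <- sample.int(k, n_units, replace = TRUE, prob = probs)
  if (!is.null(target)) {
    guard <- 0
    while (sum(cnt) != target && guard < 10000) {
      i <- sample.int(n_units, 1)
      if (sum(cnt) < target && cnt[i] < k) cnt[i] <- cnt[i] + 1L
      if (sum(cnt) > target && cnt[i] > 1L) cnt[i] <- cnt[i] - 1L
      guard <- guard + 1
    }
    if (sum(cnt) != target)
      stop("cannot reach target count within the per-unit support")
  }
  cnt
}

#' Simulate a pedigree of founder mothers, sires and their offspring
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List: `pedigree`, plus id vectors `mothers`, `sires`,
#'   `daughters`, `sons`.
#' @export
simulate_pedigree <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  if (config$n_mothers < 1) stop("need at least one mother")
  mothers <- sprintf("M%02d", seq_len(config$n_mothers))
  sires <- sprintf("S%02d", seq_len(config$n_sires))
  nd <- .draw_counts(config$n_mothers, config$daughter_dist,
                     config$target_daughters)
  dam <- rep(mothers, nd)
  daughters <- sprintf("D%03d", seq_along(dam))
  sire <- sample(sires, length(dam), replace = TRUE)
  sons <- character(0)
  dam_s <- sire_s <- character(0)
  if (config$include_sons) {
    ns <- .draw_counts(config$n_mothers, config$daughter_dist)
    dam_s <- rep(mothers, ns)
    sons <- sprintf("B%03d", seq_along(dam_s))
    sire_s <- sample(sires, length(dam_s), replace = TRUE)
  }
  ped <- pedigree(c(mothers, sires, daughters, sons),
                  dam = c(rep(NA, length(mothers) + length(sires)),
                          dam, dam_s),
                  sire = c(rep(NA, length(mothers) + length(sires)),
                           sire, sire_s))
  list(pedigree = ped, mothers = mothers, sires = sires,
       daughters = daughters, sons = sons)
}

#' Simulate philopatric home ranges and autocorrelated habitat
#'
#' Mother centroids scatter uniformly over the study extent; each
#' offspring's centroid is its mother's plus an isotropic lognormal
#' displacement with the configured median. Habitat class fractions come
#' from smooth Gaussian random fields with exponential distance-decaying
#' correlation evaluated at the centroids (softmax over four classes);
#' Simpson diversity is computed from the full class set.
#'
#' @param sim Output of [simulate_pedigree()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Home-range feature table for all phenotyped individuals
#'   (mothers and offspring).
#' @export
simulate_environment <- function(sim, config = sim_config(), seed = 1) {
  set.seed(seed + 1L)
  mothers <- sim$mothers
  offspring <- c(sim$daughters, sim$sons)
  mx <- stats::runif(length(mothers), 0, config$extent_km)
  my <- stats::runif(length(mothers), 0, config$extent_km)
  names(mx) <- names(my) <- mothers
  dam <- sim$pedigree$dam[match(offspring, sim$pedigree$id)]
  ang <- stats::runif(length(offspring), 0, 2 * pi)
  dist <- stats::rlnorm(length(offspring), log(config$dispersal_median_km),
                        config$dispersal_sdlog)
  ox <- mx[dam] + dist * cos(ang)
  oy <- my[dam] + dist * sin(ang)
  ids <- c(mothers, offspring)
  x <- c(mx, ox); y <- c(my, oy)
  D <- as.matrix(stats::dist(cbind(x, y)))
  C <- exp(-D / config$spatial_range_km)
  L <- chol(C + diag(1e-8, nrow(C)))
  g <- t(L) %*% matrix(stats::rnorm(3 * length(ids)), ncol = 3)
  logits <- cbind(-0.2 + 0.9 * g[, 1], -0.8 + 0.9 * g[, 2],
                  -0.6 + 0.9 * g[, 3], -1.2)
  p <- exp(logits) / rowSums(exp(logits))
  data.frame(bear_id = ids, centroid_x_km = unname(x),
             centroid_y_km = unname(y),
             prop_mature = p[, 1], prop_disturbed = p[, 2],
             simpson_diversity = apply(p, 1, simpson_diversity),
             stringsAsFactors = FALSE)
}

.sl_weight <- function(t, config) {
  if (config$decay == "linear")
    pmax(0, config$beta_sl * (1 - t / config$t_star))
  else config$beta_sl * exp(-t / config$t_star)
}

#' Simulate phenotypes and back-compute d15N
#'
#' Generative mirror of the animal model: breeding values
#' `a ~ N(0, s2_A A)` over the whole pedigree, maternal effects
#' `m ~ N(0, s2_M)` per mother, environmental effects `u ~ N(0, s2_E E)`
#' (E from [env_similarity()] of the simulated home ranges), permanent
#' individual effects `p ~ N(0, s2_I)`, and i.i.d. residuals. A mother's
#' (latent) trophic position is `grand_mean + a + u + p`; an offspring
#' observation t years after separation adds
#' `w(t) * (maternal TP - grand_mean)` with `w` the decaying
#' social-learning weight. d15N is back-computed by inverting the
#' trophic-position equation against the realised moose-baseline mean, so
#' ingest reproduces the simulated trophic positions exactly.
#'
#' @param sim Output of [simulate_pedigree()].
#' @param env Output of [simulate_environment()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List: `samples` (isotope table incl. d15N and
#'   `trophic_position`), `baseline` (moose d15N values), `pedigree`,
#'   `home_ranges`, `ledger` (every latent value plus per-row systematic
#'   part and residual), `true` (realised variance components and their
#'   proportions of the phenotypic variance on the daughter rows).
#' @export
simulate_phenotypes <- function(sim, env, config = sim_config(), seed = 1) {
  set.seed(seed + 2L)
  ped <- sim$pedigree
  mothers <- sim$mothers
  offspring <- c(sim$daughters, sim$sons)
  pheno <- c(mothers, offspring)

  A <- additive_relationship(ped)
  La <- chol(A + diag(1e-10, nrow(A)))
  a <- drop(t(La) %*% stats::rnorm(nrow(A))) * sqrt(config$sigma2_a)
  names(a) <- rownames(A)

  E <- env_similarity(env)
  Le <- chol(E + diag(1e-8, nrow(E)))
  u <- drop(t(Le) %*% stats::rnorm(nrow(E))) * sqrt(config$sigma2_e)
  names(u) <- rownames(E)

  m <- stats::rnorm(length(mothers), 0, sqrt(config$sigma2_m))
  names(m) <- mothers
  pp <- stats::rnorm(length(pheno), 0, sqrt(config$sigma2_i))
  names(pp) <- pheno

  maternal_tp <- config$grand_mean + a[mothers] + u[mothers] + pp[mothers]

  n_obs_m <- .draw_counts(length(mothers), config$obs_dist)
  rows_m <- data.frame(
    bear_id = rep(mothers, n_obs_m),
    year = 1990 + unlist(lapply(n_obs_m, seq_len)),
    age = 4 + unlist(lapply(n_obs_m, seq_len)) +
      rep(sample.int(10, length(mothers), replace = TRUE), n_obs_m),
    years_since_separation = NA_integer_,
    mother_id = NA_character_, father_id = NA_character_,
    sex = "female", stringsAsFactors = FALSE)
  rows_m$systematic <- maternal_tp[rows_m$bear_id]
  rows_m$sl_term <- 0

  n_obs_d <- .draw_counts(length(sim$daughters), config$obs_dist,
                          config$target_obs)
  n_obs_s <- if (length(sim$sons)) {
    # sons are monitored only briefly after family breakup
    pmin(.draw_counts(length(sim$sons), config$obs_dist), 2L)
  } else integer(0)
  n_obs_o <- c(n_obs_d, n_obs_s)
  t_o <- unlist(lapply(n_obs_o, seq_len))
  rows_o <- data.frame(
    bear_id = rep(offspring, n_obs_o),
    year = 2000 + t_o,
    age = t_o + 2L,
    years_since_separation = t_o,
    mother_id = rep(ped$dam[match(offspring, ped$id)], n_obs_o),
    father_id = rep(ped$sire[match(offspring, ped$id)], n_obs_o),
    sex = rep(ifelse(offspring %in% sim$sons, "male", "female"), n_obs_o),
    stringsAsFactors = FALSE)
  w <- .sl_weight(rows_o$years_since_separation, config)
  if (config$sex_interaction != 0) {
    w_son <- .sl_weight(rows_o$years_since_separation,
                        utils::modifyList(config, list(
                          beta_sl = config$beta_sl + config$sex_interaction)))
    w[rows_o$sex == "male"] <- w_son[rows_o$sex == "male"]
  }
  rows_o$sl_term <- w * (maternal_tp[rows_o$mother_id] - config$grand_mean)
  rows_o$systematic <- config$grand_mean + rows_o$sl_term +
    a[rows_o$bear_id] + m[rows_o$mother_id] + u[rows_o$bear_id] +
    pp[rows_o$bear_id]

  rows <- rbind(rows_m, rows_o)
  eps <- stats::rnorm(nrow(rows), 0, sqrt(config$sigma2_r))
  rows$trophic_position <- rows$systematic + eps

  moose <- stats::rnorm(config$moose_n, config$moose_mean, config$moose_sd)
  bl <- baseline_summary(moose)
  cfg_tp <- trophic_config(config$tef, config$lambda)
  rows$d15n <- (rows$trophic_position - cfg_tp$lambda) * cfg_tp$tef +
    bl$mean_d15n

  samples <- rows[c("bear_id", "year", "d15n", "age",
                    "years_since_separation", "mother_id", "father_id",
                    "sex", "trophic_position")]
  validate_isotope_table(samples)

  is_daughter_row <- samples$bear_id %in% sim$daughters
  v_sl <- stats::var(rows$sl_term[is_daughter_row])
  v_p <- config$sigma2_a + config$sigma2_m + config$sigma2_e +
    config$sigma2_i + config$sigma2_r + v_sl
  true <- list(
    variances = c(social_learning = v_sl, animal = config$sigma2_a,
                  mother = config$sigma2_m, env = config$sigma2_e,
                  individual = config$sigma2_i, residual = config$sigma2_r),
    proportions = c(social_learning = v_sl, animal = config$sigma2_a,
                    mother = config$sigma2_m, env = config$sigma2_e,
                    individual = config$sigma2_i,
                    residual = config$sigma2_r) / v_p)

  list(samples = samples, baseline = moose, pedigree = ped,
       home_ranges = env,
       ledger = list(a = a, m = m, u = u, p = pp,
                     maternal_tp = maternal_tp,
                     paternal_tp = config$grand_mean + a[sim$sires],
                     systematic = rows$systematic, residual = eps,
                     sl_term = rows$sl_term,
                     baseline_mean = bl$mean_d15n),
       true = true, config = config,
       ids = list(mothers = mothers, daughters = sim$daughters,
                  sons = sim$sons))
}

#' One-call synthetic dataset
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (drives pedigree, environment and phenotypes).
#' @return See [simulate_phenotypes()].
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  sim <- simulate_pedigree(config, seed)
  env <- simulate_environment(sim, config, seed)
  simulate_phenotypes(sim, env, config, seed)
}
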