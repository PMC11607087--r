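test_that("decomposition arithmetic on prescribed draws", {
  S <- 50; n <- 40
  set.seed(7)
  X <- cbind(`(Intercept)` = rep(1, n), x = rnorm(n))
  # all random variances zero, nonzero fixed effect -> fixed proportion 1
  f <- fake_fit(X, beta = cbind(rep(0, S), rep(2, S)),
                sigma2 = matrix(c(rep(0, S), rep(0, S)), S, 2,
                                dimnames = list(NULL, c("individual",
                                                        "residual"))))
  f$draws$sigma2[, "residual"] <- 1e-12
  dec <- decompose_variance(f)
  expect_equal(unname(dec$proportions[, "V_fixed"]), rep(1, S),
               tolerance = 1e-6)

  # two iid components with equal variance and no fixed effects
  f2 <- fake_fit(cbind(`(Intercept)` = rep(1, n)),
                 beta = matrix(0, S, 1),
                 sigma2 = matrix(2, S, 3,
                                 dimnames = list(NULL, c("a", "b",
                                                         "residual"))))
  dec2 <- decompose_variance(f2)
  expect_equal(dec2$proportions[, "V_a"], dec2$proportions[, "V_b"])
  expect_equal(unname(dec2$proportions[, "V_a"]), rep(1 / 3, S))
})

test_that("per-draw proportions sum to one and summaries stay in [0, 1]", {
  set.seed(8)
  dat <- simulate_dataset(sim_config(n_mothers = 8, target_daughters = 16,
                                     target_obs = 48), seed = 3)
  d <- dat$samples[dat$samples$bear_id %in% dat$ids$daughters, ]
  d$maternal_tp <- unname(dat$ledger$maternal_tp[d$mother_id])
  A <- phenotyped_amatrix(dat$pedigree, dat$ids$daughters)
  fit <- suppressWarnings(fit_hmm(
    d, animal_model_spec(A, K_env = NULL),
    quick_mcmc(seed = 4, iterations = 1500, warmup = 500)))
  dec <- decompose_variance(fit,
                            groups = list(V_Age = "age",
                                          V_SL = "social_learning"),
                            allow_unconverged = TRUE)
  expect_lt(max(abs(rowSums(dec$proportions) - 1)), 1e-10)
  expect_true(all(dec$summary$median >= 0 & dec$summary$median <= 1))
  expect_true(all(dec$summary$ci_low <= dec$summary$median))
  # relabeling random terms leaves the proportions unchanged
  expect_setequal(colnames(dec$proportions),
                  c("V_Age", "V_SL", "V_individual", "V_mother", "V_animal",
                    "V_residual"))
})

test_that("semi-partial fixed-effect partition is additive and exact", {
  S <- 30; n <- 200
  set.seed(9)
  # orthogonal covariates: each group's contribution is its own variance
  x1 <- rnorm(n); x1 <- x1 - mean(x1)
  x2 <- rnorm(n); x2 <- x2 - mean(x2)
  x2 <- x2 - x1 * sum(x1 * x2) / sum(x1^2)   # exactly orthogonal
  X <- cbind(`(Intercept)` = 1, a = x1, b = x2)
  beta <- cbind(rnorm(S), rnorm(S, 1, .2), rnorm(S, 1, .2))
  f <- fake_fit(X, beta,
                sigma2 = matrix(1, S, 1, dimnames = list(NULL, "residual")),
                col_group = c(NA, "ga", "gb"))
  parts <- partition_fixed(f, groups = list(A = "ga", B = "gb"))
  expect_equal(parts[, "A"], beta[, 2]^2 * var(x1), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(parts[, "B"], beta[, 3]^2 * var(x2), tolerance = 1e-10,
               ignore_attr = TRUE)

  # correlated covariates: rescaled contributions still sum to V_fixed
  x3 <- 0.7 * x1 + 0.3 * rnorm(n)
  X2 <- cbind(`(Intercept)` = 1, a = x1, b = x3)
  f2 <- fake_fit(X2, beta,
                 sigma2 = matrix(1, S, 1, dimnames = list(NULL, "residual")),
                 col_group = c(NA, "ga", "gb"))
  parts2 <- partition_fixed(f2, groups = list(A = "ga", B = "gb"))
  v_fixed <- apply(beta %*% t(X2), 1, var)
  expect_lt(max(abs(rowSums(parts2) - v_fixed)), 1e-10)
  expect_true(all(parts2 >= 0))

  # a single group holding all terms reduces to plain V_fixed
  one <- partition_fixed(f2, groups = list(all = c("ga", "gb")))
  expect_equal(unname(one[, "all"]), v_fixed, tolerance = 1e-10)

  # zeroed coefficients give a zero share
  f3 <- f2; f3$draws$beta[, 3] <- 0
  parts3 <- partition_fixed(f3, groups = list(A = "ga", B = "gb"))
  expect_equal(unname(parts3[, "B"]), rep(0, S), tolerance = 1e-12)

  expect_error(partition_fixed(f2, groups = list(A = "nope")),
               "covers no fixed-effect columns")
})

test_that("repeatability ratios follow their closed forms", {
  S <- 40; n <- 20
  f <- fake_fit(cbind(`(Intercept)` = rep(1, n)), beta = matrix(0, S, 1),
                sigma2 = cbind(individual = rep(2, S), residual = rep(2, S)))
  r <- repeatability(f)
  expect_equal(unname(r$without_fixed), rep(0.5, S))
  expect_equal(unname(r$with_fixed), rep(0.5, S))   # V_Age = 0 here
  f0 <- f; f0$draws$sigma2[, "individual"] <- 0
  expect_equal(unname(repeatability(f0)$without_fixed), rep(0, S))
  expect_error(repeatability(f, term = "ghost"), "no random term")
})

test_that("repeatability from the sampler matches the ANOVA oracle", {
  set.seed(15)
  n_id <- 70; k <- 2
  icc_true <- 0.48
  u <- rnorm(n_id, 0, sqrt(icc_true))
  d <- data.frame(bear_id = rep(sprintf("b%02d", 1:n_id), each = k),
                  age = rep(1:k, n_id))
  d$trophic_position <- 2.9 + u[as.integer(factor(d$bear_id))] +
    rnorm(n_id * k, 0, sqrt(1 - icc_true))
  f <- suppressWarnings(fit_hmm(d, basic_model_spec(),
                                quick_mcmc(seed = 16, iterations = 3000,
                                           warmup = 1000, thin = 3)))
  r <- repeatability(f, allow_unconverged = TRUE)
  ms <- anova(aov(trophic_position ~ bear_id, d))
  msb <- ms$`Mean Sq`[1]; msw <- ms$`Mean Sq`[2]
  icc_anova <- (msb - msw) / (msb + (k - 1) * msw)
  expect_equal(median(r$without_fixed), icc_anova, tolerance = 0.1)
})

test_that("Nakagawa R2 reduces correctly in the degenerate cases", {
  S <- 25; n <- 60
  set.seed(17)
  X <- cbind(`(Intercept)` = rep(1, n), x = rnorm(n))
  # no random effects: marginal = conditional
  f <- fake_fit(X, beta = cbind(rep(0, S), rep(1, S)),
                sigma2 = matrix(1, S, 1, dimnames = list(NULL, "residual")))
  r2 <- nakagawa_r2(f)
  expect_equal(r2$marginal, r2$conditional)
  # intercept-only: marginal = 0
  f2 <- fake_fit(X, beta = cbind(rep(3, S), rep(0, S)),
                 sigma2 = cbind(individual = rep(1, S),
                                residual = rep(1, S)))
  expect_equal(unname(r2_0 <- nakagawa_r2(f2)$marginal), rep(0, S))
  expect_equal(unname(nakagawa_r2(f2)$conditional), rep(0.5, S))
  # known construction: V_fix = 1, V_I = 1, V_R = 2 -> marginal 1/4,
  # conditional 1/2
  xfix <- rnorm(n); xfix <- (xfix - mean(xfix)) / sd(xfix)
  f3 <- fake_fit(cbind(`(Intercept)` = rep(1, n), x = xfix),
                 beta = cbind(rep(0, S), rep(1, S)),
                 sigma2 = cbind(individual = rep(1, S),
                                residual = rep(2, S)))
  r3 <- nakagawa_r2(f3)
  expect_equal(median(r3$marginal), 0.25, tolerance = 1e-10)
  expect_equal(median(r3$conditional), 0.5, tolerance = 1e-10)
})

test_that("equal-tail interval matches the quantile definition", {
  x <- 1:1000
  expect_equal(eti(x), quantile(x, c(0.055, 0.945), names = FALSE))
})
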