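test_that("intercept-only model recovers the residual variance", {
  set.seed(42)
  d <- data.frame(y = rnorm(500, 5, 1))
  f <- fit_hmm(d, model_spec("y"), quick_mcmc(seed = 7))
  expect_gt(median(f$draws$sigma2[, "residual"]), 0.85)
  expect_lt(median(f$draws$sigma2[, "residual"]), 1.15)
  expect_equal(median(f$draws$beta[, 1]), 5, tolerance = 0.05)
  expect_true(f$converged)
})

test_that("draws are reproducible per seed", {
  set.seed(1)
  d <- data.frame(y = rnorm(60), g = rep(letters[1:12], 5))
  sp <- model_spec("y", random = list(re_term("individual", "g")))
  f1 <- fit_hmm(d, sp, quick_mcmc(seed = 5, iterations = 600, warmup = 300))
  f2 <- fit_hmm(d, sp, quick_mcmc(seed = 5, iterations = 600, warmup = 300))
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_hmm(d, sp, quick_mcmc(seed = 6, iterations = 600, warmup = 300))
  expect_false(identical(f1$draws$beta, f3$draws$beta))
})

test_that("grouped model recovers a known ICC against the ANOVA oracle", {
  set.seed(10)
  n_id <- 80; k <- 6
  u <- rnorm(n_id, 0, 1)
  d <- data.frame(g = rep(sprintf("id%02d", 1:n_id), each = k))
  d$y <- 3 + u[as.integer(factor(d$g))] + rnorm(n_id * k, 0, 1)
  f <- fit_hmm(d, model_spec("y", random = list(re_term("individual", "g"))),
               quick_mcmc(seed = 2, iterations = 3000, warmup = 1000,
                          thin = 3))
  s2 <- f$draws$sigma2
  icc_post <- median(s2[, "individual"] / rowSums(s2))
  # one-way ANOVA moment estimator on the same data
  ms <- anova(aov(y ~ g, d))
  msb <- ms$`Mean Sq`[1]; msw <- ms$`Mean Sq`[2]
  icc_anova <- (msb - msw) / (msb + (k - 1) * msw)
  expect_equal(icc_post, icc_anova, tolerance = 0.05)
})

test_that("covariance-structured effects recover correlated truth", {
  set.seed(21)
  n_id <- 60; k <- 4
  ids <- sprintf("i%02d", 1:n_id)
  R <- 0.5^abs(outer(1:n_id, 1:n_id, `-`))   # AR(1) relatedness surrogate
  dimnames(R) <- list(ids, ids)
  u <- drop(t(chol(R)) %*% rnorm(n_id)) * sqrt(2)
  d <- data.frame(g = rep(ids, each = k))
  d$y <- u[match(d$g, ids)] + rnorm(n_id * k, 0, 1)
  f <- fit_hmm(d, model_spec("y", random = list(
    re_term("struct", "g", cov = R))),
    quick_mcmc(seed = 3, iterations = 3000, warmup = 1000, thin = 3))
  expect_equal(median(f$draws$sigma2[, "struct"]), 2, tolerance = 0.8)
  expect_equal(median(f$draws$sigma2[, "residual"]), 1, tolerance = 0.3)
})

test_that("a saturated individual effect is flagged as unidentified", {
  set.seed(3)
  d <- data.frame(y = rnorm(60), g = sprintf("i%02d", 1:60))  # 1 obs each
  expect_warning(
    fit_hmm(d, model_spec("y", random = list(re_term("individual", "g"))),
            quick_mcmc(seed = 4, iterations = 1000, warmup = 500)),
    "non-converged")
})

test_that("individual trophic positions shrink toward the intercept", {
  set.seed(6)
  n_id <- 40
  mu_true <- rnorm(n_id, 0, 0.5)
  d <- data.frame(bear_id = rep(sprintf("b%02d", 1:n_id), each = 5))
  d$trophic_position <- 2.9 + mu_true[as.integer(factor(d$bear_id))] +
    rnorm(nrow(d), 0, 0.3)
  d$age <- rep(1:5, n_id)
  f <- fit_hmm(d, basic_model_spec(),
               quick_mcmc(seed = 8, iterations = 2000, warmup = 1000))
  est <- extract_individual_tp(f)
  expect_gt(cor(est, 2.9 + mu_true), 0.9)
  top <- names(sort(mu_true + 0, decreasing = TRUE))[1]
  expect_gt(est[which.max(mu_true)], median(f$draws$beta[, 1]))
  expect_error(extract_individual_tp(f, "nobody"), "unknown id")
  expect_error(extract_individual_tp(f, term = "ghost"), "no random term")
})

test_that("pointwise log-likelihood matches the closed form", {
  set.seed(5)
  d <- data.frame(y = rnorm(30), x = rnorm(30))
  f <- fit_hmm(d, model_spec("y", fixed = list(fe_term("x"))),
               quick_mcmc(seed = 5, iterations = 600, warmup = 300))
  ll <- pointwise_loglik(f)
  expect_equal(dim(ll), c(nrow(f$draws$beta), 30))
  # direct evaluation oracle, draw by draw
  eta <- f$draws$beta %*% t(f$design$X)
  s2 <- f$draws$sigma2[, "residual"]
  direct <- sapply(1:30, function(i) dnorm(d$y[i], eta[, i], sqrt(s2),
                                           log = TRUE))
  expect_lt(max(abs(ll - direct)), 1e-10)
  # joint conditional log-likelihood = row sums
  expect_equal(rowSums(ll), sapply(seq_len(nrow(eta)), function(s)
    sum(dnorm(d$y, eta[s, ], sqrt(s2[s]), log = TRUE))), tolerance = 1e-10)
  # an observation at its predicted mean has density -0.5 log(2 pi s2),
  # and doubling the residual sd lowers it
  expect_equal(dnorm(0, 0, 1, log = TRUE), -0.5 * log(2 * pi))
  expect_lt(dnorm(0, 0, 2, log = TRUE), dnorm(0, 0, 1, log = TRUE))
})

test_that("convergence gate blocks summaries of unconverged fits", {
  sk <- fake_fit(X = cbind(`(Intercept)` = rep(1, 4)),
                 beta = matrix(0, 10, 1),
                 sigma2 = matrix(1, 10, 2,
                                 dimnames = list(NULL, c("individual",
                                                         "residual"))))
  sk$converged <- FALSE
  expect_error(check_convergence(sk), "not converged")
  expect_silent(check_convergence(sk, allow_unconverged = TRUE))
})

test_that("levels with no observations shrink to the population intercept", {
  set.seed(44)
  ids <- sprintf("i%02d", 1:21)
  K <- diag(21); dimnames(K) <- list(ids, ids)
  d <- data.frame(bear_id = rep(ids[1:20], each = 3))   # i21 unobserved
  d$trophic_position <- rnorm(60, 2.9, 0.3)
  d$age <- rep(1:3, 20)
  sp <- model_spec("trophic_position",
                   fixed = list(fe_term("age")),
                   random = list(re_term("individual", "bear_id", cov = K)))
  f <- suppressWarnings(fit_hmm(d, sp, quick_mcmc(seed = 45,
                                                  iterations = 1500,
                                                  warmup = 500)))
  est <- extract_individual_tp(f)
  b0 <- median(f$draws$beta[, "(Intercept)"])
  # prior-centred: the unobserved level sits essentially at the intercept
  expect_lt(abs(est["i21"] - b0), 0.05)
  expect_equal(median(f$draws$u$individual[, "i21"]), 0, tolerance = 0.05)
})
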