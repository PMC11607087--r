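make_pairs <- function(off, mat, t, sex = "female", pat = NA_real_,
                       id = NULL) {
  data.frame(offspring_id = id %||% sprintf("o%03d", seq_along(off)),
             offspring_tp = off, maternal_tp = mat, paternal_tp = pat,
             years_since_separation = t, sex = sex,
             stringsAsFactors = FALSE)
}

test_that("windowed correlation matches hand computation and edge rules", {
  # four hand-written pairs
  off <- c(2.8, 3.0, 3.1, 2.7); mat <- c(2.9, 3.05, 3.2, 2.75)
  p <- make_pairs(off, mat, t = c(1, 1, 2, 2))
  ct <- windowed_correlation(p, c(1, 2))
  r_hand <- sum((off - mean(off)) * (mat - mean(mat))) /
    sqrt(sum((off - mean(off))^2) * sum((mat - mean(mat))^2))
  expect_equal(ct$r, r_hand)
  expect_equal(ct$df, 2L)
  expect_equal(ct$p, cor.test(off, mat)$p.value)

  # perfectly collinear pairs
  lin <- make_pairs(1:10 / 10 + 2, 1:10 / 10 + 2.5, t = rep(1, 10))
  expect_equal(windowed_correlation(lin, c(1, 2))$r, 1)
  expect_lt(windowed_correlation(lin, c(1, 2))$p, 1e-10)

  expect_error(windowed_correlation(p, c(5, 9)), ">= 3 pairs")
  same <- make_pairs(rep(3, 5), rnorm(5, 3), t = rep(1, 5))
  expect_error(windowed_correlation(same, c(1, 2)), "zero variance")
})

test_that("window [0, Inf) equals the pooled correlation", {
  set.seed(21)
  p <- make_pairs(rnorm(40, 3, .2), rnorm(40, 3, .1), t = sample(1:8, 40,
                                                                 TRUE))
  ct <- windowed_correlation(p, c(0, Inf))
  expect_equal(ct$r, cor(p$offspring_tp, p$maternal_tp))
  expect_equal(ct$n, 40L)
})

test_that("permuting maternal values against offspring kills the signal", {
  set.seed(22)
  mat <- rnorm(200, 3, 0.2)
  off <- mat + rnorm(200, 0, 0.1)
  p_null <- make_pairs(off, sample(mat), t = rep(1, 200))
  ct <- windowed_correlation(p_null, c(1, 2))
  expect_lt(abs(ct$r), 0.2)
  expect_gt(windowed_correlation(make_pairs(off, mat, rep(1, 200)),
                                 c(1, 2))$r, 0.8)
})

test_that("individual-averaged sensitivity variant collapses repeats", {
  p <- make_pairs(c(3.0, 3.2, 2.8), c(3, 3, 2.9), t = c(1, 2, 1),
                  id = c("a", "a", "b"))
  p <- rbind(p, make_pairs(2.95, 3.05, 2, id = "c"))
  ct <- windowed_correlation(p, c(1, 2), average_within_individual = TRUE)
  expect_equal(ct$n, 3L)
})

test_that("model comparison keeps the maternal-only model when sex is inert", {
  set.seed(23)
  n_id <- 60                       # two samples per offspring
  mat_i <- rnorm(n_id, 3, 0.2)
  sex_i <- sample(c("female", "male"), n_id, TRUE)
  ind_i <- rnorm(n_id, 0, 0.1)
  mat <- rep(mat_i, each = 2); n <- 2 * n_id
  p <- make_pairs(3 + 0.8 * (mat - 3) + rep(ind_i, each = 2) +
                    rnorm(n, 0, 0.15), mat,
                  t = rep(1:2, n_id), sex = rep(sex_i, each = 2),
                  id = rep(sprintf("o%03d", 1:n_id), each = 2))
  res <- sex_model_comparison(p, settings = quick_mcmc(seed = 24,
                                                       iterations = 1500,
                                                       warmup = 500))
  expect_equal(res$chosen, "maternal_only")
  expect_gt(res$marginal_r2, 0.3)
  expect_gt(res$pearson$r, 0.5)
  expect_error(sex_model_comparison(p[p$sex == "female", ]),
               "both sexes")
})

test_that("a strong sex interaction is detected by elpd", {
  set.seed(25)
  n_id <- 150                      # two samples per offspring, n = 300
  mat_i <- rnorm(n_id, 3, 0.3)
  sex_i <- sample(c("female", "male"), n_id, TRUE)
  slope_i <- ifelse(sex_i == "female", 1.0, 0.0)  # slopes differ by 1.0
  ind_i <- rnorm(n_id, 0, 0.1)
  mat <- rep(mat_i, each = 2); n <- 2 * n_id
  p <- make_pairs(3 + rep(slope_i * (mat_i - 3) + ind_i, each = 2) +
                    rnorm(n, 0, 0.15), mat,
                  t = rep(1:2, n_id), sex = rep(sex_i, each = 2),
                  id = rep(sprintf("o%03d", 1:n_id), each = 2))
  res <- sex_model_comparison(p, settings = quick_mcmc(seed = 26,
                                                       iterations = 1500,
                                                       warmup = 500))
  expect_equal(res$chosen, "maternal_x_sex")
  tab <- res$comparison
  expect_lt(max(tab$elpd_diff[tab$model != "maternal_x_sex"]), -4)
})

test_that("paternal analysis finds nothing when fathers are uninformative", {
  set.seed(27)
  n_id <- 40                       # two samples per offspring
  pat_i <- rep(rnorm(12, 3, 0.25), length.out = n_id)
  off_i <- rnorm(n_id, 3, 0.15)
  n <- 2 * n_id
  p <- make_pairs(rep(off_i, each = 2) + rnorm(n, 0, 0.15),
                  rnorm(n, 3, 0.2), t = rep(1:2, n_id),
                  pat = rep(pat_i, each = 2),
                  id = rep(sprintf("o%03d", 1:n_id), each = 2))
  res <- paternal_effect(p, settings = quick_mcmc(seed = 28,
                                                  iterations = 1500,
                                                  warmup = 500))
  expect_lt(res$explained_variance, 0.12)
  expect_gt(res$p, 0.01)
  expect_false(any(res$comparison$preferred[res$comparison$model ==
                                              "paternal"]))
  expect_equal(res$n_fathers, 12L)
})

test_that("degenerate paternal inputs raise the documented errors", {
  p <- make_pairs(c(3, 3.1, 3.2, 2.9), rnorm(4, 3), t = rep(1, 4),
                  pat = c(3, 3.1, 3, 3.1))
  expect_error(paternal_effect(p), ">= 3 distinct fathers")
  expect_error(paternal_effect(p[1:2, ]), ">= 3 offspring")
})

test_that("offspring tracking their father exactly gives r = 1", {
  set.seed(29)
  pat <- rep(rnorm(12, 3, 0.3), each = 2)
  p <- make_pairs(pat, rnorm(24, 3, .2), t = rep(1:2, 12), pat = pat,
                  id = rep(sprintf("o%03d", 1:12), each = 2))
  res <- suppressWarnings(paternal_effect(p, settings = quick_mcmc(
    seed = 30, iterations = 1000, warmup = 500)))
  expect_equal(res$r, 1)
  expect_gt(res$explained_variance, 0.8)
})
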