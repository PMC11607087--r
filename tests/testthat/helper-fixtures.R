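# shared fixtures and independent oracles

quick_mcmc <- function(seed = 1, chains = 2, iterations = 2000,
                       warmup = 1000, thin = 2) {
  mcmc_settings(chains = chains, iterations = iterations, warmup = warmup,
                thin = thin, seed = seed)
}

# small three-generation pedigree: two founder pairs, full sibs, a grandchild
trio_pedigree <- function() {
  pedigree(id = c("f1", "m1", "f2", "m2", "c1", "c2", "c3", "g1"),
           dam = c(NA, NA, NA, NA, "m1", "m1", "m2", "c3"),
           sire = c(NA, NA, NA, NA, "f1", "f1", "f2", "c1"))
}

# random acyclic pedigree: founders first, later individuals draw parents
# from strictly earlier ones (so the structure is valid by construction)
random_pedigree <- function(n_founders = 10, n_desc = 20, seed = 1) {
  set.seed(seed)
  n <- n_founders + n_desc
  id <- sprintf("i%02d", seq_len(n))
  dam <- sire <- rep(NA_character_, n)
  for (j in (n_founders + 1):n) {
    pool <- seq_len(j - 1)
    dam[j] <- id[sample(pool, 1)]
    sire[j] <- id[sample(pool, 1)]
  }
  pedigree(id, dam, sire)
}

# gene-dropping Monte-Carlo estimate of 2 x kinship (including the diagonal
# 1 + F), fully independent of the tabular-method recursion
gene_drop_amatrix <- function(ped, n_rep = 100000, seed = 99) {
  set.seed(seed)
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  pd <- match(ped$dam, ped$id)
  ps <- match(ped$sire, ped$id)
  a1 <- matrix(0L, n_rep, n)
  a2 <- matrix(0L, n_rep, n)
  next_allele <- 0L
  new_alleles <- function() {
    next_allele <<- next_allele + 1L
    next_allele
  }
  draw_from <- function(p) {
    pick <- stats::runif(n_rep) < 0.5
    ifelse(pick, a1[, p], a2[, p])
  }
  for (j in seq_len(n)) {
    a1[, j] <- if (is.na(pd[j])) new_alleles() else draw_from(pd[j])
    a2[, j] <- if (is.na(ps[j])) new_alleles() else draw_from(ps[j])
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      f <- (colMeans(cbind(a1[, i] == a1[, j], a1[, i] == a2[, j],
                           a2[, i] == a1[, j], a2[, i] == a2[, j])))
      A[i, j] <- A[j, i] <- 2 * mean(f)
    }
  }
  A
}

# fabricate a ds_fit with prescribed draws, for testing the partitioning
# arithmetic in isolation from the sampler
fake_fit <- function(X, beta, sigma2, col_group = NULL, y = NULL,
                     u = list(), re = list()) {
  S <- nrow(beta)
  design <- structure(list(
    y = y %||% rep(0, nrow(X)), X = X,
    col_group = col_group %||% rep(NA_character_, ncol(X)),
    re = re, n = nrow(X)), class = "ds_design")
  structure(list(draws = list(beta = beta, sigma2 = sigma2, u = u),
                 chain = rep(1:2, length.out = S), design = design,
                 settings = mcmc_settings(seed = 1),
                 diagnostics = data.frame(), converged = TRUE),
            class = "ds_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
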