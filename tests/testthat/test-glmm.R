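# shared small structured similarity matrix for the GLMM unit tests
glmm_V <- local({
  co <- simulate_cohort(sim_config(n_samples = 150, n_snps = 10,
                                   total_snp_effect = 0, n_causal = 0,
                                   n_rois = 20, seed = 3))
  co$similarity$matrix
})

test_that("identity covariance reduces the gaussian GLMM to ordinary least
           squares", {
  set.seed(14)
  n <- 120
  X <- cbind(1, matrix(rnorm(n * 3), n, 3))
  y <- drop(X %*% c(1, .5, -.2, 0)) + rnorm(n)
  fit <- fit_null_glmm(y, X, diag(n), family = "gaussian")
  ols <- qr.solve(X, y)
  expect_equal(unname(fit$alpha), unname(ols), tolerance = 1e-8)
  # with V = I only tau + phi is identified; the total must match the
  # REML residual variance
  s2 <- sum(qr.resid(qr(X), y)^2) / (n - ncol(X))
  expect_equal(fit$tau + fit$phi, s2, tolerance = 1e-6)
  # score P equals the ordinary GLM score test
  g <- rnorm(n)
  ours <- score_test_snp(pmin(pmax(round(g - min(g)), 0), 2), fit)$P
  g2 <- pmin(pmax(round(g - min(g)), 0), 2)
  expect_equal(ours, glm_score_oracle(y, X, g2, gaussian()),
               tolerance = 1e-6)
})

test_that("binomial tau = 0 boundary fit reproduces the GLM score test", {
  set.seed(13)  # a null draw whose REML solution sits at the boundary
  n <- 150
  X <- cbind(1, rnorm(n))
  y <- rbinom(n, 1, 0.5)
  fit <- fit_null_glmm(y, X, glmm_V, family = "binomial")
  expect_identical(fit$tau, 0)
  expect_true(fit$boundary)
  set.seed(101)
  for (i in 1:5) {
    g <- rbinom(n, 2, 0.3)
    expect_equal(score_test_snp(g, fit)$P,
                 glm_score_oracle(y, X, g, binomial()), tolerance = 1e-5)
  }
})

test_that("a dosage lying in the covariate span is annihilated by the
           projection", {
  set.seed(21)
  n <- 150
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(0.5, 0.3)) + rnorm(n)
  fit <- fit_null_glmm(y, X, glmm_V, family = "gaussian")
  res <- sgwas:::score_test_matrix(matrix(2 * X[, 1], ncol = 1), fit)
  # constant dosage is monomorphic -> NA with a reason, never a crash
  expect_true(is.na(res$P))
  expect_equal(res$REASON, "monomorphic")
  # a non-constant column of X: score numerically zero, p near 1
  res2 <- sgwas:::score_test_matrix(matrix(X[, 2], ncol = 1), fit)
  expect_lt(res2$SCORE, 1e-10)
  expect_gt(res2$P, 1 - 1e-5)
})

test_that("score-test P-values are invariant to covariate reparameterization", {
  set.seed(33)
  n <- 150
  X <- cbind(1, matrix(rnorm(n * 3), n, 3))
  y <- rnorm(n) + 0.5 * X[, 2]
  A <- matrix(rnorm(16), 4, 4) + diag(4) * 2   # invertible
  fit1 <- fit_null_glmm(y, X, glmm_V, family = "gaussian")
  fit2 <- fit_null_glmm(y, X %*% A, glmm_V, family = "gaussian")
  G <- matrix(rbinom(n * 8, 2, 0.3), n, 8)
  p1 <- sgwas:::score_test_matrix(G, fit1)$P
  p2 <- sgwas:::score_test_matrix(G, fit2)$P
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("gaussian REML solution attains the grid-search optimum of the
           closed-form restricted likelihood", {
  set.seed(5)
  n <- 20
  V <- glmm_V[1:n, 1:n]
  diag(V) <- 1
  X <- cbind(1, rnorm(n))
  ev <- eigen(V, symmetric = TRUE)
  b <- drop(ev$vectors %*% (sqrt(pmax(ev$values, 0)) * rnorm(n)))
  y <- drop(X %*% c(1, 0.5)) + b * sqrt(0.6) + rnorm(n, sd = sqrt(0.4))
  fit <- fit_null_glmm(y, X, V, family = "gaussian")
  grid <- expand.grid(tau = seq(0.01, 3, length.out = 50),
                      phi = seq(0.05, 3, length.out = 50))
  grid_best <- max(vapply(seq_len(nrow(grid)), function(i)
    reml_logl_gaussian(y, X, V, grid$tau[i], grid$phi[i]), numeric(1)))
  fitted_logl <- reml_logl_gaussian(y, X, V, fit$tau, fit$phi)
  expect_gte(fitted_logl + 1e-6, grid_best)
  # and the logl the fitter reports matches the closed form
  expect_equal(fit$logl_reml, fitted_logl, tolerance = 1e-6)
})

test_that("variance component is recovered on data simulated with known tau", {
  set.seed(64)
  n <- 200
  co <- simulate_cohort(sim_config(n_samples = n, n_snps = 10,
                                   total_snp_effect = 0, n_causal = 0,
                                   n_rois = 30, seed = 9))
  V <- co$similarity$matrix
  ev <- eigen(V, symmetric = TRUE)
  L <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  X <- cbind(1, rnorm(n))
  taus <- replicate(25, {
    y <- drop(X %*% c(1, 1)) + sqrt(0.5) * drop(L %*% rnorm(n)) +
      rnorm(n, sd = sqrt(0.5))
    fit_null_glmm(y, X, V, family = "gaussian")$tau
  })
  # wide unit-test bound; the tight recovery check runs at acceptance scale
  expect_lt(abs(mean(taus) - 0.5), 0.15)
})

test_that("conventional GWAS matches the closed-form simple regression on a
           6-point dataset and lm() in general", {
  # hand-checkable: y on g with intercept
  g <- c(0, 0, 1, 1, 2, 2)
  y <- c(0.1, -0.2, 0.5, 0.7, 1.1, 0.9)
  res <- conventional_gwas(matrix(g, ncol = 1), y, matrix(1, 6, 1),
                           family = "gaussian")
  ref <- summary(lm(y ~ g))$coefficients["g", ]
  expect_equal(res$BETA, unname(ref["Estimate"]), tolerance = 1e-10)
  expect_equal(res$SE, unname(ref["Std. Error"]), tolerance = 1e-10)
  expect_equal(res$P, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
  # multi-covariate agreement with lm across SNPs
  set.seed(7)
  n <- 80
  X <- cbind(1, matrix(rnorm(n * 2), n, 2))
  yy <- rnorm(n)
  G <- matrix(rbinom(n * 5, 2, 0.4), n, 5)
  out <- conventional_gwas(G, yy, X, family = "gaussian")
  for (j in 1:5) {
    rf <- summary(lm(yy ~ 0 + X + G[, j]))$coefficients
    expect_equal(out$BETA[j], unname(rf[nrow(rf), "Estimate"]),
                 tolerance = 1e-10)
    expect_equal(out$P[j], unname(rf[nrow(rf), "Pr(>|t|)"]),
                 tolerance = 1e-10)
  }
})

test_that("binomial conventional GWAS matches glm() Wald statistics", {
  set.seed(10)
  n <- 200
  X <- cbind(1, rnorm(n))
  y <- rbinom(n, 1, plogis(-0.3 + 0.5 * X[, 2]))
  G <- matrix(rbinom(n * 4, 2, 0.35), n, 4)
  out <- conventional_gwas(G, y, X, family = "binomial")
  for (j in 1:4) {
    rf <- summary(glm(y ~ 0 + X + G[, j], family = binomial()))$coefficients
    expect_equal(out$BETA[j], unname(rf[nrow(rf), "Estimate"]),
                 tolerance = 1e-6)
    expect_equal(out$P[j], unname(rf[nrow(rf), "Pr(>|z|)"]),
                 tolerance = 1e-6)
  }
})

test_that("permuted phenotypes give uniform conventional-GWAS P-values", {
  set.seed(12)
  n <- 300
  X <- matrix(1, n, 1)
  y <- sample(rnorm(n))
  G <- matrix(rbinom(n * 1000, 2, runif(1000, 0.1, 0.5)[rep(1:1000, each = n)]),
              n, 1000)
  p <- conventional_gwas(G, y, X, family = "gaussian")$P
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("run_assoc aligns samples, annotates tiers and reports lambda_GC", {
  co <- simulate_cohort(sim_config(n_samples = 250, n_snps = 60,
                                   n_causal = 12, total_snp_effect = 0.6,
                                   n_rois = 30, seed = 77))
  X <- cbind(1, co$covariates)
  res <- run_assoc(co$genotypes, co$phenotype, X, co$similarity,
                   family = "gaussian", thresholds = c(5e-8, 1e-5))
  expect_s3_class(res, "sgwas_assoc")
  expect_equal(nrow(res), 60L)
  expect_true(all(res$P > 0 & res$P <= 1, na.rm = TRUE))
  expect_true(is.finite(attr(res, "lambda_gc")))
  # tier annotation equals a hand filter
  expect_equal(sum(res$TIER == "5e-08", na.rm = TRUE), sum(res$P < 5e-8))
  # strong signal: causal variants enriched among the smallest P-values
  # (standard-normal effect sizes leave some causal SNPs undetectable, so the
  # ceiling is well below 1 even at high total SNP effect)
  auc <- auc_score(co$causal_mask[match(res$id, co$genotypes$variants$id)],
                   -log10(res$P))
  expect_gt(auc, 0.65)
  expect_gt(mean(-log10(res$P[co$causal_mask])),
            2 * mean(-log10(res$P[!co$causal_mask])))
  # shuffled sample order in the genotype panel must not change results
  perm <- sample(co$genotypes$sample_ids)
  genop <- genotype_panel(co$genotypes$dosage[perm, ],
                          co$genotypes$variants, sample_ids = perm)
  res2 <- run_assoc(genop, co$phenotype, X, co$similarity,
                    family = "gaussian")
  expect_equal(res2$P, res$P, tolerance = 1e-8)
})
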