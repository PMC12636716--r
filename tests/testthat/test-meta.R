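test_that("fixed-effects meta matches hand-computed worked examples", {
  # single study: identity
  r1 <- fixed_effect_meta(0.2, 0.1)
  expect_equal(r1$beta, 0.2, tolerance = 1e-12)
  expect_equal(r1$var, 0.1^2, tolerance = 1e-12)
  # two studies: w = (100, 25), beta = 17.5/125, var = 1/125
  r2 <- fixed_effect_meta(c(0.1, 0.3), c(0.1, 0.2))
  expect_equal(r2$beta, 0.14, tolerance = 1e-12)
  expect_equal(r2$var, 0.008, tolerance = 1e-12)
  # k identical studies: replication law var = sigma^2 / k
  r3 <- fixed_effect_meta(rep(0.4, 5), rep(0.3, 5))
  expect_equal(r3$beta, 0.4, tolerance = 1e-12)
  expect_equal(r3$var, 0.3^2 / 5, tolerance = 1e-12)
  expect_error(fixed_effect_meta(numeric(0), numeric(0)), "at least")
  expect_error(fixed_effect_meta(c(0, 1), c(1, -1)), "study")
})

test_that("Cochran's Q and DerSimonian-Laird tau2 match hand evaluation", {
  q <- cochran_q(c(0, 2), c(1, 1))
  expect_equal(q$Q, 2, tolerance = 1e-12)
  expect_equal(q$df, 1L)
  # identical effects: exact homogeneity
  expect_equal(cochran_q(rep(0.7, 4), rep(0.2, 4))$Q, 0, tolerance = 1e-12)
  # permutation symmetry
  set.seed(1); b <- rnorm(6); s <- runif(6, .1, 1); o <- sample(6)
  expect_equal(cochran_q(b, s)$Q, cochran_q(b[o], s[o])$Q, tolerance = 1e-12)
  # DL: Q=2, k-1=1, denom = 2 - 2/2 = 1 -> tau2 = 1
  expect_equal(dersimonian_laird_tau2(c(0, 2), c(1, 1)), 1, tolerance = 1e-12)
  # max(0, .) branch: Q = 0.5 < 1 -> 0
  expect_identical(dersimonian_laird_tau2(c(0, 1), c(1, 1)), 0)
  expect_identical(dersimonian_laird_tau2(rep(0.3, 3), rep(0.5, 3)), 0)
})

test_that("random-effects meta continues the hand example and collapses when
           tau2 = 0", {
  r <- random_effect_meta(c(0, 2), c(1, 1))
  expect_equal(r$tau2, 1, tolerance = 1e-12)
  expect_equal(r$beta, 1, tolerance = 1e-12)
  expect_equal(r$var, 1, tolerance = 1e-12)
  # tau2 = 0 -> identical to fixed effects
  fx <- fixed_effect_meta(c(0, 1), c(1, 1))
  rd <- random_effect_meta(c(0, 1), c(1, 1))
  expect_equal(rd$beta, fx$beta, tolerance = 1e-15)
  expect_equal(rd$var, fx$var, tolerance = 1e-15)
  # a study with enormous SE has vanishing influence
  r0 <- fixed_effect_meta(c(0.1, 0.5), c(0.2, 0.3))
  r1 <- fixed_effect_meta(c(0.1, 0.5, 99), c(0.2, 0.3, 1e6))
  expect_equal(r1$beta, r0$beta, tolerance = 1e-9)
})

test_that("meta estimators agree with WLS oracle on 1000 random cases", {
  worst_f <- worst_r <- 0
  for (i in seq_len(1000)) {
    cs <- random_effects_case(k = sample(2:8, 1), seed = i)
    w <- 1 / cs$se^2
    # independent oracle: weighted least squares intercept-only fit
    fit <- lm(cs$beta ~ 1, weights = w)
    fx <- fixed_effect_meta(cs$beta, cs$se)
    worst_f <- max(worst_f, abs(fx$beta - unname(coef(fit)[1])))
    # random effects via the printed moment formula, recomputed independently
    bfix <- sum(w * cs$beta) / sum(w)
    Q <- sum(w * (cs$beta - bfix)^2)
    t2 <- max(0, (Q - (length(w) - 1)) / (sum(w) - sum(w^2) / sum(w)))
    ws <- 1 / (t2 + cs$se^2)
    fit_r <- lm(cs$beta ~ 1, weights = ws)
    rd <- random_effect_meta(cs$beta, cs$se)
    worst_r <- max(worst_r, abs(rd$beta - unname(coef(fit_r)[1])),
                   abs(rd$var - 1 / sum(ws)))
  }
  expect_lt(worst_f, 1e-10)
  expect_lt(worst_r, 1e-10)
})

test_that("meta estimators agree with metafor on random cases", {
  skip_if_not_installed("metafor")
  for (i in c(3, 17, 99)) {
    cs <- random_effects_case(k = 6, seed = i)
    fe <- suppressWarnings(metafor::rma(yi = cs$beta, sei = cs$se,
                                        method = "FE"))
    dl <- suppressWarnings(metafor::rma(yi = cs$beta, sei = cs$se,
                                        method = "DL"))
    expect_equal(fixed_effect_meta(cs$beta, cs$se)$beta,
                 unname(as.numeric(fe$beta)), tolerance = 1e-8)
    expect_equal(dersimonian_laird_tau2(cs$beta, cs$se),
                 unname(dl$tau2), tolerance = 1e-8)
    expect_equal(random_effect_meta(cs$beta, cs$se)$beta,
                 unname(as.numeric(dl$beta)), tolerance = 1e-8)
    expect_equal(cochran_q(cs$beta, cs$se)$Q, unname(dl$QE),
                 tolerance = 1e-8)
  }
})

test_that("meta invariants: bounds, monotone variance, scale equivariance", {
  set.seed(77)
  for (i in 1:50) {
    cs <- random_effects_case(k = sample(2:10, 1), seed = 1000 + i)
    fx <- fixed_effect_meta(cs$beta, cs$se)
    rd <- random_effect_meta(cs$beta, cs$se)
    expect_gte(fx$beta, min(cs$beta) - 1e-12)
    expect_lte(fx$beta, max(cs$beta) + 1e-12)
    expect_lte(fx$var, rd$var + 1e-15)
    # adding a study always shrinks the fixed-effects variance
    fx2 <- fixed_effect_meta(c(cs$beta, 0), c(cs$se, 1))
    expect_lt(fx2$var, fx$var)
    # scale equivariance: c * (beta, se) scales beta by c, tau2 by c^2
    cc <- 3.7
    expect_equal(fixed_effect_meta(cc * cs$beta, cc * cs$se)$beta,
                 cc * fx$beta, tolerance = 1e-10)
    expect_equal(dersimonian_laird_tau2(cc * cs$beta, cc * cs$se),
                 cc^2 * dersimonian_laird_tau2(cs$beta, cs$se),
                 tolerance = 1e-8)
  }
})

make_study <- function(chr, pos, a1, a2, beta, se, n = 1000) {
  data.frame(CHR = chr, POS = pos, SNP = paste0("rs", pos), A1 = a1, A2 = a2,
             BETA = beta, SE = se, P = 0.5, N = n, stringsAsFactors = FALSE)
}

test_that("harmonization flips swapped alleles and drops palindromic SNPs", {
  primary <- make_study(1, c(100, 200, 300), c("A", "A", "C"),
                        c("G", "T", "G"), c(0.2, 0.1, 0.3), c(0.1, 0.1, 0.1))
  ext <- make_study(1, c(100, 200, 300), c("G", "A", "C"), c("A", "T", "G"),
                    c(-0.1, 0.5, 0.25), c(0.15, 0.2, 0.12))
  h <- harmonize_studies(primary, list(ext1 = ext))
  eff <- h$effects[h$effects$study == "ext1", ]
  # swapped A1/A2 at pos 100: sign flip -0.1 -> +0.1
  expect_equal(eff$BETA[eff$ref_index == 1], 0.1)
  # A/T (pos 200) and C/G (pos 300) are strand-ambiguous: dropped and counted
  expect_false(2 %in% eff$ref_index)
  expect_false(3 %in% eff$ref_index)
  expect_equal(h$log$n_palindromic_dropped, 2L)
  expect_equal(h$log$n_matched, 1L)
})

test_that("three-study toy table groups and models as hand-matched", {
  primary <- make_study(1, c(100, 200), "A", "G", c(0.2, -0.1), c(0.1, 0.05))
  s1 <- make_study(1, 100, "A", "G", 0.25, 0.12)        # matches variant 1
  s2 <- make_study(1, c(100, 999), "A", "G", c(0.15, 1), c(0.2, 0.2))
  h <- harmonize_studies(primary, list(a = s1, b = s2))
  res <- meta_analyze(h)
  expect_equal(res$K, c(3L, 1L))
  expect_equal(res$MODEL_USED[2], "single")
  # k = 1 row carries the single study's estimate through
  expect_equal(res$BETA_FIXED[2], -0.1)
  expect_equal(res$SE_FIXED[2], 0.05)
  # k = 3 fixed estimate equals the direct computation
  b <- c(0.2, 0.25, 0.15); s <- c(0.1, 0.12, 0.2)
  expect_equal(res$BETA_FIXED[1], sum(b / s^2) / sum(1 / s^2),
               tolerance = 1e-12)
  expect_true(res$MODEL_USED[1] %in% c("fixed", "random"))
})
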