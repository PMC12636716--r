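#' Simulation configuration
#'
#' Study design for the synthetic cohorts used to benchmark the spatial GLMM
#' against conventional per-SNP regression: 1,000 individuals, 100 SNPs (20
#' causal), 6 covariates and 100 brain ROIs by default. The phenotype is a
#' unit-variance liability composed of four independent parts: a genetic
#' component carrying a fraction `total_snp_effect` (theta) of the variance,
#' and a brain random effect, covariate effect and iid noise splitting the
#' remaining `1 - theta` according to the three `*_share` fractions.
#'
#' Each individual's 100 ROI activities have mean `phi_i ~ Uniform(0, 1)` and
#' variance `roi_variance` (default 10). The deviations around `phi_i` mix a
#' set of cohort-level latent activity patterns (individual loadings on the
#' unit sphere) with idiosyncratic noise; `profile_shared_frac` is the shared
#' fraction, which is what gives different individuals genuinely similar or
#' dissimilar brain interaction profiles (see the methods vignette).
#'
#' @param n_samples,n_snps,n_causal,n_covariates,n_rois Cohort dimensions.
#' @param total_snp_effect Fraction theta of phenotypic variance carried by
#'   the causal SNPs jointly, in `[0, 1)`.
#' @param brain_effect_share,covariate_share,noise_share Fractions of
#'   `1 - theta` given to the brain random effect, covariates and noise; must
#'   sum to 1.
#' @param roi_mean_range Range of the per-sample ROI mean `phi_i`.
#' @param roi_variance Variance of ROI activities around `phi_i`.
#' @param n_latent_patterns,profile_shared_frac Latent-structure parameters of
#'   the ROI deviations (see Details).
#' @param maf_range Allele-frequency range for simulated SNPs.
#' @param binary Also produce a liability-threshold binary phenotype.
#' @param prevalence Case fraction for the binary phenotype.
#' @param seed Integer seed; every draw in [simulate_cohort()] flows from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 1000L, n_snps = 100L, n_causal = 20L,
                       n_covariates = 6L, n_rois = 100L,
                       total_snp_effect = 0.05,
                       brain_effect_share = 0.5, covariate_share = 0.25,
                       noise_share = 0.25,
                       roi_mean_range = c(0, 1), roi_variance = 10,
                       n_latent_patterns = 5L, profile_shared_frac = 0.8,
                       maf_range = c(0.05, 0.5),
                       binary = FALSE, prevalence = 0.5, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
              n_causal = as.integer(n_causal),
              n_covariates = as.integer(n_covariates),
              n_rois = as.integer(n_rois),
              total_snp_effect = total_snp_effect,
              brain_effect_share = brain_effect_share,
              covariate_share = covariate_share, noise_share = noise_share,
              roi_mean_range = roi_mean_range, roi_variance = roi_variance,
              n_latent_patterns = as.integer(n_latent_patterns),
              profile_shared_frac = profile_shared_frac,
              maf_range = maf_range, binary = isTRUE(binary),
              prevalence = prevalence, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_causal > n_snps) stop("n_causal must not exceed n_snps")
    if (total_snp_effect < 0 || total_snp_effect >= 1)
      stop("total_snp_effect must lie in [0, 1)")
    shares <- brain_effect_share + covariate_share + noise_share
    if (abs(shares - 1) > 1e-12)
      stop("brain_effect_share + covariate_share + noise_share must equal 1 ",
           "(got ", shares, ")")
    if (roi_variance <= 0) stop("roi_variance must be positive")
    if (profile_shared_frac < 0 || profile_shared_frac > 1)
      stop("profile_shared_frac must lie in [0, 1]")
    if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
      stop("maf_range must satisfy 0 < lower <= upper <= 0.5")
    if (n_rois < 2) stop("need at least 2 ROIs")
  })
  invisible(cfg)
}

# center and rescale a component to an exact variance share (0 -> zero vector)
scale_component <- function(x, share) {
  if (share == 0) return(numeric(length(x)))
  s <- stats::sd(x)
  if (s == 0) stop("degenerate (constant) phenotype component")
  (x - mean(x)) / s * sqrt(share)
}

#' Simulate a benchmark cohort
#'
#' Draws genotypes, covariates, individualized ROI activity profiles and a
#' phenotype under the design of [sim_config()]. The brain random effect is
#' drawn from a multivariate normal whose correlation is the spatial-kernel
#' similarity matrix computed from the simulated ROI activities by the
#' package's own pipeline ([build_similarity()]), so the ground-truth
#' covariance and the matrix the GLMM is given coincide. Causal effect sizes
#' are standard normal, rescaled jointly so the genetic component carries
#' exactly its variance share.
#'
#' @param config A [sim_config()].
#' @return Object of class `sgwas_cohort`: `genotypes` ([genotype_panel()]),
#'   `covariates`, `roi_values`, `phenotype` (quantitative liability),
#'   `phenotype_binary` (if requested), `causal_mask`, `true_effects`,
#'   `similarity` (`sgwas_similarity`) and the `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  n <- cfg$n_samples; p <- cfg$n_snps; m <- cfg$n_rois
  sample_ids <- sprintf("sim%04d", seq_len(n))

  # genotypes: Binomial(2, maf) per SNP, monomorphic draws resampled
  maf <- stats::runif(p, cfg$maf_range[1], cfg$maf_range[2])
  G <- matrix(stats::rbinom(n * p, 2L, rep(maf, each = n)), n, p)
  for (tries in 1:10) {
    mono <- which(apply(G, 2L, function(g) length(unique(g))) == 1L)
    if (!length(mono)) break
    G[, mono] <- stats::rbinom(n * length(mono), 2L,
                               rep(maf[mono], each = n))
  }
  if (length(mono <- which(apply(G, 2L, stats::var) == 0)))
    stop("monomorphic SNP draw persisted after 10 resampling attempts ",
         "(SNPs ", paste(mono, collapse = ", "), "); increase n_samples or maf")
  variants <- data.frame(chrom = 1L, pos = seq_len(p) * 10000L,
                         id = sprintf("snp%03d", seq_len(p)),
                         A1 = "A", A2 = "G", af = colMeans(G) / 2,
                         stringsAsFactors = FALSE)
  geno <- genotype_panel(G, variants, sample_ids)

  # covariates
  Z <- matrix(stats::rnorm(n * cfg$n_covariates), n, cfg$n_covariates,
              dimnames = list(sample_ids,
                              paste0("covar", seq_len(cfg$n_covariates))))

  # ROI activities: mean phi_i, variance roi_variance; deviations share
  # latent cohort-level patterns in proportion profile_shared_frac
  phi <- stats::runif(n, cfg$roi_mean_range[1], cfg$roi_mean_range[2])
  K <- cfg$n_latent_patterns
  # latent cohort-level activity patterns, centered and scaled per pattern so
  # individual profile means stay at phi_i and the deviation variance at 1
  A <- scale(matrix(stats::rnorm(m * K), m, K))
  W <- abs(matrix(stats::rnorm(n * K), n, K))
  W <- W / sqrt(rowSums(W^2))
  c_sh <- cfg$profile_shared_frac
  dev <- sqrt(c_sh) * tcrossprod(W, A) +
    sqrt(1 - c_sh) * matrix(stats::rnorm(n * m), n, m)
  roi_values <- phi + sqrt(cfg$roi_variance) * dev
  dimnames(roi_values) <- list(sample_ids, sprintf("roi%03d", seq_len(m)))

  # ground-truth similarity via the package's own kernel pipeline
  panel <- roi_panel(roi_values,
                     data.frame(roi = colnames(roi_values),
                                modality = "sim", feature = "activity",
                                stringsAsFactors = FALSE),
                     sample_ids = sample_ids, roi_ids = colnames(roi_values))
  V <- build_similarity(panel)

  # phenotype components, each rescaled to its exact variance share
  theta <- cfg$total_snp_effect
  causal_idx <- sort(sample.int(p, cfg$n_causal))
  causal_mask <- seq_len(p) %in% causal_idx
  beta_raw <- stats::rnorm(cfg$n_causal)
  g_raw <- drop(G[, causal_idx, drop = FALSE] %*% beta_raw)
  g_comp <- scale_component(g_raw, theta)
  scale_factor <- if (theta > 0) sqrt(theta) / stats::sd(g_raw) else 0
  true_effects <- numeric(p)
  true_effects[causal_idx] <- beta_raw * scale_factor

  cov_comp <- scale_component(drop(Z %*% stats::rnorm(cfg$n_covariates)),
                              cfg$covariate_share * (1 - theta))
  ev <- V$eigen
  b_raw <- drop(ev$vectors %*% (sqrt(pmax(ev$values, 0)) * stats::rnorm(n)))
  b_comp <- scale_component(b_raw, cfg$brain_effect_share * (1 - theta))
  e_comp <- scale_component(stats::rnorm(n), cfg$noise_share * (1 - theta))

  y <- g_comp + cov_comp + b_comp + e_comp
  names(y) <- sample_ids
  out <- list(genotypes = geno, covariates = Z, roi_values = roi_values,
              phenotype = y, causal_mask = causal_mask,
              true_effects = true_effects,
              components = cbind(genetic = g_comp, covariate = cov_comp,
                                 brain = b_comp, noise = e_comp),
              similarity = V, config = cfg)
  if (cfg$binary) {
    thr <- stats::quantile(y, 1 - cfg$prevalence)
    out$phenotype_binary <- as.integer(y > thr)
    names(out$phenotype_binary) <- sample_ids
  }
  structure(out, class = "sgwas_cohort")
}

#' @export
print.sgwas_cohort <- function(x, ...) {
  cfg <- x$config
  cat("Simulated cohort:", cfg$n_samples, "samples,", cfg$n_snps, "SNPs (",
      cfg$n_causal, "causal ),", cfg$n_covariates, "covariates,",
      cfg$n_rois, "ROIs\n")
  cat("  total SNP effect theta =", cfg$total_snp_effect, "\n")
  invisible(x)
}

#' Area under the ROC curve for ranking causal SNPs
#'
#' Midrank (Wilcoxon) AUROC of `scores` for the binary `labels`; ties receive
#' midranks, so exchangeable scores give 0.5 in expectation.
#'
#' @param labels Logical or 0/1 vector (TRUE = causal).
#' @param scores Numeric ranking scores (higher = more likely causal).
#' @return AUROC in `[0, 1]`.
#' @export
auc_score <- function(labels, scores) {
  labels <- as.logical(labels)
  if (length(labels) != length(scores)) stop("labels/scores length mismatch")
  if (anyNA(scores) || anyNA(labels)) stop("NA in AUC inputs")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)                       # midranks for ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Benchmark the spatial GLMM against conventional GWAS
#'
#' Replicated simulation experiment: per replicate a fresh cohort is drawn
#' (child seed spawned from the master seed), each requested method is run
#' over all SNPs, and the AUROC for recovering the causal SNPs from
#' `-log10(P)` is recorded. Replicates on which a method fails are flagged and
#' excluded from the summary with the reason retained, never silently dropped.
#'
#' @param config A [sim_config()]; its `seed` is the master seed.
#' @param n_replicates Number of independent cohorts (the reference design
#'   uses 50).
#' @param methods Subset of `c("spatial_glmm", "conventional_glm")`.
#' @return Object of class `sgwas_benchmark`: `results` (replicate x method
#'   AUC table), `summary` (mean/sd per method), `failures`, `config`.
#' @export
benchmark_auc <- function(config = sim_config(), n_replicates = 50L,
                          methods = c("spatial_glmm", "conventional_glm")) {
  methods <- match.arg(methods, several.ok = TRUE)
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  rows <- list(); failures <- list()
  for (r in seq_len(n_replicates)) {
    cfg_r <- config
    cfg_r$seed <- child_seeds[r]
    cohort <- simulate_cohort(cfg_r)
    y <- cohort$phenotype
    X <- cbind(`(Intercept)` = 1, cohort$covariates)
    for (mth in methods) {
      auc <- tryCatch({
        p <- if (mth == "spatial_glmm") {
          fit <- fit_null_glmm(y, X, cohort$similarity, family = "gaussian")
          score_test_matrix(dosage_matrix(cohort$genotypes), fit)$P
        } else {
          conventional_gwas(cohort$genotypes, y, X, family = "gaussian")$P
        }
        if (anyNA(p)) stop("untestable SNP in replicate")
        auc_score(cohort$causal_mask, -log10(p))
      }, error = function(e) e)
      if (inherits(auc, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(replicate = r, method = mth,
                     reason = conditionMessage(auc),
                     stringsAsFactors = FALSE)
        auc <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, seed = child_seeds[r], method = mth,
        total_snp_effect = cfg$total_snp_effect, auc = auc,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  ok <- results[!is.na(results$auc), ]
  summary <- do.call(rbind, lapply(split(ok, ok$method), function(d)
    data.frame(method = d$method[1], n_replicates = nrow(d),
               mean_auc = mean(d$auc), sd_auc = stats::sd(d$auc),
               stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary,
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL,
                 config = cfg, n_replicates = n_replicates),
            class = "sgwas_benchmark")
}

#' @export
print.sgwas_benchmark <- function(x, ...) {
  cat("Causal-SNP recovery benchmark (", x$n_replicates, " replicates, theta = ",
      x$config$total_snp_effect, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$failures))
    cat("  failed method-replicates:", nrow(x$failures), "\n")
  invisible(x)
}

#' Benchmark sweep over total SNP effect values
#'
#' Runs [benchmark_auc()] at each value of `effects` (fresh master seed per
#' setting derived from `config$seed`) and stacks the per-replicate results.
#'
#' @inheritParams benchmark_auc
#' @param effects Vector of `total_snp_effect` values, e.g.
#'   `c(0.05, 0.2, 0.4, 0.8)`.
#' @return Data frame of per-replicate AUCs across settings with a
#'   `summary` attribute.
#' @export
benchmark_sweep <- function(config = sim_config(), effects = c(0.05, 0.2, 0.4, 0.8),
                            n_replicates = 50L,
                            methods = c("spatial_glmm", "conventional_glm")) {
  out <- lapply(seq_along(effects), function(i) {
    cfg <- config
    cfg$total_snp_effect <- effects[i]
    cfg$seed <- config$seed + i - 1L
    b <- benchmark_auc(cfg, n_replicates = n_replicates, methods = methods)
    list(results = b$results, summary = cbind(total_snp_effect = effects[i],
                                              b$summary))
  })
  res <- do.call(rbind, lapply(out, `[[`, "results"))
  attr(res, "summary") <- do.call(rbind, lapply(out, `[[`, "summary"))
  res
}
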