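# Independent reference implementations used as oracles. These deliberately
# use naive loops / textbook formulas and share no code with the package.

# full spatial-kernel pipeline, nested loops: raw ROI values (n x m, one
# activity per ROI), optional coords (m x 3), explicit z-scoring, RBF kernel
# over lexicographic pairs, textbook Pearson correlation. No PSD repair.
naive_similarity <- function(values, coords = NULL, sigma, lambda = 1) {
  n <- nrow(values); m <- ncol(values)
  zs <- function(x) {
    s <- sd(x)
    if (s == 0) return(x - mean(x))
    (x - mean(x)) / s
  }
  Z <- apply(values, 2, zs)
  C <- if (!is.null(coords)) apply(coords, 2, zs) else NULL
  profiles <- matrix(NA_real_, n, m * (m - 1) / 2)
  for (i in seq_len(n)) {
    idx <- 0
    for (k in seq_len(m - 1)) for (l in (k + 1):m) {
      idx <- idx + 1
      sk <- Z[i, k]; sl <- Z[i, l]
      if (!is.null(C)) {
        sk <- c(sk, lambda * C[k, ]); sl <- c(sl, lambda * C[l, ])
      }
      profiles[i, idx] <- exp(-sum((sk - sl)^2) / (2 * sigma^2))
    }
  }
  V <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- profiles[i, ]; b <- profiles[j, ]
    r <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    V[i, j] <- V[j, i] <- r
  }
  list(profiles = profiles, V = V)
}

# closed-form gaussian restricted log-likelihood of y ~ X with
# Var = tau * V + phi * I (same constant convention as the fitter)
reml_logl_gaussian <- function(y, X, V, tau, phi) {
  Sigma <- tau * V + diag(phi, length(y))
  Si <- solve(Sigma)
  XtSiX <- t(X) %*% Si %*% X
  a <- solve(XtSiX, t(X) %*% Si %*% y)
  r <- y - X %*% a
  -0.5 * (determinant(Sigma, logarithm = TRUE)$modulus[1] +
            determinant(XtSiX, logarithm = TRUE)$modulus[1] +
            drop(t(r) %*% Si %*% r))
}

# ordinary GLM score test of adding g to a fitted null glm (dispersion from
# the null model for gaussian, 1 for binomial)
glm_score_oracle <- function(y, X, g, family) {
  fit0 <- glm.fit(X, y, family = family)
  mu <- fit0$fitted.values
  w <- fit0$weights             # IRLS weights = variance weights at the null
  phi <- if (family$family == "gaussian")
    sum((y - mu)^2) / (length(y) - ncol(X)) else 1
  U <- sum(g * (y - mu)) / phi
  gw <- g * w
  v <- (sum(g * gw) - t(gw) %*% X %*% solve(t(X) %*% (X * w), t(X) %*% gw)) / phi
  stat <- U^2 / drop(v)
  pchisq(stat, 1, lower.tail = FALSE)
}

# tiny deterministic genotype panel builder
toy_panel <- function(dosage, chrom = 1L) {
  p <- ncol(dosage)
  genotype_panel(dosage,
                 data.frame(chrom = chrom, pos = seq_len(p) * 100L,
                            id = paste0("rs", seq_len(p)),
                            A1 = "A", A2 = "G", stringsAsFactors = FALSE))
}

# minimal single-sample-block VCF writer for round-trip tests
write_mini_vcf <- function(path, dosage, chrom = 1L, pos = NULL,
                           ref = "G", alt = "A") {
  n <- nrow(dosage); p <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(p) * 100L
  gtmap <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(dosage) %||%
                       paste0("s", seq_len(n))), collapse = "\t"))
  for (j in seq_len(p)) {
    gt <- ifelse(is.na(dosage[, j]), "./.", gtmap[as.character(dosage[, j])])
    lines <- c(lines, paste(c(chrom, pos[j], paste0("rs", j), ref, alt, ".",
                              "PASS", ".", "GT", gt), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random meta-analysis study sets for oracle sweeps
random_effects_case <- function(k, seed) {
  set.seed(seed)
  list(beta = rnorm(k), se = runif(k, 0.05, 2))
}
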