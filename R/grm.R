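#' Genetic relationship matrix
#'
#' Standardized-genotype cross-product
#' `G_ij = (1/M) * sum_m (x_im - 2 p_m)(x_jm - 2 p_m) / (2 p_m (1 - p_m))`
#' with `p_m` the sample allele frequency. Missing dosages are mean-imputed
#' before standardization; monomorphic variants are skipped with a count.
#'
#' @param genotypes A [genotype_panel()] or dosage matrix.
#' @return Object of class `sgwas_grm`: `matrix` (n x n), `n_variants` used,
#'   `n_skipped` monomorphic, `sample_ids`.
#' @export
compute_grm <- function(genotypes) {
  X <- dosage_matrix(genotypes)
  if (ncol(X) < 1L) stop("at least one variant is required")
  cm <- colMeans(X, na.rm = TRUE)
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- cm[idx[, 2L]]
  }
  p <- cm / 2
  poly <- p > 0 & p < 1
  n_skipped <- sum(!poly)
  if (!any(poly)) stop("all variants are monomorphic")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  S <- sweep(X, 2L, 2 * p, "-")
  S <- sweep(S, 2L, sqrt(2 * p * (1 - p)), "/")
  M <- ncol(S)
  G <- tcrossprod(S) / M
  structure(list(matrix = G, n_variants = M, n_skipped = n_skipped,
                 sample_ids = rownames(X)),
            class = "sgwas_grm")
}

#' @export
print.sgwas_grm <- function(x, ...) {
  cat("GRM:", nrow(x$matrix), "samples,", x$n_variants, "variants",
      if (x$n_skipped) paste0("(", x$n_skipped, " monomorphic skipped)"), "\n")
  cat("  mean diagonal:", signif(mean(diag(x$matrix)), 4), "\n")
  invisible(x)
}

#' @export
as.matrix.sgwas_grm <- function(x, ...) x$matrix

# AI-REML for Var(y) = sg2 * G + se2 * I in the eigenbasis of G, where the
# covariance is diagonal and every quantity is O(n q^2). EM-style fallback
# steps when the AI update leaves the parameter space; components clamped >= 0
# (with a small positive floor on se2 for numerical stability).
reml_two_component <- function(yr, Xr, lam, tol = 1e-6, maxit = 100L) {
  n <- length(yr)
  q <- ncol(Xr)
  vy <- stats::var(yr)
  th <- c(sg2 = vy / 2, se2 = vy / 2)
  floor_se <- 1e-8 * vy
  logl_fun <- function(th) {
    d <- th[1] * lam + th[2]
    if (any(d <= 0)) return(-Inf)
    Xd <- Xr / d
    XtX <- crossprod(Xr, Xd)
    a <- solve(XtX, crossprod(Xd, yr))
    r <- yr - Xr %*% a
    -0.5 * (sum(log(d)) + determinant(XtX, logarithm = TRUE)$modulus +
              sum(r^2 / d))
  }
  logl <- -Inf
  for (it in seq_len(maxit)) {
    d <- th[1] * lam + th[2]
    Xd <- Xr / d
    XtX_inv <- solve(crossprod(Xr, Xd))
    a <- XtX_inv %*% crossprod(Xd, yr)
    Py <- (yr - drop(Xr %*% a)) / d
    # tr(P D_i): D_1 = diag(lam), D_2 = I
    trP <- function(w) sum(w / d) - sum(XtX_inv * crossprod(Xd, Xd * w))
    tr1 <- trP(lam); tr2 <- trP(rep(1, n))
    lPy <- lam * Py; iPy <- Py
    # P v = D^{-1} v - D^{-1} X (X'D^{-1}X)^{-1} X' D^{-1} v
    Pv <- function(v) v / d - drop(Xd %*% (XtX_inv %*% crossprod(Xd, v)))
    P_l <- Pv(lPy); P_i <- Pv(iPy)
    score <- -0.5 * c(tr1 - sum(Py * lPy), tr2 - sum(Py * iPy))
    AI <- 0.5 * matrix(c(sum(lPy * P_l), sum(lPy * P_i),
                         sum(lPy * P_i), sum(iPy * P_i)), 2L)
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    new <- th + if (is.null(step)) rep(NA_real_, 2) else step
    if (is.null(step) || any(!is.finite(new)) ||
        logl_fun(pmax(new, c(0, floor_se))) < logl - 1e-8) {
      new <- th + th^2 * score * (2 / n)   # damped EM-style step
    }
    th_new <- pmax(new, c(0, floor_se))
    logl_new <- logl_fun(th_new)
    conv <- abs(logl_new - logl) < tol && it > 1L
    th <- th_new; logl <- logl_new
    if (conv) break
  }
  boundary <- th[1] == 0 || th[2] <= floor_se
  # observed AI at the optimum for the delta-method SE
  d <- th[1] * lam + th[2]
  Xd <- Xr / d
  XtX_inv <- solve(crossprod(Xr, Xd))
  a <- XtX_inv %*% crossprod(Xd, yr)
  Py <- (yr - drop(Xr %*% a)) / d
  Pv <- function(v) v / d - drop(Xd %*% (XtX_inv %*% crossprod(Xd, v)))
  lPy <- lam * Py; iPy <- Py
  AI <- 0.5 * matrix(c(sum(lPy * Pv(lPy)), sum(lPy * Pv(iPy)),
                       sum(lPy * Pv(iPy)), sum(iPy * Pv(iPy))), 2L)
  list(sg2 = unname(th[1]), se2 = unname(th[2]), logl = as.numeric(logl),
       AI = AI, iterations = it, converged = it < maxit || conv,
       boundary = boundary)
}

#' REML estimate of SNP heritability
#'
#' Fits `y = X beta + u + e` with `u ~ MVN(0, sg2 * G)` and
#' `e ~ MVN(0, se2 * I)` by AI-REML (EM-style fallback steps, components
#' clamped at zero) in the eigenbasis of the GRM, and reports
#' `h2 = sg2 / (sg2 + se2)` with a delta-method standard error from the
#' average-information matrix. A likelihood-ratio test against `sg2 = 0` uses
#' the boundary-corrected `0.5 chi2_0 + 0.5 chi2_1` mixture.
#'
#' @param y Trait vector.
#' @param X Covariate matrix including an intercept.
#' @param grm An [compute_grm()] result, a plain matrix, or a precomputed
#'   eigendecomposition (`list(values, vectors)`), which lets a scan over many
#'   traits decompose the GRM once.
#' @param tol REML convergence tolerance on the restricted log-likelihood.
#' @return Object of class `sgwas_h2`: `sigma2_g`, `sigma2_e`, `h2`, `se_h2`,
#'   `logl_reml`, `logl_null`, `lrt`, `p_lrt`, `converged`, `boundary`.
#' @export
estimate_h2 <- function(y, X = matrix(1, length(y), 1), grm, tol = 1e-6) {
  X <- as.matrix(X)
  ev <- if (inherits(grm, "sgwas_grm")) eigen(grm$matrix, symmetric = TRUE)
        else if (is.list(grm) && all(c("values", "vectors") %in% names(grm))) grm
        else eigen(as.matrix(grm), symmetric = TRUE)
  if (length(y) != nrow(ev$vectors)) stop("y and GRM dimensions disagree")
  yr <- drop(crossprod(ev$vectors, y))
  Xr <- crossprod(ev$vectors, X)
  fit <- reml_two_component(yr, Xr, pmax(ev$values, 0), tol = tol)
  tot <- fit$sg2 + fit$se2
  h2 <- fit$sg2 / tot
  # delta method: grad h2 = (se2, -sg2) / tot^2 ; cov(theta) ~ AI^{-1}
  se_h2 <- NA_real_
  covth <- tryCatch(solve(fit$AI), error = function(e) NULL)
  if (!is.null(covth)) {
    gr <- c(fit$se2, -fit$sg2) / tot^2
    v <- drop(t(gr) %*% covth %*% gr)
    if (is.finite(v) && v >= 0) se_h2 <- sqrt(v)
  }
  # null model sg2 = 0: closed-form restricted likelihood
  qx <- qr(Xr)
  r0 <- qr.resid(qx, yr)
  n <- length(yr); q <- ncol(Xr)
  se2_0 <- sum(r0^2) / (n - q)
  logl0 <- -0.5 * (n * log(se2_0) +
                     determinant(crossprod(Xr) / se2_0,
                                 logarithm = TRUE)$modulus +
                     sum(r0^2) / se2_0)
  lrt <- max(0, 2 * (fit$logl - as.numeric(logl0)))
  p_lrt <- 0.5 * (lrt <= 0) + 0.5 * stats::pchisq(lrt, df = 1L,
                                                  lower.tail = FALSE)
  structure(list(sigma2_g = fit$sg2, sigma2_e = fit$se2, h2 = h2,
                 se_h2 = se_h2, logl_reml = fit$logl,
                 logl_null = as.numeric(logl0), lrt = lrt, p_lrt = p_lrt,
                 converged = fit$converged, boundary = fit$boundary,
                 iterations = fit$iterations),
            class = "sgwas_h2")
}

#' @export
print.sgwas_h2 <- function(x, ...) {
  cat(sprintf("SNP heritability: h2 = %.4f (SE %.4f)\n", x$h2, x$se_h2))
  cat(sprintf("  sigma2_g = %.4g, sigma2_e = %.4g, REML logL = %.4f\n",
              x$sigma2_g, x$sigma2_e, x$logl_reml))
  cat(sprintf("  LRT vs h2=0: %.3f, P = %.3g%s\n", x$lrt, x$p_lrt,
              if (x$boundary) " (boundary estimate; SE approximate)" else ""))
  invisible(x)
}

#' Heritability scan over a trait table
#'
#' [estimate_h2()] per trait column, decomposing the GRM once. Per-trait
#' failures are isolated (recorded as NA rows with the error message) and the
#' scan continues.
#'
#' @param traits Numeric samples x traits matrix (column names = trait ids).
#' @param X Covariate matrix including intercept.
#' @param grm See [estimate_h2()].
#' @param alpha Significance threshold on the boundary-mixture LRT P-value
#'   (default 1e-5, the screening level used for imaging phenotypes).
#' @return Data frame with one row per trait: `trait, h2, se_h2, sigma2_g,
#'   sigma2_e, lrt, p, significant, converged, error`.
#' @export
h2_scan <- function(traits, X = NULL, grm, alpha = 1e-5) {
  traits <- as.matrix(traits)
  if (is.null(colnames(traits)))
    colnames(traits) <- paste0("trait", seq_len(ncol(traits)))
  if (is.null(X)) X <- matrix(1, nrow(traits), 1)
  ev <- if (inherits(grm, "sgwas_grm")) eigen(grm$matrix, symmetric = TRUE)
        else if (is.list(grm) && all(c("values", "vectors") %in% names(grm))) grm
        else eigen(as.matrix(grm), symmetric = TRUE)
  rows <- lapply(colnames(traits), function(tr) {
    res <- tryCatch(estimate_h2(traits[, tr], X, ev), error = function(e) e)
    if (inherits(res, "error"))
      data.frame(trait = tr, h2 = NA_real_, se_h2 = NA_real_,
                 sigma2_g = NA_real_, sigma2_e = NA_real_, lrt = NA_real_,
                 p = NA_real_, significant = NA, converged = FALSE,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    else
      data.frame(trait = tr, h2 = res$h2, se_h2 = res$se_h2,
                 sigma2_g = res$sigma2_g, sigma2_e = res$sigma2_e,
                 lrt = res$lrt, p = res$p_lrt,
                 significant = res$p_lrt < alpha, converged = res$converged,
                 error = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
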