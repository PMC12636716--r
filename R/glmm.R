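#' Family specification for the spatial GLMM
#'
#' Wraps a GLM family with the pieces the mixed-model fitter needs: link
#' `g(.)`, variance function `nu(.)`, and whether the dispersion `phi` is
#' estimated (gaussian) or fixed at 1 (binomial).
#'
#' @param family `"gaussian"` (identity link) or `"binomial"` (logit link), or
#'   a `stats::family` object of one of those families.
#' @return Object of class `sgwas_family`.
#' @export
sgwas_family <- function(family = c("gaussian", "binomial")) {
  if (inherits(family, "sgwas_family")) return(family)
  if (is.function(family)) family <- family()
  if (!inherits(family, "family"))
    family <- switch(match.arg(family),
                     gaussian = stats::gaussian(),
                     binomial = stats::binomial())
  if (!family$family %in% c("gaussian", "binomial"))
    stop("only gaussian and binomial families are supported")
  structure(list(family = family,
                 estimate_dispersion = family$family == "gaussian"),
            class = "sgwas_family")
}

# ---- restricted likelihood machinery on Sigma = phi * A + tau * V ----------
# A = diag(1/W) from the working weights; all quantities on the working scale.

# Cholesky-based projections; returns pieces reused by scores, AI and the
# score test: Sigma^{-1}, Sigma^{-1} X, (X' Sigma^{-1} X)^{-1}, P z, REML logL.
reml_pieces <- function(z, X, Sigma) {
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Si <- chol2inv(R)
  SiX <- Si %*% X
  XtSiX <- crossprod(X, SiX)
  cX <- tryCatch(chol(XtSiX), error = function(e) NULL)
  if (is.null(cX)) return(NULL)
  XtSiX_inv <- chol2inv(cX)
  Siz <- Si %*% z
  alpha <- XtSiX_inv %*% crossprod(SiX, z)
  Pz <- Siz - SiX %*% (XtSiX_inv %*% crossprod(X, Siz))
  logdet_Sigma <- 2 * sum(log(diag(R)))
  logdet_XtSiX <- 2 * sum(log(diag(cX)))
  logl <- -0.5 * (logdet_Sigma + logdet_XtSiX + sum(z * Pz))
  list(Si = Si, SiX = SiX, XtSiX_inv = XtSiX_inv, alpha = drop(alpha),
       Pz = drop(Pz), logl = logl)
}

# tr(P B) for symmetric B, using the pieces above.
trace_PB <- function(pieces, B) {
  SiB <- pieces$Si %*% B
  sum(diag(SiB)) - sum(pieces$XtSiX_inv * crossprod(pieces$SiX, B %*% pieces$SiX))
}

# tr(P diag(a)) without forming the diagonal matrix
trace_P_diag <- function(pieces, a) {
  sum(diag(pieces$Si) * a) -
    sum(pieces$XtSiX_inv * crossprod(pieces$SiX, a * pieces$SiX))
}

# One pass of variance-component estimation on the working model by
# average-information REML with an EM-style fallback and a zero clamp.
# theta = (phi, tau) for gaussian; tau only for binomial (phi fixed at 1).
ai_reml <- function(z, X, A_diag, V, phi, tau, estimate_phi,
                    tol = 1e-6, maxit = 50L) {
  n <- length(z)
  floor_phi <- 1e-8 * max(stats::var(z), 1e-8)
  trace <- list()
  for (it in seq_len(maxit)) {
    Sigma <- tau * V
    diag(Sigma) <- diag(Sigma) + phi * A_diag
    pieces <- reml_pieces(z, X, Sigma)
    if (is.null(pieces))
      stop("working covariance matrix is numerically singular (phi = ",
           signif(phi, 4), ", tau = ", signif(tau, 4), ")")
    Pz <- pieces$Pz
    VPz <- V %*% Pz
    APz <- A_diag * Pz
    proj <- function(v) drop(pieces$Si %*% v -
      pieces$SiX %*% (pieces$XtSiX_inv %*% crossprod(pieces$SiX, v)))
    # REML scores dl/dtheta_i = -0.5 * (tr(P V_i) - z'P V_i P z)
    sc_tau <- -0.5 * (trace_PB(pieces, V) - sum(Pz * VPz))
    if (estimate_phi) {
      sc_phi <- -0.5 * (trace_P_diag(pieces, A_diag) - sum(Pz * APz))
      # average information: 0.5 * z' P V_i P V_j P z
      P_VPz <- proj(VPz)
      P_APz <- proj(APz)
      AI <- 0.5 * matrix(c(sum(APz * P_APz), sum(APz * P_VPz),
                           sum(APz * P_VPz), sum(VPz * P_VPz)), 2L)
      score <- c(sc_phi, sc_tau)
      step <- tryCatch(solve(AI, score), error = function(e) NULL)
      new <- c(phi, tau) + if (is.null(step)) rep(NA_real_, 2) else step
      if (is.null(step) || any(!is.finite(new)) || new[1] <= floor_phi * 0.5) {
        # EM-flavoured fallback: guaranteed-direction damped gradient step
        new <- c(phi, tau) + c(phi^2, max(tau, 0.1 * phi)^2) * score * (2 / n)
      }
      phi_new <- max(new[1], floor_phi)
      tau_new <- max(new[2], 0)
    } else {
      P_VPz <- proj(VPz)
      AI <- 0.5 * sum(VPz * P_VPz)
      step <- if (AI > 0) sc_tau / AI else NA_real_
      tau_new <- tau + if (is.finite(step)) step else
        max(tau, 0.1)^2 * sc_tau * (2 / n)
      tau_new <- max(tau_new, 0)
      phi_new <- phi
    }
    delta <- max(abs(phi_new - phi), abs(tau_new - tau)) /
      max(abs(phi), abs(tau), 1e-3)
    trace[[it]] <- c(iter = it, phi = phi_new, tau = tau_new, delta = delta)
    phi <- phi_new; tau <- tau_new
    if (delta < tol) break
  }
  # boundary check: tau clamped at 0 with negative score is a valid optimum
  list(phi = phi, tau = tau, iterations = it,
       converged = delta < tol || (tau == 0 && sc_tau < 0),
       trace = do.call(rbind, trace))
}

#' Fit the null spatial GLMM
#'
#' Penalized quasi-likelihood (PQL) fit of
#' `g(E[y | b]) = X alpha + b`, `b ~ MVN(0, tau * V)`, with no genetic term:
#' the null model whose projection structures drive the per-SNP score test.
#' The working linear mixed model is refitted at each PQL iteration and its
#' variance components updated by average-information REML with `tau` clamped
#' at zero; the dispersion `phi` is estimated for the gaussian family and
#' fixed at 1 for the binomial family.
#'
#' @param y Response vector (0/1 for binomial).
#' @param X Covariate matrix including an intercept column; must be full rank.
#' @param V Random-effect covariance: an `sgwas_similarity` or an n x n
#'   symmetric PSD matrix.
#' @param family See [sgwas_family()].
#' @param tol Convergence tolerance on the maximum relative change in
#'   `(alpha, tau)` (default `1e-6`).
#' @param maxit Maximum PQL iterations (default 100).
#' @return Object of class `sgwas_null_fit` with elements `alpha`, `tau`,
#'   `phi`, `fitted` (means), `working_weights`, projection pieces for the
#'   score test, `converged`, `boundary` (`tau` at 0), and an iteration trace.
#' @export
fit_null_glmm <- function(y, X, V, family = "gaussian", tol = 1e-6,
                          maxit = 100L) {
  fam <- sgwas_family(family)
  f <- fam$family
  X <- as.matrix(X)
  M <- if (inherits(V, "sgwas_similarity")) V$matrix else as.matrix(V)
  n <- length(y)
  if (nrow(X) != n || nrow(M) != n || ncol(M) != n)
    stop("dimensions of y, X and V do not agree")
  if (qr(X)$rank < ncol(X)) stop("'X' is rank deficient")
  if (f$family == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial family requires a 0/1 response")
  g0 <- stats::glm.fit(X, y, family = f)
  eta <- g0$linear.predictors
  mu <- g0$fitted.values
  alpha <- g0$coefficients
  phi <- if (fam$estimate_dispersion)
    sum((y - mu)^2) / (n - ncol(X)) else 1
  tau <- 0.1 * phi
  trace <- list()
  converged <- FALSE
  for (it in seq_len(maxit)) {
    mu_eta <- f$mu.eta(eta)
    Wd <- mu_eta^2 / f$variance(mu)       # working weights (phi kept separate)
    z <- eta + (y - mu) / mu_eta          # working response
    vc <- ai_reml(z, X, A_diag = 1 / Wd, V = M, phi = phi, tau = tau,
                  estimate_phi = fam$estimate_dispersion)
    phi <- vc$phi; tau <- vc$tau
    Sigma <- tau * M
    diag(Sigma) <- diag(Sigma) + phi / Wd
    pieces <- reml_pieces(z, X, Sigma)
    alpha_new <- pieces$alpha
    b <- drop(tau * (M %*% pieces$Pz))
    eta_new <- drop(X %*% alpha_new) + b
    delta_alpha <- max(abs(alpha_new - alpha)) / max(abs(alpha_new), 1e-3)
    delta_tau <- if (it == 1) Inf else abs(tau - tau_prev) / max(abs(tau), 1e-3)
    delta <- max(delta_alpha, if (is.finite(delta_tau)) delta_tau else 0)
    tau_prev <- tau
    alpha <- alpha_new
    eta <- eta_new
    mu <- f$linkinv(eta)
    trace[[it]] <- c(iter = it, tau = tau, phi = phi, delta = delta)
    if (it > 1 && delta < tol) { converged <- TRUE; break }
    if (f$family == "gaussian" && f$link == "identity" && it >= 2) {
      # working model is exact: one refit confirms the fixed point
      converged <- TRUE; break
    }
  }
  if (!converged)
    warning("PQL did not converge in ", maxit,
            " iterations (last relative change ", signif(delta, 3), ")")
  structure(list(alpha = alpha, tau = tau, phi = phi,
                 fitted = mu, eta = eta, b = b,
                 working_weights = Wd, working_response = z,
                 family = fam, X = X, n = n,
                 Si = pieces$Si, SiX = pieces$SiX,
                 XtSiX_inv = pieces$XtSiX_inv, Pz = pieces$Pz,
                 logl_reml = pieces$logl,
                 converged = converged, boundary = tau == 0,
                 vc_converged = vc$converged,
                 iterations = it, trace = do.call(rbind, trace)),
            class = "sgwas_null_fit")
}

#' @export
print.sgwas_null_fit <- function(x, ...) {
  cat("Null spatial GLMM (", x$family$family$family, " family)\n", sep = "")
  cat("  n =", x$n, "; tau =", signif(x$tau, 4), "; phi =", signif(x$phi, 4),
      if (x$boundary) "(boundary: tau = 0)", "\n")
  cat("  converged:", x$converged, "in", x$iterations, "PQL iterations\n")
  invisible(x)
}

# P g for one or more columns g (projection of the null working model)
project_P <- function(fit, G) {
  SiG <- fit$Si %*% G
  SiG - fit$SiX %*% (fit$XtSiX_inv %*% crossprod(fit$SiX, G))
}

#' Score test of one SNP under the null spatial GLMM
#'
#' Score statistic `U = g' P z` with variance `g' P g`, where `P` is the
#' REML projection of the null working model; P-value from the upper tail of
#' chi-square with 1 df. The reported effect `beta = U / (g'Pg)` and
#' `se = (g'Pg)^{-1/2}` are the one-step approximations used for downstream
#' meta-analysis (not a per-SNP Wald refit).
#'
#' @param g Dosage vector (0..2); missing values are mean-imputed.
#' @param fit A converged [fit_null_glmm()] object.
#' @param id Variant id carried into the output.
#' @return One-row data frame: `SNP, AF, N, BETA, SE, SCORE, P, REASON`.
#' @export
score_test_snp <- function(g, fit, id = NA_character_) {
  stopifnot(inherits(fit, "sgwas_null_fit"))
  res <- score_test_matrix(matrix(g, ncol = 1L), fit)
  data.frame(SNP = id, res, stringsAsFactors = FALSE)
}

# Vectorized score tests for a dosage matrix (samples x variants).
score_test_matrix <- function(G, fit) {
  G <- as.matrix(G)
  if (nrow(G) != fit$n) stop("dosage length does not match the fitted model")
  nmiss <- colSums(!is.na(G))
  cm <- colMeans(G, na.rm = TRUE)
  if (anyNA(G)) {
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- cm[idx[, 2L]]
  }
  af <- cm / 2
  mono <- apply(G, 2L, stats::var) == 0 | !is.finite(cm)
  U <- drop(crossprod(G, fit$Pz))
  PG <- project_P(fit, G)
  vU <- colSums(G * PG)
  bad <- !mono & vU <= 0
  ok <- !mono & !bad
  stat <- p <- beta <- se <- rep(NA_real_, ncol(G))
  stat[ok] <- U[ok]^2 / vU[ok]
  p[ok] <- stats::pchisq(stat[ok], df = 1L, lower.tail = FALSE)
  beta[ok] <- U[ok] / vU[ok]
  se[ok] <- 1 / sqrt(vU[ok])
  reason <- rep(NA_character_, ncol(G))
  reason[mono] <- "monomorphic"
  reason[bad] <- "nonpositive_score_variance"
  data.frame(AF = af, N = nmiss, BETA = beta, SE = se, SCORE = stat, P = p,
             REASON = reason, stringsAsFactors = FALSE)
}

#' Conventional per-SNP GWAS baseline
#'
#' Ordinary per-SNP GLM with covariates and no random effect: Wald effect,
#' standard error and two-sided P-value per variant (t reference for the
#' gaussian family, normal for binomial).
#'
#' @param genotypes A [genotype_panel()] or dosage matrix (samples x variants).
#' @param y Response vector.
#' @param X Covariate matrix including intercept.
#' @param family See [sgwas_family()].
#' @return Data frame with one row per variant: variant metadata (when a panel
#'   is supplied) plus `AF, N, BETA, SE, SCORE, P, METHOD`.
#' @export
conventional_gwas <- function(genotypes, y, X, family = "gaussian") {
  fam <- sgwas_family(family)
  f <- fam$family
  G <- dosage_matrix(genotypes)
  X <- as.matrix(X)
  n <- length(y)
  nmiss <- colSums(!is.na(G))
  cm <- colMeans(G, na.rm = TRUE)
  if (anyNA(G)) {
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- cm[idx[, 2L]]
  }
  mono <- apply(G, 2L, stats::var) == 0
  p_var <- ncol(G)
  beta <- se <- stat <- pval <- rep(NA_real_, p_var)
  if (f$family == "gaussian" && f$link == "identity") {
    # closed form: residualize on X once, then per-SNP simple regression
    qx <- qr(X)
    ry <- qr.resid(qx, y)
    rg <- qr.resid(qx, G)
    sxx <- colSums(rg^2)
    ok <- !mono & sxx > 0
    bhat <- colSums(rg * ry)[ok] / sxx[ok]
    df <- n - ncol(X) - 1L
    rss <- sum(ry^2) - bhat^2 * sxx[ok]
    sehat <- sqrt(rss / df / sxx[ok])
    beta[ok] <- bhat
    se[ok] <- sehat
    stat[ok] <- (bhat / sehat)^2
    pval[ok] <- 2 * stats::pt(abs(bhat / sehat), df, lower.tail = FALSE)
  } else {
    for (j in which(!mono)) {
      fit <- tryCatch(stats::glm.fit(cbind(X, g = G[, j]), y, family = f),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) next
      k <- ncol(X) + 1L
      # Wald from the final IRLS weighted information
      W <- fit$weights
      XX <- cbind(X, g = G[, j])
      info <- crossprod(XX * sqrt(W))
      vc <- tryCatch(solve(info), error = function(e) NULL)
      if (is.null(vc)) next
      beta[j] <- fit$coefficients[k]
      se[j] <- sqrt(vc[k, k])
      stat[j] <- (beta[j] / se[j])^2
      pval[j] <- 2 * stats::pnorm(abs(beta[j] / se[j]), lower.tail = FALSE)
    }
  }
  reason <- rep(NA_character_, p_var)
  reason[mono] <- "monomorphic"
  out <- data.frame(AF = cm / 2, N = nmiss, BETA = beta, SE = se, SCORE = stat,
                    P = pval, REASON = reason, METHOD = "conventional_glm",
                    stringsAsFactors = FALSE)
  add_variant_metadata(genotypes, out)
}

# prepend CHR/POS/SNP/A1/A2 columns when a genotype panel is available
add_variant_metadata <- function(genotypes, records) {
  if (inherits(genotypes, "genotype_panel")) {
    cbind(genotypes$variants[, c("chrom", "pos", "id", "A1", "A2")],
          records, row.names = NULL)
  } else {
    ids <- colnames(dosage_matrix(genotypes))
    if (is.null(ids)) ids <- paste0("snp", seq_len(nrow(records)))
    cbind(data.frame(id = ids, stringsAsFactors = FALSE), records,
          row.names = NULL)
  }
}

#' Genome-wide association scan with the spatial GLMM
#'
#' Fits the null GLMM once and streams the score test across all variants.
#' Sample ids are aligned by intersection when all inputs carry names. The
#' result is annotated with significance tiers and the genomic-inflation
#' factor `lambda_GC`.
#'
#' @inheritParams conventional_gwas
#' @param V Similarity matrix (see [fit_null_glmm()]).
#' @param thresholds Significance tiers annotated in the output (default
#'   `5e-8` and `1e-5`).
#' @param min_overlap Abort if fewer aligned samples remain.
#' @return Data frame of association records (class `sgwas_assoc`), with
#'   attributes `lambda_gc` and `null_fit`.
#' @export
run_assoc <- function(genotypes, y, X, V, family = "gaussian",
                      thresholds = c(5e-8, 1e-5), min_overlap = 30L) {
  G <- dosage_matrix(genotypes)
  M <- if (inherits(V, "sgwas_similarity")) V$matrix else as.matrix(V)
  ids_g <- rownames(G)
  ids_v <- if (inherits(V, "sgwas_similarity")) V$sample_ids else rownames(M)
  ids_y <- names(y)
  if (!is.null(ids_g) && !is.null(ids_v) && !is.null(ids_y)) {
    keep <- Reduce(intersect, list(ids_g, ids_v, ids_y))
    if (length(keep) < min_overlap)
      stop("only ", length(keep), " samples shared across genotypes, ",
           "phenotype and similarity matrix (< ", min_overlap, ")")
    G <- G[keep, , drop = FALSE]
    M <- M[keep, keep]
    y <- y[keep]
    X <- as.matrix(X)[keep, , drop = FALSE]
  }
  fit <- fit_null_glmm(y, X, M, family = family)
  rec <- score_test_matrix(G, fit)
  rec$METHOD <- "spatial_glmm"
  out <- add_variant_metadata(genotypes, rec)
  thresholds <- sort(thresholds)
  out$TIER <- NA_character_
  for (th in rev(thresholds)) out$TIER[!is.na(out$P) & out$P < th] <-
    formatC(th, format = "g")
  if (all(c("chrom", "pos") %in% names(out)))
    out <- out[order(out$chrom, out$pos), ]
  attr(out, "lambda_gc") <- lambda_gc(out$P)
  attr(out, "null_fit") <- fit
  class(out) <- c("sgwas_assoc", class(out))
  out
}

#' Genomic-control inflation factor
#'
#' `lambda_GC = median(chisq) / qchisq(0.5, 1)` where the chi-square statistics
#' are recovered from two-sided P-values.
#'
#' @param p Vector of P-values (NAs dropped).
#' @return The inflation factor.
#' @export
lambda_gc <- function(p) {
  p <- p[!is.na(p)]
  stats::median(stats::qchisq(p, df = 1L, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1L)
}
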