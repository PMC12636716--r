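check_effects <- function(beta, se, min_k = 1L) {
  if (length(beta) != length(se)) stop("beta and se must have equal length")
  k <- length(beta)
  if (k < min_k) stop("at least ", min_k, " stud", if (min_k > 1) "ies" else "y",
                      " required (got ", k, ")")
  bad <- which(!is.finite(se) | se <= 0)
  if (length(bad)) stop("non-positive or non-finite standard error for ",
                        "study(ies): ", paste(bad, collapse = ", "))
  k
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Combined effect `sum(w_i beta_i) / sum(w_i)` with weights `w_i = 1/se_i^2`
#' and variance `1 / sum(w_i)`.
#'
#' @param beta Per-study effect estimates.
#' @param se Per-study standard errors (all positive).
#' @return List `beta`, `var`, `se`, `p` (two-sided normal).
#' @export
fixed_effect_meta <- function(beta, se) {
  check_effects(beta, se, 1L)
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  v <- 1 / sum(w)
  list(beta = b, var = v, se = sqrt(v),
       p = 2 * stats::pnorm(abs(b) / sqrt(v), lower.tail = FALSE))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_i (beta_i - beta_fixed)^2)` about the fixed-effects estimate,
#' with heterogeneity P-value from chi-square on `k - 1` df.
#'
#' @inheritParams fixed_effect_meta
#' @return List `Q`, `df`, `p`.
#' @export
cochran_q <- function(beta, se) {
  k <- check_effects(beta, se, 2L)
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - b)^2)
  list(Q = Q, df = k - 1L,
       p = stats::pchisq(Q, df = k - 1L, lower.tail = FALSE))
}

#' DerSimonian-Laird between-study variance
#'
#' Moment estimator
#' `tau2 = max(0, (Q - (k-1)) / (sum(w_i) - sum(w_i^2)/sum(w_i)))` with
#' `w_i = 1/se_i^2`.
#'
#' @inheritParams fixed_effect_meta
#' @return Non-negative `tau2`.
#' @export
dersimonian_laird_tau2 <- function(beta, se) {
  k <- check_effects(beta, se, 2L)
  w <- 1 / se^2
  Q <- cochran_q(beta, se)$Q
  denom <- sum(w) - sum(w^2) / sum(w)
  if (denom <= 0) {
    warning("degenerate DerSimonian-Laird denominator (all weight on one ",
            "study); tau2 set to 0")
    return(0)
  }
  max(0, (Q - (k - 1)) / denom)
}

#' Random-effects meta-analysis (DerSimonian-Laird)
#'
#' Plugs the DL `tau2` into weights `w_i* = 1/(tau2 + se_i^2)`; collapses to
#' the fixed-effects result when `tau2 = 0`.
#'
#' @inheritParams fixed_effect_meta
#' @return List `beta`, `var`, `se`, `p`, `tau2`.
#' @export
random_effect_meta <- function(beta, se) {
  check_effects(beta, se, 2L)
  tau2 <- dersimonian_laird_tau2(beta, se)
  ws <- 1 / (tau2 + se^2)
  b <- sum(ws * beta) / sum(ws)
  v <- 1 / sum(ws)
  list(beta = b, var = v, se = sqrt(v),
       p = 2 * stats::pnorm(abs(b) / sqrt(v), lower.tail = FALSE),
       tau2 = tau2)
}

# palindromic (strand-ambiguous) allele pair?
is_palindromic <- function(a1, a2) {
  u1 <- toupper(a1); u2 <- toupper(a2)
  (u1 == "A" & u2 == "T") | (u1 == "T" & u2 == "A") |
    (u1 == "C" & u2 == "G") | (u1 == "G" & u2 == "C")
}

# match one external table against reference variants on (chrom, pos);
# flip beta when alleles are swapped; drop palindromic and irreconcilable rows
harmonize_one <- function(ref, ext) {
  key_ref <- paste(ref$CHR, ref$POS)
  key_ext <- paste(ext$CHR, ext$POS)
  i <- match(key_ext, key_ref)
  matched <- !is.na(i)
  ext <- ext[matched, , drop = FALSE]
  i <- i[matched]
  pal <- is_palindromic(ext$A1, ext$A2)
  same <- toupper(ext$A1) == toupper(ref$A1[i]) &
    toupper(ext$A2) == toupper(ref$A2[i])
  swap <- toupper(ext$A1) == toupper(ref$A2[i]) &
    toupper(ext$A2) == toupper(ref$A1[i])
  ok <- !pal & (same | swap)
  beta <- ifelse(swap, -ext$BETA, ext$BETA)
  list(rows = data.frame(ref_index = i[ok],
                         BETA = beta[ok], SE = ext$SE[ok],
                         N = if ("N" %in% names(ext)) ext$N[ok] else NA_real_,
                         stringsAsFactors = FALSE),
       n_palindromic = sum(pal),
       n_allele_mismatch = sum(!pal & !(same | swap)),
       n_unmatched = sum(!matched))
}

#' Harmonize a primary association table with external studies
#'
#' Variants are matched on (chromosome, position); external effects with
#' swapped A1/A2 have their sign flipped; strand-ambiguous palindromic (A/T,
#' C/G) external records are dropped with a count; variants with
#' irreconcilable allele sets are excluded per study with a count. Unmatched
#' primary variants pass through with a single study.
#'
#' @param primary Association table with columns `CHR, POS, SNP, A1, A2,
#'   BETA, SE` (and optionally `N`); [run_assoc()] output is accepted
#'   (lower-case metadata columns are renamed).
#' @param externals A list of summary-statistic tables (see
#'   [read_summary_stats()]).
#' @return List of class `sgwas_harmonized`: `variants` (reference rows),
#'   `effects` (long study x variant effect table) and a per-study `log` of
#'   exclusion counts.
#' @export
harmonize_studies <- function(primary, externals = list()) {
  ref <- as.data.frame(primary)
  ren <- c(chrom = "CHR", pos = "POS", id = "SNP")
  for (i in seq_along(ren))
    names(ref)[names(ref) == names(ren)[i]] <- ren[[i]]
  need <- c("CHR", "POS", "A1", "A2", "BETA", "SE")
  miss <- setdiff(need, names(ref))
  if (length(miss)) stop("primary table missing column(s): ",
                         paste(miss, collapse = ", "))
  ref <- ref[is.finite(ref$BETA) & is.finite(ref$SE) & ref$SE > 0, ,
             drop = FALSE]
  rownames(ref) <- NULL
  eff <- data.frame(study = "primary", ref_index = seq_len(nrow(ref)),
                    BETA = ref$BETA, SE = ref$SE,
                    N = if ("N" %in% names(ref)) ref$N else NA_real_,
                    stringsAsFactors = FALSE)
  logs <- list()
  if (length(externals)) {
    nm <- names(externals) %||% paste0("study", seq_along(externals))
    nm[nm == ""] <- paste0("study", which(nm == ""))
    for (s in seq_along(externals)) {
      h <- harmonize_one(ref, as.data.frame(externals[[s]]))
      if (nrow(h$rows))
        eff <- rbind(eff, cbind(study = nm[s], h$rows))
      logs[[nm[s]]] <- data.frame(study = nm[s],
                                  n_matched = nrow(h$rows),
                                  n_palindromic_dropped = h$n_palindromic,
                                  n_allele_mismatch = h$n_allele_mismatch,
                                  n_unmatched = h$n_unmatched,
                                  stringsAsFactors = FALSE)
    }
  }
  structure(list(variants = ref, effects = eff,
                 log = if (length(logs)) do.call(rbind, c(logs,
                   make.row.names = FALSE)) else NULL),
            class = "sgwas_harmonized")
}

#' Per-variant meta-analysis across harmonized studies
#'
#' For every reference variant, combines all harmonized study effects:
#' fixed-effects and (for k >= 2) DerSimonian-Laird random-effects estimates,
#' Cochran's Q with its P-value, and `tau2`. `MODEL_USED` is `"single"` for
#' k = 1, `"random"` when the heterogeneity P-value is below
#' `heterogeneity_alpha`, else `"fixed"`.
#'
#' @param harmonized An [harmonize_studies()] result.
#' @param heterogeneity_alpha Q-test level switching to the random-effects
#'   model (default 0.05).
#' @return Data frame with one row per variant: `K, Q, Q_P, TAU2,
#'   BETA_FIXED, SE_FIXED, P_FIXED, BETA_RANDOM, SE_RANDOM, P_RANDOM,
#'   MODEL_USED` appended to the variant key columns.
#' @export
meta_analyze <- function(harmonized, heterogeneity_alpha = 0.05) {
  stopifnot(inherits(harmonized, "sgwas_harmonized"))
  ref <- harmonized$variants
  eff <- harmonized$effects
  out <- lapply(seq_len(nrow(ref)), function(i) {
    e <- eff[eff$ref_index == i, , drop = FALSE]
    k <- nrow(e)
    fx <- fixed_effect_meta(e$BETA, e$SE)
    if (k >= 2L) {
      q <- cochran_q(e$BETA, e$SE)
      rnd <- random_effect_meta(e$BETA, e$SE)
      model <- if (q$p < heterogeneity_alpha) "random" else "fixed"
      data.frame(K = k, Q = q$Q, Q_P = q$p, TAU2 = rnd$tau2,
                 BETA_FIXED = fx$beta, SE_FIXED = fx$se, P_FIXED = fx$p,
                 BETA_RANDOM = rnd$beta, SE_RANDOM = rnd$se,
                 P_RANDOM = rnd$p, MODEL_USED = model)
    } else {
      data.frame(K = 1L, Q = NA_real_, Q_P = NA_real_, TAU2 = NA_real_,
                 BETA_FIXED = fx$beta, SE_FIXED = fx$se, P_FIXED = fx$p,
                 BETA_RANDOM = fx$beta, SE_RANDOM = fx$se, P_RANDOM = fx$p,
                 MODEL_USED = "single")
    }
  })
  keep <- intersect(c("CHR", "POS", "SNP", "A1", "A2"), names(ref))
  cbind(ref[, keep, drop = FALSE], do.call(rbind, out))
}
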