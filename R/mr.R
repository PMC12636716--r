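#' Instrumental-variable set for two-sample MR
#'
#' Per-instrument exposure and outcome effects with their standard errors.
#' Instruments must be unique by variant key and all SEs positive. LD
#' clumping is *not* performed here: instruments are assumed independent
#' (pre-pruned), as required for valid IVW inference.
#'
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome Numeric vectors.
#' @param variant Optional variant identifiers (defaults `iv1..ivJ`).
#' @param p_threshold Instrument-selection P threshold recorded for
#'   provenance.
#' @return Object of class `sgwas_ivset` (a data frame).
#' @export
iv_set <- function(beta_exposure, se_exposure, beta_outcome, se_outcome,
                   variant = NULL, p_threshold = NA_real_) {
  J <- length(beta_exposure)
  if (is.null(variant)) variant <- paste0("iv", seq_len(J))
  if (anyDuplicated(variant)) stop("instruments must be unique by variant key")
  if (length(se_exposure) != J || length(beta_outcome) != J ||
      length(se_outcome) != J || length(variant) != J)
    stop("all instrument vectors must have equal length")
  if (any(se_exposure <= 0) || any(se_outcome <= 0))
    stop("all standard errors must be positive")
  structure(data.frame(variant = variant, beta_exposure = beta_exposure,
                       se_exposure = se_exposure, beta_outcome = beta_outcome,
                       se_outcome = se_outcome, stringsAsFactors = FALSE),
            p_threshold = p_threshold,
            class = c("sgwas_ivset", "data.frame"))
}

#' Inverse-variance-weighted MR estimate
#'
#' Fixed-effect IVW causal estimate
#' `beta = sum(bx_j by_j / sy_j^2) / sum(bx_j^2 / sy_j^2)`,
#' `se = (sum(bx_j^2 / sy_j^2))^{-1/2}` -- equivalently, weighted regression
#' of outcome on exposure effects through the origin with weights
#' `1/sy_j^2`. A single instrument reduces to the Wald ratio.
#'
#' @param ivs An [iv_set()].
#' @return List `beta`, `se`, `p` (two-sided normal), `n_instruments`.
#' @export
ivw_estimate <- function(ivs) {
  stopifnot(inherits(ivs, "sgwas_ivset"))
  if (nrow(ivs) < 1L) stop("at least one instrument is required")
  w <- 1 / ivs$se_outcome^2
  denom <- sum(ivs$beta_exposure^2 * w)
  if (denom == 0) stop("all exposure effects are zero; IVW estimate undefined")
  b <- sum(ivs$beta_exposure * ivs$beta_outcome * w) / denom
  se <- 1 / sqrt(denom)
  list(beta = b, se = se,
       p = 2 * stats::pnorm(abs(b) / se, lower.tail = FALSE),
       n_instruments = nrow(ivs))
}

#' Cochran's Q heterogeneity for the fixed-effect IVW model
#'
#' `Q = sum(w_j (by_j/bx_j - beta_ivw)^2)` with `w_j = bx_j^2 / sy_j^2`;
#' P-value from chi-square on J - 1 df. Instruments with a zero exposure
#' effect cannot form a Wald ratio and are excluded with a warning.
#'
#' @param ivs An [iv_set()].
#' @param beta_ivw The full IVW estimate (recomputed if omitted).
#' @return List `Q`, `df`, `p`, `n_used`.
#' @export
mr_cochran_q <- function(ivs, beta_ivw = NULL) {
  stopifnot(inherits(ivs, "sgwas_ivset"))
  if (nrow(ivs) < 2L) stop("at least two instruments are required")
  zero <- ivs$beta_exposure == 0
  if (any(zero)) {
    warning(sum(zero), " instrument(s) with zero exposure effect excluded ",
            "from the ratio-based Q")
    ivs <- ivs[!zero, , drop = FALSE]
  }
  if (is.null(beta_ivw)) beta_ivw <- ivw_estimate(ivs)$beta
  w <- ivs$beta_exposure^2 / ivs$se_outcome^2
  ratio <- ivs$beta_outcome / ivs$beta_exposure
  Q <- sum(w * (ratio - beta_ivw)^2)
  list(Q = Q, df = nrow(ivs) - 1L,
       p = stats::pchisq(Q, df = nrow(ivs) - 1L, lower.tail = FALSE),
       n_used = nrow(ivs))
}

#' Leave-one-out MR sensitivity analysis
#'
#' Re-estimates the IVW effect J times, each time excluding one instrument,
#' and flags instruments whose removal changes the sign of the estimate or
#' moves its P-value across `alpha`.
#'
#' @param ivs An [iv_set()] with at least two instruments.
#' @param alpha Significance boundary used for flagging (default 0.05).
#' @return Data frame with one row per dropped instrument: `dropped`, `beta`,
#'   `se`, `p`, `delta_beta`, `flagged`.
#' @export
leave_one_out <- function(ivs, alpha = 0.05) {
  stopifnot(inherits(ivs, "sgwas_ivset"))
  J <- nrow(ivs)
  if (J < 2L) stop("leave-one-out requires at least two instruments")
  full <- ivw_estimate(ivs)
  rows <- lapply(seq_len(J), function(j) {
    est <- ivw_estimate(ivs[-j, , drop = FALSE])
    data.frame(dropped = ivs$variant[j], beta = est$beta, se = est$se,
               p = est$p, delta_beta = est$beta - full$beta,
               flagged = sign(est$beta) != sign(full$beta) ||
                 ((est$p < alpha) != (full$p < alpha)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-sample Mendelian randomization analysis
#'
#' Builds the instrument set from harmonized exposure and outcome summary
#' statistics (instrument selection at `p_threshold` on the exposure;
#' palindromic variants dropped, swapped alleles sign-flipped -- the same
#' harmonization rules as [harmonize_studies()]), then runs the fixed-effect
#' IVW estimate, Cochran's Q, and the leave-one-out analysis.
#'
#' @param exposure,outcome Summary-statistic tables (see
#'   [read_summary_stats()]); `exposure` needs a `P` column for instrument
#'   selection unless `p_threshold = 1`.
#' @param p_threshold Instrument-selection threshold (default `5e-8`).
#' @param random_effects Also report a multiplicative random-effects IVW
#'   (SE inflated by `sqrt(max(1, Q/df))`).
#' @return Object of class `sgwas_mr`: `estimate` (`beta`, `se`, `p`, CI95),
#'   `Q`, `Q_p`, `loo` table, `n_instruments`, `harmonization_log`.
#' @export
mr_analyze <- function(exposure, outcome, p_threshold = 5e-8,
                       random_effects = FALSE) {
  exposure <- as.data.frame(exposure)
  outcome <- as.data.frame(outcome)
  if (p_threshold < 1) {
    if (!"P" %in% names(exposure))
      stop("exposure table needs a P column for instrument selection")
    exposure <- exposure[exposure$P < p_threshold, , drop = FALSE]
  }
  if (nrow(exposure) == 0L) stop("no instrument passes the exposure ",
                                 "P threshold ", p_threshold)
  h <- harmonize_one(exposure, outcome)
  if (nrow(h$rows) == 0L) stop("no instrument could be harmonized with the ",
                               "outcome statistics")
  idx <- h$rows$ref_index
  ids <- if ("SNP" %in% names(exposure)) exposure$SNP[idx] else
    paste(exposure$CHR[idx], exposure$POS[idx], sep = ":")
  ivs <- iv_set(beta_exposure = exposure$BETA[idx],
                se_exposure = exposure$SE[idx],
                beta_outcome = h$rows$BETA, se_outcome = h$rows$SE,
                variant = ids, p_threshold = p_threshold)
  est <- ivw_estimate(ivs)
  qq <- if (nrow(ivs) >= 2L) mr_cochran_q(ivs, est$beta) else
    list(Q = NA_real_, df = NA_integer_, p = NA_real_)
  if (random_effects && is.finite(qq$Q)) {
    infl <- sqrt(max(1, qq$Q / qq$df))
    est$se_random <- est$se * infl
    est$p_random <- 2 * stats::pnorm(abs(est$beta) / est$se_random,
                                     lower.tail = FALSE)
  }
  loo <- if (nrow(ivs) >= 2L) leave_one_out(ivs) else NULL
  structure(list(estimate = c(est, list(
    ci_lower = est$beta - 1.96 * est$se,
    ci_upper = est$beta + 1.96 * est$se)),
    Q = qq$Q, Q_df = qq$df, Q_p = qq$p, loo = loo,
    n_instruments = nrow(ivs), ivs = ivs,
    harmonization_log = h[c("n_palindromic", "n_allele_mismatch",
                            "n_unmatched")]),
    class = "sgwas_mr")
}

#' @export
print.sgwas_mr <- function(x, ...) {
  e <- x$estimate
  cat(sprintf("IVW MR estimate: beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], P = %.3g\n",
              e$beta, e$se, e$ci_lower, e$ci_upper, e$p))
  cat(sprintf("  %d instruments; Cochran's Q = %.3f (df %d, P = %.3g)\n",
              x$n_instruments, x$Q, x$Q_df, x$Q_p))
  if (!is.null(x$loo) && any(x$loo$flagged))
    cat("  leave-one-out flags:", paste(x$loo$dropped[x$loo$flagged],
                                        collapse = ", "), "\n")
  invisible(x)
}
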