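#' Gaussian radial basis function kernel
#'
#' Similarity between two ROI feature vectors,
#' `exp(-||s_k - s_l||^2 / (2 * sigma^2))`. The value lies in `(0, 1]` and
#' decreases monotonically with the Euclidean distance between the vectors.
#'
#' @param s_k,s_l Numeric vectors of equal length (one ROI's feature vector).
#' @param sigma Kernel bandwidth, must be positive.
#' @return A single kernel value in `(0, 1]`.
#' @examples
#' rbf_kernel(c(0, 0), c(3, 4), sigma = 5)  # exp(-25/50)
#' @export
rbf_kernel <- function(s_k, s_l, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number")
  if (length(s_k) != length(s_l))
    stop("'s_k' and 's_l' must have equal length")
  if (anyNA(s_k) || anyNA(s_l) || any(!is.finite(c(s_k, s_l))))
    stop("kernel inputs must be finite and non-missing")
  exp(-sum((s_k - s_l)^2) / (2 * sigma^2))
}

# Lexicographic unordered ROI pairs (k < l): (1,2), (1,3), ..., (m-1,m).
roi_pairs <- function(m) {
  if (m < 2L) stop("at least 2 ROIs are required (m >= 2)")
  k <- rep.int(seq_len(m - 1L), times = (m - 1L):1L)
  l <- sequence((m - 1L):1L, from = 2L:m)
  cbind(k = k, l = l)
}

#' Median-heuristic kernel bandwidth
#'
#' Bandwidth default for the ROI kernel: the median Euclidean distance between
#' ROI feature vectors, pooled over all ROI pairs of a reference subsample of
#' individuals. Scale-free and robust; can always be overridden explicitly.
#'
#' @param panel An [roi_panel()] object.
#' @param lambda Coordinate weight used when assembling ROI vectors.
#' @param max_samples Number of individuals pooled (first `max_samples`).
#' @return Positive bandwidth.
#' @export
median_bandwidth <- function(panel, lambda = 1, max_samples = 20L) {
  n <- length(panel$sample_ids)
  idx <- seq_len(min(n, max_samples))
  d <- unlist(lapply(idx, function(i) {
    S <- sample_roi_matrix(panel, i, lambda = lambda)
    as.vector(stats::dist(S))
  }), use.names = FALSE)
  med <- stats::median(d)
  if (!is.finite(med) || med <= 0) {
    # all ROI vectors coincide; any positive bandwidth gives a flat kernel
    med <- 1
  }
  med
}

#' ROI feature panel
#'
#' Container for per-sample, per-ROI imaging-derived phenotypes (IDPs).
#' `values` holds one column per IDP slot, where a slot is a
#' (ROI, modality, feature) triple; `info` describes the columns. Columns are
#' z-scored across samples at construction so that activity features and
#' (optionally) centroid coordinates live on a common scale.
#'
#' @param values Numeric n x F matrix of IDP values (samples in rows).
#' @param info Data frame with one row per column of `values` and columns
#'   `roi`, `modality`, `feature`.
#' @param coords Optional m x 3 matrix of ROI centroid coordinates (MNI mm),
#'   with rownames (or order) matching `roi_ids`.
#' @param sample_ids,roi_ids Identifiers; defaults derived from dimnames.
#' @param standardize Z-score columns across samples (default `TRUE`).
#' @return An object of class `roi_panel`.
#' @export
roi_panel <- function(values, info, coords = NULL, sample_ids = rownames(values),
                      roi_ids = NULL, standardize = TRUE) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(values)))
  if (!is.data.frame(info) || nrow(info) != ncol(values))
    stop("'info' must be a data.frame with one row per column of 'values'")
  if (!all(c("roi", "modality", "feature") %in% names(info)))
    stop("'info' needs columns roi, modality, feature")
  if (anyNA(values)) stop("missing values are not allowed in an ROI panel")
  if (is.null(roi_ids)) roi_ids <- unique(as.character(info$roi))
  if (length(roi_ids) < 2L) stop("at least 2 ROIs are required (m >= 2)")
  if (standardize) {
    sds <- apply(values, 2L, stats::sd)
    mns <- colMeans(values)
    sds[sds == 0] <- 1  # constant IDP stays at 0 after centering
    values <- sweep(sweep(values, 2L, mns, "-"), 2L, sds, "/")
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (ncol(coords) != 3L) stop("'coords' must have three columns (x, y, z)")
    if (nrow(coords) != length(roi_ids))
      stop("'coords' must have one row per ROI")
    if (!is.null(rownames(coords))) coords <- coords[roi_ids, , drop = FALSE]
    csd <- apply(coords, 2L, stats::sd)
    csd[csd == 0] <- 1
    coords <- sweep(sweep(coords, 2L, colMeans(coords), "-"), 2L, csd, "/")
  }
  structure(list(values = values, info = info, coords = coords,
                 sample_ids = as.character(sample_ids),
                 roi_ids = as.character(roi_ids)),
            class = "roi_panel")
}

#' @export
print.roi_panel <- function(x, ...) {
  cat("ROI feature panel:", length(x$sample_ids), "samples,",
      length(x$roi_ids), "ROIs,", ncol(x$values), "IDP slots",
      if (is.null(x$coords)) "(no coordinates)\n" else "(with coordinates)\n")
  invisible(x)
}

#' Read ROI features and centroid coordinates from CSV
#'
#' Features come as a long table `sample_id,roi_id,modality,feature,value`;
#' coordinates as `roi_id,x,y,z`.
#'
#' @param features_csv,coords_csv File paths; `coords_csv` may be `NULL`.
#' @param standardize Passed to [roi_panel()].
#' @return An [roi_panel()].
#' @export
read_roi_features <- function(features_csv, coords_csv = NULL, standardize = TRUE) {
  long <- utils::read.csv(features_csv, stringsAsFactors = FALSE)
  need <- c("sample_id", "roi_id", "modality", "feature", "value")
  miss <- setdiff(need, names(long))
  if (length(miss)) stop("features CSV is missing column(s): ",
                         paste(miss, collapse = ", "))
  info <- unique(data.frame(roi = as.character(long$roi_id),
                            modality = as.character(long$modality),
                            feature = as.character(long$feature),
                            stringsAsFactors = FALSE))
  info <- info[order(info$roi, info$modality, info$feature), , drop = FALSE]
  rownames(info) <- NULL
  key <- function(r, m, f) paste(r, m, f, sep = "\r")
  slot <- match(key(long$roi_id, long$modality, long$feature),
                key(info$roi, info$modality, info$feature))
  samples <- unique(long$sample_id)
  wide <- matrix(NA_real_, length(samples), nrow(info),
                 dimnames = list(samples, NULL))
  wide[cbind(match(long$sample_id, samples), slot)] <- long$value
  if (anyNA(wide)) stop("ROI feature table is not complete: every sample needs ",
                        "a value for every (roi, modality, feature) slot")
  coords <- NULL
  roi_ids <- unique(as.character(long$roi_id))
  if (!is.null(coords_csv)) {
    cc <- utils::read.csv(coords_csv, stringsAsFactors = FALSE)
    if (!all(c("roi_id", "x", "y", "z") %in% names(cc)))
      stop("coordinates CSV needs columns roi_id, x, y, z")
    coords <- as.matrix(cc[, c("x", "y", "z")])
    rownames(coords) <- cc$roi_id
    coords <- coords[roi_ids, , drop = FALSE]
  }
  roi_panel(wide, info, coords = coords, sample_ids = samples,
            roi_ids = roi_ids, standardize = standardize)
}

#' Filter IDPs by case/control significance
#'
#' Two-sided two-sample t-test of every IDP slot against a binary phenotype;
#' slots with P below `alpha` are retained and re-standardized. A pooled-
#' variance test is used unless a class has zero variance for a slot, in which
#' case the Welch form is applied and the slot flagged.
#'
#' @param panel An [roi_panel()].
#' @param phenotype Binary vector (0/1 or logical), one value per sample.
#' @param alpha Retention threshold on the two-sided P-value (default `1e-5`).
#' @return The filtered `roi_panel`, with attribute `"idp_report"` holding a
#'   data frame of per-slot `t`, `df`, `p` and retention flags.
#' @export
filter_significant_idps <- function(panel, phenotype, alpha = 1e-5) {
  stopifnot(inherits(panel, "roi_panel"))
  ph <- as.integer(phenotype)
  if (length(ph) != nrow(panel$values))
    stop("'phenotype' must have one value per sample")
  if (!all(ph %in% c(0L, 1L))) stop("'phenotype' must be binary (0/1)")
  n1 <- sum(ph == 1L); n0 <- sum(ph == 0L)
  if (n1 < 2L || n0 < 2L) stop("need at least 2 samples in each phenotype class")
  x1 <- panel$values[ph == 1L, , drop = FALSE]
  x0 <- panel$values[ph == 0L, , drop = FALSE]
  m1 <- colMeans(x1); m0 <- colMeans(x0)
  v1 <- apply(x1, 2L, stats::var); v0 <- apply(x0, 2L, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  tt <- (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
  df <- rep(n1 + n0 - 2, length(tt))
  welch <- (v1 == 0) != (v0 == 0)  # exactly one degenerate class
  if (any(welch)) {
    se2 <- v1[welch] / n1 + v0[welch] / n0
    tt[welch] <- (m1[welch] - m0[welch]) / sqrt(se2)
    df[welch] <- se2^2 / ((v1[welch] / n1)^2 / (n1 - 1) +
                          (v0[welch] / n0)^2 / (n0 - 1))
  }
  both0 <- v1 == 0 & v0 == 0
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  p[both0] <- ifelse(m1[both0] == m0[both0], 1, 0)
  tt[both0] <- ifelse(m1[both0] == m0[both0], 0, Inf)
  retained <- is.finite(p) & (p < alpha | alpha >= 1)
  report <- data.frame(panel$info, t = tt, df = df, p = p,
                       retained = retained, welch = welch | both0,
                       row.names = NULL, stringsAsFactors = FALSE)
  if (!any(retained)) {
    cond <- structure(class = c("sgwas_empty_panel", "error", "condition"),
                      list(message = sprintf(
                        "no IDP passed the significance filter at alpha = %g; consider relaxing alpha",
                        alpha), call = sys.call(-1)))
    stop(cond)
  }
  out <- roi_panel(panel$values[, retained, drop = FALSE],
                   panel$info[retained, , drop = FALSE],
                   coords = panel$coords, sample_ids = panel$sample_ids,
                   roi_ids = panel$roi_ids, standardize = TRUE)
  attr(out, "idp_report") <- report
  out
}

# ROI-by-dimension matrix s_k(i) for one sample: the ROI's activity slots
# aligned on (modality, feature) across ROIs (zero where a ROI has no surviving
# value for a slot -- i.e. held at the population mean), plus lambda-weighted
# z-scored centroid coordinates when available.
sample_roi_matrix <- function(panel, sample, lambda = 1) {
  if (is.character(sample)) {
    i <- match(sample, panel$sample_ids)
    if (is.na(i)) stop("sample '", sample, "' not found in panel")
  } else i <- as.integer(sample)
  m <- length(panel$roi_ids)
  slots <- unique(panel$info[, c("modality", "feature")])
  S <- matrix(0, m, nrow(slots))
  ridx <- match(panel$info$roi, panel$roi_ids)
  sidx <- match(interaction(panel$info$modality, panel$info$feature),
                interaction(slots$modality, slots$feature))
  S[cbind(ridx, sidx)] <- panel$values[i, ]
  if (!is.null(panel$coords) && lambda != 0)
    S <- cbind(S, lambda * panel$coords)
  S
}

#' Individualized spatial kernel profile
#'
#' Evaluates the RBF kernel over all unordered ROI pairs (k < l, lexicographic
#' order) of one sample's ROI feature vectors, yielding the length
#' `m(m-1)/2` brain spatial-interaction profile of that individual.
#'
#' @param panel An [roi_panel()].
#' @param sample Sample id or index.
#' @param sigma Bandwidth; default is the pooled median heuristic
#'   ([median_bandwidth()]).
#' @param lambda Weight of the z-scored ROI centroid coordinates appended to
#'   each ROI's activity vector (0 disables the coordinate block).
#' @return Numeric vector of kernel values in `(0, 1]` with attributes
#'   `sigma`, `lambda`, `sample_id`.
#' @export
spatial_profile <- function(panel, sample, sigma = NULL, lambda = 1) {
  stopifnot(inherits(panel, "roi_panel"))
  if (is.null(sigma)) sigma <- median_bandwidth(panel, lambda = lambda)
  if (sigma <= 0) stop("'sigma' must be positive")
  S <- sample_roi_matrix(panel, sample, lambda = lambda)
  pr <- roi_pairs(nrow(S))
  d2 <- as.matrix(stats::dist(S))^2
  out <- exp(-d2[pr] / (2 * sigma^2))
  attr(out, "sigma") <- sigma
  attr(out, "lambda") <- lambda
  attr(out, "sample_id") <- if (is.character(sample)) sample else
    panel$sample_ids[as.integer(sample)]
  out
}

# All profiles at once (n x m(m-1)/2). Fast path when every ROI contributes a
# single activity slot and no coordinates are used (the simulation layout).
profile_matrix <- function(panel, sigma = NULL, lambda = 1) {
  if (is.null(sigma)) sigma <- median_bandwidth(panel, lambda = lambda)
  m <- length(panel$roi_ids)
  pr <- roi_pairs(m)
  one_slot <- is.null(panel$coords) || lambda == 0
  if (one_slot) {
    slots <- unique(panel$info[, c("modality", "feature")])
    one_slot <- nrow(slots) == 1L && nrow(panel$info) == m &&
      !anyDuplicated(panel$info$roi)
  }
  if (one_slot) {
    X <- panel$values[, match(panel$roi_ids, panel$info$roi), drop = FALSE]
    D <- X[, pr[, "k"], drop = FALSE] - X[, pr[, "l"], drop = FALSE]
    P <- exp(-(D * D) / (2 * sigma^2))
  } else {
    P <- t(vapply(seq_along(panel$sample_ids), function(i)
      as.numeric(spatial_profile(panel, i, sigma = sigma, lambda = lambda)),
      numeric(nrow(pr))))
  }
  rownames(P) <- panel$sample_ids
  attr(P, "sigma") <- sigma
  attr(P, "lambda") <- lambda
  P
}

#' Cross-sample similarity matrix of spatial kernel profiles
#'
#' Pearson correlation between every pair of individuals' spatial kernel
#' profiles, the covariance structure `V` of the spatial GLMM random effect.
#' A correlation matrix of kernel profiles need not be positive semi-definite,
#' so negative eigenvalues are clipped at zero and the matrix rescaled back to
#' unit diagonal; the repair is recorded in the returned object.
#'
#' @param profiles n x L matrix of profiles (rows = samples, identical pair
#'   order), e.g. from [spatial_profile()] stacked row-wise, or a list of
#'   profile vectors.
#' @param psd_repair Apply the eigenvalue-clipping repair (default `TRUE`).
#' @return Object of class `sgwas_similarity`: `matrix` (n x n), `sample_ids`,
#'   `psd_adjusted`, `min_eigenvalue_before`, `min_eigenvalue_after`,
#'   `frobenius_delta`, and the eigen pair of the final matrix.
#' @export
similarity_matrix <- function(profiles, psd_repair = TRUE) {
  if (is.list(profiles)) {
    ids <- vapply(profiles, function(p) {
      s <- attr(p, "sample_id"); if (is.null(s)) NA_character_ else s
    }, character(1))
    profiles <- do.call(rbind, lapply(profiles, as.numeric))
    if (!anyNA(ids)) rownames(profiles) <- ids
  }
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 2L) stop("need at least two samples")
  sds <- apply(profiles, 1L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance kernel profile for sample(s): ",
         paste(if (!is.null(rownames(profiles))) rownames(profiles)[sds == 0]
               else which(sds == 0), collapse = ", "),
         "; Pearson correlation is undefined")
  Z <- (profiles - rowMeans(profiles)) / sds
  V <- tcrossprod(Z) / (ncol(profiles) - 1L)
  V <- (V + t(V)) / 2
  diag(V) <- 1
  if (anyNA(V)) stop("undefined correlation encountered in similarity matrix")
  ev <- eigen(V, symmetric = TRUE)
  min_before <- min(ev$values)
  adjusted <- FALSE
  fdelta <- 0
  if (psd_repair && min_before < 0) {
    vals <- pmax(ev$values, 0)
    V2 <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(pmax(diag(V2), .Machine$double.eps))
    V2 <- V2 / tcrossprod(d)
    V2 <- (V2 + t(V2)) / 2
    diag(V2) <- 1
    fdelta <- sqrt(sum((V2 - V)^2))
    V <- V2
    ev <- eigen(V, symmetric = TRUE)
    adjusted <- TRUE
  }
  structure(list(matrix = V,
                 sample_ids = rownames(profiles),
                 psd_adjusted = adjusted,
                 min_eigenvalue_before = min_before,
                 min_eigenvalue_after = min(ev$values),
                 frobenius_delta = fdelta,
                 eigen = ev),
            class = "sgwas_similarity")
}

#' @export
print.sgwas_similarity <- function(x, ...) {
  cat("Spatial similarity matrix:", nrow(x$matrix), "x", ncol(x$matrix), "\n")
  cat("  PSD repair applied:", x$psd_adjusted,
      sprintf(" (min eigenvalue %.3g -> %.3g, ||delta||_F = %.3g)\n",
              x$min_eigenvalue_before, x$min_eigenvalue_after,
              x$frobenius_delta))
  invisible(x)
}

#' @export
as.matrix.sgwas_similarity <- function(x, ...) x$matrix

#' Build the similarity matrix straight from an ROI panel
#'
#' Convenience wrapper: profiles for every sample ([spatial_profile()]) then
#' their Pearson correlation ([similarity_matrix()]).
#'
#' @inheritParams spatial_profile
#' @inheritParams similarity_matrix
#' @return An `sgwas_similarity` object (with `sigma`/`lambda` recorded).
#' @export
build_similarity <- function(panel, sigma = NULL, lambda = 1, psd_repair = TRUE) {
  P <- profile_matrix(panel, sigma = sigma, lambda = lambda)
  V <- similarity_matrix(P, psd_repair = psd_repair)
  V$sigma <- attr(P, "sigma")
  V$lambda <- attr(P, "lambda")
  V
}

#' Write / read a similarity matrix as TSV
#'
#' TSV with a header row and a leading column of sample ids. `write_similarity`
#' also writes a JSON sidecar (`<path>.json`) recording the bandwidth,
#' coordinate weight and PSD-repair metadata.
#'
#' @param V An `sgwas_similarity` (or plain matrix) to write.
#' @param path Output TSV path.
#' @return `write_similarity` returns `path` invisibly; `read_similarity`
#'   returns an `sgwas_similarity`.
#' @export
write_similarity <- function(V, path) {
  meta <- NULL
  if (inherits(V, "sgwas_similarity")) {
    meta <- V[c("psd_adjusted", "min_eigenvalue_before", "min_eigenvalue_after",
                "frobenius_delta")]
    meta$sigma <- V$sigma
    meta$lambda <- V$lambda
    M <- V$matrix
    ids <- V$sample_ids
  } else {
    M <- as.matrix(V)
    ids <- rownames(M)
  }
  if (is.null(ids)) ids <- paste0("sample", seq_len(nrow(M)))
  df <- data.frame(sample_id = ids, M, check.names = FALSE)
  colnames(df) <- c("sample_id", ids)
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  M <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(M) <- list(ids, ids)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)
  structure(list(matrix = (M + t(M)) / 2, sample_ids = ids,
                 psd_adjusted = FALSE,
                 min_eigenvalue_before = min(ev$values),
                 min_eigenvalue_after = min(ev$values),
                 frobenius_delta = 0,
                 eigen = eigen((M + t(M)) / 2, symmetric = TRUE)),
            class = "sgwas_similarity")
}
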