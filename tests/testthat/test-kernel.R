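make_panel <- function(values, coords = NULL) {
  m <- ncol(values)
  roi_panel(values,
            data.frame(roi = paste0("roi", seq_len(m)), modality = "sim",
                       feature = "activity", stringsAsFactors = FALSE),
            coords = coords, standardize = TRUE)
}

test_that("RBF kernel matches hand evaluation, symmetry and bounds", {
  expect_equal(rbf_kernel(c(0, 0), c(3, 4), sigma = 5), exp(-25 / 50))
  expect_equal(rbf_kernel(c(0, 0), c(3, 4), sigma = 5), 0.606530659712633,
               tolerance = 1e-12)
  x <- rnorm(7); y <- rnorm(7)
  expect_identical(rbf_kernel(x, y, 1.3), rbf_kernel(y, x, 1.3))
  expect_equal(rbf_kernel(x, x, 2), 1.0)
  # monotone decreasing in distance at fixed sigma
  d <- seq(0, 5, by = 0.5)
  k <- vapply(d, function(dd) rbf_kernel(0, dd, sigma = 1.7), numeric(1))
  expect_true(all(diff(k) < 0))
  expect_true(all(k > 0 & k <= 1))
  expect_error(rbf_kernel(1, 2, sigma = 0), "sigma")
  expect_error(rbf_kernel(c(1, NA), c(1, 2), sigma = 1), "finite")
})

test_that("spatial profile has C(m,2) entries in lexicographic pair order", {
  set.seed(11)
  panel <- make_panel(matrix(rnorm(5 * 3), 5, 3))
  pr <- spatial_profile(panel, 1, sigma = 1)
  expect_length(pr, 3L)
  # identical activities and no coordinates -> all entries exactly 1
  flat <- make_panel(matrix(rep(rnorm(6), each = 4), 4, 6))
  # constant columns z-score to zero, so every ROI vector coincides
  pr_flat <- spatial_profile(flat, 2, sigma = 1, lambda = 0)
  expect_equal(as.numeric(pr_flat), rep(1, choose(6, 2)))
})

test_that("kernel pipeline equals the naive nested-loop reference", {
  set.seed(42)
  for (case in list(c(n = 4, m = 3), c(n = 7, m = 5), c(n = 10, m = 6))) {
    vals <- matrix(rnorm(case["n"] * case["m"], sd = 3), case["n"])
    coords <- matrix(rnorm(case["m"] * 3, sd = 20), ncol = 3)
    for (lambda in c(0, 1, 0.5)) {
      sigma <- 1.9
      panel <- make_panel(vals, coords = coords)
      ref <- naive_similarity(vals, coords, sigma = sigma, lambda = lambda)
      P <- t(vapply(seq_len(nrow(vals)), function(i)
        as.numeric(spatial_profile(panel, i, sigma = sigma, lambda = lambda)),
        numeric(ncol(ref$profiles))))
      expect_equal(P, ref$profiles, tolerance = 1e-12, ignore_attr = TRUE)
      V <- similarity_matrix(P, psd_repair = FALSE)
      expect_equal(V$matrix, ref$V, tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("ROI order permutation leaves profiles invariant", {
  set.seed(3)
  n <- 6; m <- 5
  vals <- matrix(rnorm(n * m), n, m,
                 dimnames = list(NULL, paste0("roi", 1:m)))
  coords <- matrix(rnorm(m * 3), m, 3, dimnames = list(colnames(vals), NULL))
  perm <- sample(m)
  p1 <- make_panel(vals, coords)
  info_p <- data.frame(roi = colnames(vals)[perm], modality = "sim",
                       feature = "activity", stringsAsFactors = FALSE)
  p2 <- roi_panel(vals[, perm], info_p, coords = coords[perm, ],
                  roi_ids = colnames(vals))   # canonical ROI order restored
  pr1 <- spatial_profile(p1, 3, sigma = 1.2)
  pr2 <- spatial_profile(p2, 3, sigma = 1.2)
  expect_equal(as.numeric(pr1), as.numeric(pr2), tolerance = 1e-12)
})

test_that("similarity matrix is symmetric, unit-diagonal, PSD after repair", {
  set.seed(9)
  panel <- make_panel(matrix(rnorm(40 * 8), 40, 8))
  V <- build_similarity(panel)
  M <- V$matrix
  expect_lt(max(abs(M - t(M))), 1e-10)
  expect_equal(unname(diag(M)), rep(1, 40))
  expect_true(all(M >= -1 - 1e-12 & M <= 1 + 1e-12))
  expect_gte(V$min_eigenvalue_after, -1e-10)
  # all-identical profiles -> all-ones matrix
  prof <- matrix(rep(rnorm(10), each = 5), 5, 10)
  Vones <- similarity_matrix(prof, psd_repair = FALSE)
  expect_equal(unname(Vones$matrix), matrix(1, 5, 5))
  # zero-variance profile is an error naming the sample
  prof[2, ] <- 7
  expect_error(similarity_matrix(prof), "zero-variance")
})

test_that("PSD repair clips negative eigenvalues and logs the change", {
  # build an indefinite correlation-like matrix directly
  M <- matrix(c(1, .9, -.9, .9, 1, .9, -.9, .9, 1), 3)
  ev <- eigen(M, symmetric = TRUE)
  expect_lt(min(ev$values), 0)
  # exercise the repair path with near-antipodal profiles whose raw
  # correlation matrix is indefinite
  set.seed(1)
  base <- rnorm(6)
  profs <- rbind(base, -base + rnorm(6, sd = 1e-3), base + rnorm(6, sd = 1e-3),
                 -base + rnorm(6, sd = 1e-3))
  V <- similarity_matrix(profs, psd_repair = TRUE)
  expect_gte(V$min_eigenvalue_after, -1e-12)
  if (V$psd_adjusted) {
    expect_lt(V$min_eigenvalue_before, 0)
    expect_gt(V$frobenius_delta, 0)
    expect_lt(V$frobenius_delta, 2 * abs(V$min_eigenvalue_before) * nrow(profs))
  }
  expect_equal(unname(diag(V$matrix)), rep(1, 4))
})

test_that("IDP significance filter retains exactly the shifted features", {
  set.seed(21)
  n <- 60
  ph <- rep(c(0L, 1L), each = n / 2)
  vals <- matrix(rnorm(n * 5), n, 5)
  vals[ph == 1, 1] <- vals[ph == 1, 1] + 5   # huge shift
  vals[ph == 1, 4] <- vals[ph == 1, 4] - 5   # huge shift
  panel <- make_panel(vals)
  filt <- filter_significant_idps(panel, ph, alpha = 1e-5)
  rep <- attr(filt, "idp_report")
  # direct t.test oracle per column
  p_ref <- apply(vals, 2, function(x)
    t.test(x[ph == 1], x[ph == 0], var.equal = TRUE)$p.value)
  expect_equal(rep$p, unname(p_ref), tolerance = 1e-10)
  expect_identical(which(rep$retained), c(1L, 4L))
  expect_equal(ncol(filt$values), 2L)
  # retained columns re-standardized
  expect_equal(unname(colMeans(filt$values)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(filt$values, 2, sd)), c(1, 1), tolerance = 1e-10)
})

test_that("IDP filter limits: alpha = 1 keeps all; pure noise raises the
           empty-panel condition at tiny alpha", {
  set.seed(5)
  n <- 40
  ph <- rep(c(0L, 1L), n / 2)
  panel <- make_panel(matrix(rnorm(n * 6), n, 6))
  all_kept <- filter_significant_idps(panel, ph, alpha = 1)
  expect_equal(ncol(all_kept$values), 6L)
  expect_error(filter_significant_idps(panel, ph, alpha = 1e-12),
               class = "sgwas_empty_panel")
})

test_that("null permutation retention rate is near alpha", {
  set.seed(8)
  n <- 50; reps <- 40; alpha <- 0.05
  hits <- 0; total <- 0
  for (r in seq_len(reps)) {
    ph <- sample(rep(c(0L, 1L), n / 2))
    panel <- make_panel(matrix(rnorm(n * 20), n, 20))
    rep_tab <- tryCatch(
      attr(filter_significant_idps(panel, ph, alpha = alpha), "idp_report"),
      sgwas_empty_panel = function(e) NULL)
    if (is.null(rep_tab)) {
      total <- total + 20
    } else {
      hits <- hits + sum(rep_tab$retained)
      total <- total + nrow(rep_tab)
    }
  }
  rate <- hits / total
  se <- sqrt(alpha * (1 - alpha) / total)
  expect_lt(abs(rate - alpha), 4 * se)
})

test_that("similarity TSV round-trips with sidecar metadata", {
  set.seed(2)
  panel <- make_panel(matrix(rnorm(12 * 6), 12, 6))
  V <- build_similarity(panel)
  tmp <- tempfile(fileext = ".tsv")
  write_similarity(V, tmp)
  expect_true(file.exists(paste0(tmp, ".json")))
  V2 <- read_similarity(tmp)
  expect_equal(V2$matrix, V$matrix, tolerance = 1e-12, ignore_attr = TRUE)
  meta <- jsonlite::read_json(paste0(tmp, ".json"))
  expect_equal(meta$sigma, V$sigma, tolerance = 1e-8)
})
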