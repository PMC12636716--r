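#' Genotype panel
#'
#' Additive dosage matrix (samples x variants, counted allele = A1, values
#' 0/1/2 or NA) together with variant and sample metadata.
#'
#' @param dosage Numeric matrix, samples in rows.
#' @param variants Data frame with columns `chrom, pos, id, A1, A2` (an `af`
#'   column is added/refreshed from the data).
#' @param sample_ids Character vector of sample identifiers.
#' @param provenance Optional list (source file, notes, QC log).
#' @return Object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, variants, sample_ids = rownames(dosage),
                           provenance = list()) {
  dosage <- as.matrix(dosage)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(dosage)))
  if (nrow(variants) != ncol(dosage))
    stop("variant table length must equal the number of dosage columns")
  if (length(sample_ids) != nrow(dosage))
    stop("sample table length must equal the number of dosage rows")
  need <- c("chrom", "pos", "id", "A1", "A2")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variant table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0, 1, 2 or missing")
  rownames(dosage) <- sample_ids
  colnames(dosage) <- variants$id
  variants$af <- colMeans(dosage, na.rm = TRUE) / 2
  structure(list(dosage = dosage, variants = variants,
                 sample_ids = as.character(sample_ids),
                 provenance = provenance),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("Genotype panel:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "variants\n")
  if (length(x$provenance))
    cat("  source:", x$provenance$source %||% "in-memory", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the dosage matrix
#' @param x A [genotype_panel()] or a plain matrix.
#' @return Numeric samples x variants matrix.
#' @export
dosage_matrix <- function(x) {
  if (inherits(x, "genotype_panel")) x$dosage else as.matrix(x)
}

# ---- PLINK bed/bim/fam ------------------------------------------------------
# 2-bit SNP-major codes (low bits = first sample): 00 hom A1 (dosage 2),
# 01 missing, 10 het, 11 hom A2 (dosage 0).

#' Read a PLINK bed/bim/fam fileset
#'
#' SNP-major binary genotypes; the counted allele is bim allele 1 (A1),
#' positions are 1-based, variant order is file order.
#'
#' @param prefix Path prefix (reads `prefix.bed`, `.bim`, `.fam`).
#' @return A [genotype_panel()].
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  bimdf <- utils::read.table(bim, stringsAsFactors = FALSE,
                             col.names = c("chrom", "id", "cm", "pos",
                                           "A1", "A2"))
  famdf <- utils::read.table(fam, stringsAsFactors = FALSE,
                             col.names = c("fid", "iid", "pat", "mat",
                                           "sex", "pheno"))
  if (nrow(bimdf) == 0L) stop("empty variant file: ", bim)
  n <- nrow(famdf); p <- nrow(bimdf)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("malformed PLINK bed magic bytes in ", bed, " (offset 0)")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major PLINK bed files are supported (mode byte at offset 2)")
  bpv <- ceiling(n / 4)
  if (length(raw) - 3L != bpv * p)
    stop("truncated PLINK bed: expected ", bpv * p, " data bytes, found ",
         length(raw) - 3L, " (after byte offset 3)")
  body <- as.integer(raw[-(1:3)])
  codes <- matrix(0L, nrow = bpv * 4L, ncol = p)
  m <- matrix(body, nrow = bpv, ncol = p)
  codes[seq(1, bpv * 4, by = 4), ] <- m %% 4L
  codes[seq(2, bpv * 4, by = 4), ] <- (m %/% 4L) %% 4L
  codes[seq(3, bpv * 4, by = 4), ] <- (m %/% 16L) %% 4L
  codes[seq(4, bpv * 4, by = 4), ] <- (m %/% 64L) %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  dosage <- matrix(NA_real_, n, p)
  dosage[codes == 0L] <- 2       # hom A1
  dosage[codes == 2L] <- 1       # het
  dosage[codes == 3L] <- 0       # hom A2
  genotype_panel(dosage,
                 bimdf[, c("chrom", "pos", "id", "A1", "A2")],
                 sample_ids = famdf$iid,
                 provenance = list(source = bed, format = "plink-bed"))
}

#' Write a genotype panel as PLINK bed/bim/fam
#'
#' @param panel A [genotype_panel()].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  D <- panel$dosage
  n <- nrow(D); p <- ncol(D)
  code <- matrix(1L, n, p)       # 01 = missing
  code[!is.na(D) & D == 2] <- 0L
  code[!is.na(D) & D == 1] <- 2L
  code[!is.na(D) & D == 0] <- 3L
  bpv <- ceiling(n / 4)
  pad <- matrix(0L, bpv * 4L - n, p)
  code <- rbind(code, pad)
  i1 <- seq(1, bpv * 4, by = 4)
  bytes <- code[i1, , drop = FALSE] + 4L * code[i1 + 1L, , drop = FALSE] +
    16L * code[i1 + 2L, , drop = FALSE] + 64L * code[i1 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  close(con)
  v <- panel$variants
  utils::write.table(data.frame(v$chrom, v$id, 0, v$pos, v$A1, v$A2),
                     paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(panel$sample_ids, panel$sample_ids,
                                0, 0, 0, -9),
                     paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

# ---- VCF --------------------------------------------------------------------

#' Read genotypes from a VCF
#'
#' Hard GT calls are converted to ALT-allele dosage (the counted allele A1 is
#' the ALT allele, matching the PLINK A1 convention used throughout). When a
#' `DS` FORMAT field is present and `prefer_ds = TRUE`, rounded DS dosages are
#' used instead. Multi-allelic sites are skipped (with a count) unless
#' `multiallelic = "error"`.
#'
#' @param path VCF path (may be bgzipped; parsed by the vcfR package).
#' @param prefer_ds Use the DS dosage field when present.
#' @param multiallelic `"skip"` (default) or `"error"`.
#' @return A [genotype_panel()].
#' @export
read_vcf_genotypes <- function(path, prefer_ds = FALSE,
                               multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("empty variant file: ", path)
  multi <- grepl(",", fix$ALT)
  if (any(multi) && multiallelic == "error")
    stop(sum(multi), " multi-allelic site(s) in ", path)
  gt <- NULL
  if (prefer_ds && "DS" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    gt <- round(ds)
  } else {
    g <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(x) {
      a <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
      vapply(a, function(al) {
        if (any(is.na(al)) || any(al == ".")) return(NA_real_)
        sum(al != "0")
      }, numeric(1))
    }
    gt <- apply(g, 2L, count_alt)
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  }
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (nrow(fix) == 0L) stop("no usable bi-allelic variants in ", path)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = ids, A1 = fix$ALT, A2 = fix$REF,
                         stringsAsFactors = FALSE)
  genotype_panel(t(gt), variants, sample_ids = colnames(gt),
                 provenance = list(source = path, format = "vcf",
                                   multiallelic_skipped = sum(multi)))
}

#' Read genotypes (dispatch on format)
#'
#' @param path PLINK prefix or VCF path.
#' @param format `"plink-bed"` or `"vcf"`; guessed from the extension when
#'   omitted.
#' @param ... Passed to the format reader.
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path, format = NULL, ...) {
  if (is.null(format)) {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "plink-bed"
  }
  switch(match.arg(format, c("plink-bed", "vcf")),
         "plink-bed" = read_plink(sub("\\.bed$", "", path), ...),
         "vcf" = read_vcf_genotypes(path, ...))
}

# ---- QC ---------------------------------------------------------------------

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact two-sided P-value for deviation from HWE given the genotype counts,
#' by enumerating the conditional distribution of the heterozygote count given
#' the allele counts and summing the probabilities not exceeding that of the
#' observed configuration.
#'
#' @param n_het,n_hom1,n_hom2 Genotype counts (heterozygote, two homozygotes).
#' @return Exact P-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  if (n == 0L) return(1)
  n_rare <- 2L * min(n_hom1, n_hom2) + n_het
  # heterozygote count has the parity of the rare-allele count
  hets <- seq(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
  # unnormalized log-probabilities of each possible het count
  lp <- vapply(hets, function(h) {
    r_hom <- (n_rare - h) / 2
    c_hom <- n - h - r_hom
    -(lfactorial(r_hom) + lfactorial(c_hom) + lfactorial(h)) + h * log(2)
  }, numeric(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  p_obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= p_obs + 1e-12]))
}

#' Quality-control filter for a genotype panel
#'
#' Samples with more than `sample_missing_max` missing dosages are removed
#' first; variants are then filtered on minor allele frequency and the exact
#' HWE test, both computed on the surviving samples.
#'
#' @param panel A [genotype_panel()].
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param hwe_p_min Minimum exact HWE P-value (default 1e-6).
#' @param sample_missing_max Maximum per-sample missingness fraction
#'   (default 0.20).
#' @return List with the filtered `panel` and a `report` (class
#'   `sgwas_qc_report`) reconciling input, removed and surviving counts.
#' @export
qc_filter <- function(panel, maf_min = 0.05, hwe_p_min = 1e-6,
                      sample_missing_max = 0.20) {
  stopifnot(inherits(panel, "genotype_panel"))
  D <- panel$dosage
  n0 <- nrow(D); p0 <- ncol(D)
  if (n0 == 0L || p0 == 0L) stop("empty genotype panel")
  miss_frac <- rowMeans(is.na(D))
  keep_s <- miss_frac <= sample_missing_max
  if (!any(keep_s)) stop("all samples removed by the missingness filter")
  D <- D[keep_s, , drop = FALSE]
  af <- colMeans(D, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  fail_maf <- is.na(maf) | maf < maf_min
  hwe_p <- vapply(seq_len(ncol(D)), function(j) {
    g <- D[, j]; g <- g[!is.na(g)]
    hwe_exact_test(sum(g == 1), sum(g == 2), sum(g == 0))
  }, numeric(1))
  fail_hwe <- hwe_p < hwe_p_min
  keep_v <- !fail_maf & !fail_hwe
  if (!any(keep_v)) stop("all variants removed by the MAF/HWE filters")
  out <- genotype_panel(D[, keep_v, drop = FALSE],
                        panel$variants[keep_v, , drop = FALSE],
                        sample_ids = panel$sample_ids[keep_s],
                        provenance = c(panel$provenance,
                                       list(qc = "maf/hwe/missingness")))
  report <- structure(list(
    samples_in = n0, samples_removed_missing = sum(!keep_s),
    samples_out = sum(keep_s),
    variants_in = p0,
    variants_removed_maf = sum(fail_maf),
    variants_removed_hwe = sum(fail_hwe & !fail_maf),
    variants_out = sum(keep_v),
    thresholds = list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                      sample_missing_max = sample_missing_max)),
    class = "sgwas_qc_report")
  list(panel = out, report = report)
}

#' @export
print.sgwas_qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  samples:  %d in, %d removed (missingness), %d out\n",
              x$samples_in, x$samples_removed_missing, x$samples_out))
  cat(sprintf("  variants: %d in, %d removed (MAF), %d removed (HWE), %d out\n",
              x$variants_in, x$variants_removed_maf, x$variants_removed_hwe,
              x$variants_out))
  invisible(x)
}

# ---- summary statistics -----------------------------------------------------

#' Read a GWAS summary-statistics table
#'
#' TSV/CSV with required columns `CHR, POS, A1, A2, BETA, SE` (optional `SNP,
#' P, N`). Rows with non-finite `BETA` or `SE` are dropped and counted. An
#' odds-ratio column is never silently log-transformed: a table with `OR` but
#' no `BETA` is a schema error.
#'
#' @param path File path (field separator sniffed from the header line).
#' @return Typed data frame with attribute `n_dropped`.
#' @export
read_summary_stats <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE)
  names(df) <- toupper(names(df))
  need <- c("CHR", "POS", "A1", "A2", "BETA", "SE")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    if ("OR" %in% names(df) && "BETA" %in% miss)
      stop("summary statistics contain an OR column but no BETA; refusing to ",
           "log-transform implicitly -- provide BETA on the log-odds scale")
    stop("summary statistics missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  df$POS <- as.integer(df$POS)
  df$BETA <- as.numeric(df$BETA)
  df$SE <- as.numeric(df$SE)
  ok <- is.finite(df$BETA) & is.finite(df$SE) & df$SE > 0
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Write an association table as TSV
#'
#' Standard summary-statistics layout (`CHR, POS, SNP, A1, A2, AF, N, BETA,
#' SE, SCORE, P, METHOD`), written atomically.
#'
#' @param records Association data frame (e.g. from [run_assoc()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assoc <- function(records, path) {
  df <- as.data.frame(records)
  ren <- c(chrom = "CHR", pos = "POS", id = "SNP")
  for (i in seq_along(ren))
    names(df)[names(df) == names(ren)[i]] <- ren[[i]]
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
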