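#' Conventional global-scaling size factors
#'
#' From-scratch implementations of the three conventional count normalizers
#' used as comparison baselines: upper quartile (UQ), relative log expression
#' (RLE, the median-of-ratios factor of DESeq) and trimmed mean of M-values
#' (TMM, the edgeR factor). All three return per-sample factors renormalized
#' to geometric mean 1, so that a sample's effective size is
#' `library size x factor`.
#'
#' \describe{
#'   \item{UQ}{factor proportional to the 75th percentile of the sample's
#'     counts over genes expressed in at least one sample, divided by the
#'     library size.}
#'   \item{RLE}{median over genes (positive in every sample) of the gene's
#'     count divided by its across-sample geometric mean — the DESeq
#'     size-factor statistic — divided by the library size so that, like the
#'     other two methods, the returned factor is the residual correction on
#'     top of library size (the absolute DESeq-style size factor is
#'     `factor x library size`, up to the geometric-mean-1 convention).}
#'   \item{TMM}{for each sample against a reference, gene-wise log2 count
#'     ratios M and average log2 abundances A are computed on
#'     library-size-scaled counts; the most extreme 30% of M and 5% of A are
#'     trimmed symmetrically, and the factor is 2 to the
#'     inverse-variance-weighted mean of the surviving M values
#'     (delta-method weights). The automatic reference is the sample whose
#'     upper-quartile/library-size statistic is closest to the mean of that
#'     statistic.}
#' }
#'
#' @param m count matrix: non-negative integers, genes in rows (rownames),
#'   samples in columns (colnames).
#' @return named numeric vector of per-sample factors (geometric mean 1)
#'   with attribute `method`.
#' @seealso [normalize_matrix()]
#' @export
#' @examples
#' m <- matrix(rpois(40, 50), 10, 4,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' size_factors_uq(m)
size_factors_uq <- function(m) {
  m <- check_count_matrix(m)
  if (all(m == 0)) stop_snv("UQ: all-zero count matrix")
  expressed <- rowSums(m) > 0
  lib <- colSums(m)
  q75 <- apply(m[expressed, , drop = FALSE], 2, quantile, probs = 0.75)
  if (any(q75 == 0))
    stop_snv("UQ: a sample has upper quartile 0 over expressed genes")
  as_size_factors(q75 / lib, "UQ")
}

#' @rdname size_factors_uq
#' @export
size_factors_rle <- function(m) {
  m <- check_count_matrix(m)
  allpos <- rowSums(m == 0) == 0
  if (!any(allpos))
    stop_snv("RLE: no gene has positive counts in every sample")
  logm <- log(m[allpos, , drop = FALSE])
  loggeo <- rowMeans(logm)
  f <- apply(exp(logm - loggeo), 2, median) / colSums(m)
  as_size_factors(f, "RLE")
}

#' @rdname size_factors_uq
#' @param ref_sample `"auto"` or the name/index of the reference sample.
#' @param trim_M fraction of genes trimmed from each usage-weighted extreme
#'   of the log-ratio distribution (default 0.30).
#' @param trim_A trim fraction on average log abundance (default 0.05).
#' @export
size_factors_tmm <- function(m, ref_sample = "auto",
                             trim_M = 0.30, trim_A = 0.05) {
  m <- check_count_matrix(m)
  lib <- colSums(m)
  if (any(lib == 0)) stop_snv("TMM: a sample has library size 0")
  if (identical(ref_sample, "auto")) {
    expressed <- rowSums(m) > 0
    f75 <- apply(m[expressed, , drop = FALSE], 2, quantile, probs = 0.75) / lib
    ref <- which.min(abs(f75 - mean(f75)))
  } else {
    ref <- if (is.character(ref_sample)) match(ref_sample, colnames(m)) else ref_sample
    if (is.na(ref) || ref < 1 || ref > ncol(m))
      stop_snv("TMM: unknown reference sample")
  }
  f <- vapply(seq_len(ncol(m)), function(j) {
    tmm_pair(m[, j], m[, ref], lib[j], lib[ref], trim_M, trim_A)
  }, numeric(1))
  names(f) <- colnames(m)
  as_size_factors(f, "TMM")
}

# one-sample-vs-reference TMM factor (Robinson-Oshlack weighted trimmed mean)
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_M, trim_A) {
  pos <- obs > 0 & ref > 0
  obs <- obs[pos]; ref <- ref[pos]
  if (!length(obs)) stop_snv("TMM: no gene positive in both sample and reference")
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  if (max(abs(M)) < 1e-6) return(1)
  w <- 1 / ((n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref))
  n <- length(M)
  loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) stop_snv("TMM: no genes survive trimming")
  2^(sum(M[keep] * w[keep]) / sum(w[keep]))
}

as_size_factors <- function(f, method) {
  f <- f / exp(mean(log(f)))
  structure(f, method = method, class = "size_factors")
}

#' @export
print.size_factors <- function(x, ...) {
  cat(attr(x, "method"), "size factors (geometric mean 1):\n")
  print(round(unclass(x), 4))
  invisible(x)
}

check_count_matrix <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop_snv("count matrix contains negative values")
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop_snv("count matrix has duplicated gene or sample ids")
  m
}

#' Normalize a count matrix by size factors
#'
#' Scales counts to CPM-style values on the effective library size:
#' `counts[g, j] / (libsize_j * factor_j) * 1e6`.
#'
#' @param m count matrix (genes x samples).
#' @param f size factors from one of the `size_factors_*` functions (or any
#'   positive per-sample vector).
#' @return matrix of normalized values, same dimnames and row order as `m`.
#' @export
normalize_matrix <- function(m, f) {
  m <- check_count_matrix(m)
  if (length(f) != ncol(m)) stop_snv("one size factor per sample required")
  if (any(f <= 0)) stop_snv("size factors must be positive")
  lib <- colSums(m)
  t(t(m) / (lib * as.numeric(f))) * 1e6
}

#' Read and write gene x sample count matrices
#'
#' TSV with a header; first column `gene`, one column per sample.
#'
#' @param m count matrix.
#' @param path file path.
#' @return `write_count_matrix` returns `path` invisibly;
#'   `read_count_matrix` returns the matrix.
#' @export
write_count_matrix <- function(m, path) {
  m <- check_count_matrix(m)
  dt <- data.table(gene = rownames(m))
  for (j in colnames(m)) dt[, (j) := m[, j]]
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  x <- fread(path, sep = "\t")
  if (names(x)[1] != "gene")
    stop_snv("count-matrix file ", path, " must have 'gene' as first column")
  m <- as.matrix(x[, -1])
  rownames(m) <- x$gene
  check_count_matrix(m)
}
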