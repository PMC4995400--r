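#' Coefficient of variation, in percent
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation. ND
#' (`NA`) values are excluded before computing.
#'
#' @param values numeric vector.
#' @return CV in percent. Errors if fewer than 2 defined values remain or the
#'   mean is 0.
#' @export
#' @examples
#' cv(c(1, 3))   # 70.71068
cv <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 2) stop_snv("cv: need at least 2 defined values")
  m <- mean(x)
  if (m == 0) stop_snv("cv: mean is zero")
  100 * sd(x) / m
}

#' Agreement between two sets of per-gene values
#'
#' For genes defined in both inputs, forms the per-gene ratio
#' `values1 / values2` and summarizes it by its mean and CV — the agreement
#' statistic used to compare technical replicates (mean near 1 and a low CV
#' indicate reproducible normalized values).
#'
#' @param values1,values2 numeric vectors named by gene; `NA` marks ND.
#' @return list `n_genes` (genes used), `mean_ratio` (mean of per-gene
#'   ratios) and `cv` (CV of the per-gene ratios, percent).
#' @export
#' @examples
#' v <- c(g1 = 2, g2 = 3, g3 = 0.5)
#' agreement(v, v)   # mean_ratio 1, cv 0
agreement <- function(values1, values2) {
  stopifnot(!is.null(names(values1)), !is.null(names(values2)))
  shared <- intersect(names(values1)[!is.na(values1)],
                      names(values2)[!is.na(values2)])
  shared <- shared[values2[shared] > 0]
  if (length(shared) < 2)
    stop_snv("agreement: need at least 2 genes defined in both inputs")
  r <- as.numeric(values1[shared]) / as.numeric(values2[shared])
  list(n_genes = length(shared), mean_ratio = mean(r), cv = cv(r))
}

#' Pearson correlation of two sets of per-gene values
#'
#' @param values1,values2 numeric vectors named by gene.
#' @param log_transform correlate on log10 scale; pairs with a nonpositive
#'   value on either side are dropped first.
#' @return list `pearson_r`, `r_squared`, `n` (pairs used).
#' @export
correlation <- function(values1, values2, log_transform = FALSE) {
  stopifnot(!is.null(names(values1)), !is.null(names(values2)))
  shared <- intersect(names(values1)[!is.na(values1)],
                      names(values2)[!is.na(values2)])
  x <- as.numeric(values1[shared]); y <- as.numeric(values2[shared])
  if (log_transform) {
    ok <- x > 0 & y > 0
    x <- log10(x[ok]); y <- log10(y[ok])
  }
  if (length(x) < 3) stop_snv("correlation: need at least 3 shared finite pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop_snv("correlation: zero variance on one side")
  r <- cor(x, y)
  list(pearson_r = r, r_squared = r^2, n = length(x))
}

#' Coverage flattening by SNV normalization
#'
#' Positional biases skew the raw read distribution along a transcript; the
#' per-locus human/chimp ratios should be flat because both species
#' experience the same bias at the same locus. Flatness is quantified as a
#' within-transcript CV (an artifact-defined scalar for what is usually
#' inspected visually): `raw_cv` over per-position total depth, `snv_cv`
#' over per-locus SNV ratios (defined ratios only). Transcripts with fewer
#' than 2 usable loci are skipped with a message.
#'
#' @param mixed pileup data.frame of the mixed sample (full, not
#'   position-restricted, so that raw coverage is represented).
#' @param positions informative positions.
#' @param counts optional precomputed [count_alleles()] result for
#'   `mixed`/`positions`; computed if missing.
#' @return list `report` (data.frame `transcript, n_loci, raw_cv, snv_cv`)
#'   and `profile` (per-position table `transcript, pos0, depth, snv_ratio`
#'   with `snv_ratio` `NA` away from informative loci) for plotting.
#' @export
flatten_profile <- function(mixed, positions, counts = NULL) {
  if (is.null(counts)) counts <- count_alleles(mixed, positions)
  lr <- locus_ratio(counts)
  depth_df <- data.frame(transcript = mixed$transcript, pos0 = mixed$pos0,
                         depth = pileup_depth(mixed), stringsAsFactors = FALSE)

  ratio_by_tx <- split(lr[!is.na(lr$value), c("pos0", "value")],
                       lr$transcript[!is.na(lr$value)])
  depth_by_tx <- split(depth_df[, c("pos0", "depth")], depth_df$transcript)

  rows <- lapply(names(ratio_by_tx), function(tx) {
    vals <- ratio_by_tx[[tx]]$value
    if (length(vals) < 2) {
      message("flatten_profile: skipping ", tx, " (<2 usable loci)")
      return(NULL)
    }
    d <- depth_by_tx[[tx]]$depth
    data.frame(transcript = tx, n_loci = length(vals),
               raw_cv = cv(d), snv_cv = cv(vals), stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(report))
    report <- data.frame(transcript = character(), n_loci = integer(),
                         raw_cv = numeric(), snv_cv = numeric())
  profile <- merge(depth_df, lr[, c("transcript", "pos0", "value")],
                   by = c("transcript", "pos0"), all.x = TRUE)
  names(profile)[names(profile) == "value"] <- "snv_ratio"
  profile <- profile[order(profile$transcript, profile$pos0), , drop = FALSE]
  rownames(profile) <- NULL
  list(report = report, profile = profile)
}

#' Count loci/genes where two fold-change estimates disagree
#'
#' A key is discordant when the two estimates differ by more than `factor`
#' (strictly; an exactly `factor`-fold difference is concordant). Symmetric
#' in its two arguments; keys undefined (ND) or nonpositive on either side
#' are excluded.
#'
#' @param folds1,folds2 numeric fold-change vectors named by locus/gene.
#' @param factor discordance threshold (default 2).
#' @return list `n_discordant`, `n_compared`.
#' @export
discordance_count <- function(folds1, folds2, factor = 2) {
  stopifnot(!is.null(names(folds1)), !is.null(names(folds2)), factor >= 1)
  shared <- intersect(names(folds1)[!is.na(folds1) & folds1 > 0],
                      names(folds2)[!is.na(folds2) & folds2 > 0])
  f1 <- as.numeric(folds1[shared]); f2 <- as.numeric(folds2[shared])
  list(n_discordant = sum(pmax(f1 / f2, f2 / f1) > factor),
       n_compared = length(shared))
}

#' Housekeeping-gene CV comparison across normalization methods
#'
#' Normalizers cannot be compared value-by-value (global scaling yields
#' normalized counts, the SNV method yields human:chimp ratios), so they are
#' compared indirectly: for a set of genes expected to be stable
#' (housekeeping genes), the per-gene CV across technical replicates of each
#' method's normalized value is computed, and the methods' CV distributions
#' are summarized side by side. Lower CVs mean the method removed more
#' between-replicate variation.
#'
#' @param counts gene x replicate count matrix (input to the global-scaling
#'   baselines).
#' @param snv_values gene x replicate matrix of per-transcript SNV ratios
#'   (`NA` = ND); rows must be named like `counts` rows.
#' @param hk_genes character vector of housekeeping gene ids.
#' @param methods subset of `c("UQ", "RLE", "TMM", "SNV")`.
#' @return list `summary` (data.frame `method, n, min, q1, median, q3, max`
#'   of per-gene CVs) and `cvs` (named list of per-gene CV vectors).
#' @export
hk_cv_compare <- function(counts, snv_values, hk_genes,
                          methods = c("UQ", "RLE", "TMM", "SNV")) {
  methods <- match.arg(methods, several.ok = TRUE)
  counts <- check_count_matrix(counts)
  if (ncol(counts) < 2) stop_snv("hk_cv_compare: need >= 2 replicates")
  hk <- intersect(hk_genes, rownames(counts))
  if (!length(hk)) stop_snv("hk_cv_compare: housekeeping list does not intersect matrix genes")

  row_cvs <- function(m) {
    ok <- rowSums(is.na(m)) == 0 & rowMeans(m, na.rm = TRUE) > 0
    apply(m[ok, , drop = FALSE], 1, cv)
  }
  cvs <- list()
  for (meth in methods) {
    cvs[[meth]] <- if (meth == "SNV") {
      sv <- snv_values[intersect(hk, rownames(snv_values)), , drop = FALSE]
      row_cvs(sv)
    } else {
      f <- switch(meth, UQ = size_factors_uq(counts),
                  RLE = size_factors_rle(counts),
                  TMM = size_factors_tmm(counts))
      row_cvs(normalize_matrix(counts, f)[hk, , drop = FALSE])
    }
  }
  summary <- do.call(rbind, lapply(names(cvs), function(meth) {
    q <- quantile(cvs[[meth]], c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(method = meth, n = length(cvs[[meth]]),
               min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, cvs = cvs)
}
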