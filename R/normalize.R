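#' Per-locus SNV-normalized expression values
#'
#' The normalized value at an informative position is the human read count
#' divided by the chimpanzee read count. Because both species' reads at a
#' locus passed through the same extraction, library preparation and
#' sequencing, any multiplicative locus-level bias cancels in the ratio. The
#' value is not determined (ND, stored as `NA`) when the chimpanzee
#' denominator is zero; `n_other` never enters the ratio.
#'
#' @param counts allele-count data.frame from [count_alleles()].
#' @return the input with columns `value` (`n_human / n_chimp`, `NA` when
#'   `n_chimp == 0`) and `scope = "locus"` appended.
#' @export
#' @examples
#' locus_ratio(data.frame(transcript = "tx1", pos0 = 1L,
#'                        n_human = 80L, n_chimp = 40L, n_other = 0L))$value
locus_ratio <- function(counts) {
  stopifnot(all(c("n_human", "n_chimp") %in% names(counts)))
  counts$value <- ifelse(counts$n_chimp > 0,
                         counts$n_human / counts$n_chimp, NA_real_)
  counts$scope <- "locus"
  counts
}

#' Per-transcript SNV-normalized expression values
#'
#' Reads over all informative loci of a transcript are discriminatively
#' summed into total human and total chimpanzee counts, and the summed human
#' count is divided by the summed chimpanzee count. Summing before dividing
#' (rather than averaging per-locus ratios) pools coverage, so individual
#' zero-denominator loci do not make the transcript value ND.
#'
#' @param counts allele-count data.frame from [count_alleles()] (any number
#'   of transcripts; rows are grouped by `transcript`).
#' @return data.frame `transcript, n_loci, n_human, n_chimp, value, scope`
#'   with one row per transcript; `value` is `NA` (ND) when the summed
#'   chimpanzee count is 0.
#' @export
#' @examples
#' x <- data.frame(transcript = "tx1", pos0 = c(10L, 20L),
#'                 n_human = c(10L, 30L), n_chimp = c(5L, 15L),
#'                 n_other = 0L)
#' transcript_ratio(x)$value   # 40 / 20 = 2
transcript_ratio <- function(counts) {
  stopifnot(all(c("transcript", "n_human", "n_chimp") %in% names(counts)))
  dt <- as.data.table(counts)
  agg <- dt[, .(n_loci = .N, n_human = sum(n_human), n_chimp = sum(n_chimp)),
            by = transcript]
  agg[, value := ifelse(n_chimp > 0, n_human / n_chimp, NA_real_)]
  setorder(agg, transcript)
  out <- as.data.frame(agg)
  out$scope <- "transcript"
  out
}

#' Apply the low-count cutoff
#'
#' Low read counts inflate technical noise in ratio estimates, so transcripts
#' are retained only when both species' summed counts reach the threshold
#' (default 40, roughly RPKM 2.8 at the reference sequencing depth).
#' Requiring both sides guards the denominator; the boundary is inclusive.
#'
#' @param ratios data.frame with `n_human` and `n_chimp` columns (locus or
#'   transcript scope).
#' @param threshold minimum count for each species (default 40).
#' @return the retained subset of rows.
#' @export
apply_cutoff <- function(ratios, threshold = 40) {
  stopifnot(threshold >= 0)
  keep <- pmin(ratios$n_human, ratios$n_chimp) >= threshold
  ratios[keep, , drop = FALSE]
}

#' Differential expression from two spiked samples
#'
#' The fold change of a transcript between two samples is the ratio of its
#' SNV-normalized values. Since both samples carry spike RNA from the same
#' batch, the chimpanzee denominators represent the same molecules and the
#' fold change is free of library-size and locus-level biases. ND
#' propagates: the fold is `NA` unless both values are defined and the
#' sample-2 value is positive.
#'
#' @param r1,r2 per-transcript ratio data.frames from [transcript_ratio()]
#'   (typically after [apply_cutoff()]).
#' @return data.frame `transcript, ratio_s1, ratio_s2, fold`, containing
#'   every transcript present in either input (absent side is ND).
#' @export
differential_expression <- function(r1, r2) {
  m <- merge(r1[, c("transcript", "value")], r2[, c("transcript", "value")],
             by = "transcript", all = TRUE, suffixes = c("_1", "_2"))
  fold <- ifelse(!is.na(m$value_1) & !is.na(m$value_2) & m$value_2 > 0,
                 m$value_1 / m$value_2, NA_real_)
  data.frame(transcript = m$transcript,
             ratio_s1 = m$value_1, ratio_s2 = m$value_2, fold = fold,
             stringsAsFactors = FALSE)
}

#' Naive library-size-normalized fold change
#'
#' The conventional comparator: counts are divided by their library size and
#' the two normalized counts are divided. Vectorized.
#'
#' @param count1,count2 read counts in samples 1 and 2.
#' @param libsize1,libsize2 library sizes (> 0).
#' @return fold changes; `NA` (ND) where `count2 == 0`.
#' @export
unnormalized_fold <- function(count1, count2, libsize1, libsize2) {
  stopifnot(all(libsize1 > 0), all(libsize2 > 0))
  ifelse(count2 > 0, (count1 / libsize1) / (count2 / libsize2), NA_real_)
}

#' Reads per kilobase per million mapped reads
#'
#' @param count read count for the transcript.
#' @param transcript_length transcript length in bp (> 0).
#' @param total_mapped total mapped reads in the library (> 0).
#' @return `1e9 * count / (transcript_length * total_mapped)`.
#' @export
#' @examples
#' rpkm(40, 1000, 1e7)   # 4
rpkm <- function(count, transcript_length, total_mapped) {
  stopifnot(all(transcript_length > 0), all(total_mapped > 0))
  1e9 * count / (transcript_length * total_mapped)
}

#' Read and write SNV-ratio and fold tables
#'
#' Ratio TSV: `transcript n_human n_chimp snv_ratio`; fold TSV:
#' `transcript ratio_s1 ratio_s2 fold`. ND is rendered as the literal `ND`.
#'
#' @param ratios per-transcript ratio data.frame.
#' @param folds fold data.frame from [differential_expression()].
#' @param path file path.
#' @return writers return `path` invisibly; readers return the data.frame
#'   with ND decoded to `NA`.
#' @export
write_ratios <- function(ratios, path) {
  out <- data.table(transcript = ratios$transcript,
                    n_human = ratios$n_human, n_chimp = ratios$n_chimp,
                    snv_ratio = nd_encode(ratios$value))
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_ratios
#' @export
read_ratios <- function(path) {
  x <- fread(path, sep = "\t", colClasses = list(character = "snv_ratio"))
  data.frame(transcript = x$transcript,
             n_human = x$n_human, n_chimp = x$n_chimp,
             value = nd_decode(x$snv_ratio),
             scope = "transcript", stringsAsFactors = FALSE)
}

#' @rdname write_ratios
#' @export
write_folds <- function(folds, path) {
  out <- data.table(transcript = folds$transcript,
                    ratio_s1 = nd_encode(folds$ratio_s1),
                    ratio_s2 = nd_encode(folds$ratio_s2),
                    fold = nd_encode(folds$fold))
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_ratios
#' @export
read_folds <- function(path) {
  x <- fread(path, sep = "\t", colClasses = list(
    character = c("ratio_s1", "ratio_s2", "fold")))
  data.frame(transcript = x$transcript,
             ratio_s1 = nd_decode(x$ratio_s1),
             ratio_s2 = nd_decode(x$ratio_s2),
             fold = nd_decode(x$fold), stringsAsFactors = FALSE)
}
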