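#' Count species alleles at informative positions in a mixed sample
#'
#' At each informative position, reads showing the human allele are counted
#' as `n_human`, reads showing the chimpanzee allele as `n_chimp`, and reads
#' showing either remaining base as `n_other` (sequencing errors; excluded
#' from all downstream ratios). Classification is per position, not per
#' read: a read overlapping k informative positions contributes k allele
#' observations. Positions with no coverage yield `(0, 0, 0)`.
#'
#' @param mixed pileup data.frame of the mixed (spiked) sample.
#' @param positions informative positions (`transcript, pos0, human_base,
#'   chimp_base`), from [find_informative()] or [read_informative_bed()].
#' @return data.frame `transcript, pos0, human_base, chimp_base, n_human,
#'   n_chimp, n_other`, one row per informative position, ordered.
#'   `n_human + n_chimp + n_other` equals the pileup depth at that position.
#' @export
#' @examples
#' mixed <- data.frame(transcript = "tx1", pos0 = 7L,
#'                     A = 30L, C = 0L, G = 10L, T = 1L)
#' pos <- data.frame(transcript = "tx1", pos0 = 7L,
#'                   human_base = "A", chimp_base = "G")
#' count_alleles(mixed, pos)   # n_human 30, n_chimp 10, n_other 1
count_alleles <- function(mixed, positions) {
  stopifnot(all(c("transcript", "pos0", "human_base", "chimp_base")
                %in% names(positions)))
  m <- merge(positions, mixed, by = c("transcript", "pos0"), all.x = TRUE)
  counts <- as.matrix(m[, BASES])
  counts[is.na(counts)] <- 0L
  ridx <- seq_len(nrow(m))
  n_h <- counts[cbind(ridx, match(m$human_base, BASES))]
  n_c <- counts[cbind(ridx, match(m$chimp_base, BASES))]
  out <- data.frame(
    transcript = m$transcript, pos0 = m$pos0,
    human_base = m$human_base, chimp_base = m$chimp_base,
    n_human = as.integer(n_h), n_chimp = as.integer(n_c),
    n_other = as.integer(rowSums(counts) - n_h - n_c),
    stringsAsFactors = FALSE)
  out <- out[order(out$transcript, out$pos0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and write allele-count tables
#'
#' Tab-separated with header
#' `transcript pos0 human_base chimp_base n_human n_chimp n_other`.
#'
#' @param counts allele-count data.frame from [count_alleles()].
#' @param path file path.
#' @return `write_allele_counts` returns `path` invisibly;
#'   `read_allele_counts` returns the data.frame.
#' @export
write_allele_counts <- function(counts, path) {
  need <- c("transcript", "pos0", "human_base", "chimp_base",
            "n_human", "n_chimp", "n_other")
  stopifnot(all(need %in% names(counts)))
  fwrite(as.data.table(counts)[, need, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' @rdname write_allele_counts
#' @export
read_allele_counts <- function(path) {
  x <- fread(path, sep = "\t")
  need <- c("transcript", "pos0", "human_base", "chimp_base",
            "n_human", "n_chimp", "n_other")
  if (!all(need %in% names(x)))
    stop_snv("allele-count file ", path, " lacks columns: ",
             paste(setdiff(need, names(x)), collapse = ", "))
  as.data.frame(x[, need, with = FALSE])
}
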