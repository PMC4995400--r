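#' Major allele of a pileup column
#'
#' @param column base counts at one position: a named numeric vector with
#'   names among `A, C, G, T`, or a one-row pileup data.frame.
#' @return list with `base` (the base with maximal count; ties broken by the
#'   fixed order A < C < G < T) and `freq` (its count divided by depth).
#' @export
#' @examples
#' major_allele(c(A = 19, G = 1))   # A, 0.95
major_allele <- function(column) {
  counts <- column_counts(column)
  depth <- sum(counts)
  if (depth <= 0) stop_snv("major_allele: column has zero depth")
  i <- which.max(counts)          # which.max takes the first maximum: A<C<G<T
  list(base = BASES[i], freq = unname(counts[i] / depth))
}

#' Homozygosity test for a pileup column
#'
#' A position is treated as homozygous when its major allele reaches at least
#' 90% of the depth — a tolerance for up to 10% sequencing error that also
#' excludes heterozygous loci (whose major-allele frequency is near 50%).
#'
#' @inheritParams major_allele
#' @param threshold minimum major-allele frequency (default 0.90, inclusive).
#' @return `TRUE` iff depth > 0 and major-allele frequency >= `threshold`.
#' @export
#' @examples
#' passes_homozygosity(c(A = 9, G = 1))   # TRUE: exactly 90%
#' passes_homozygosity(c(A = 8, G = 2))   # FALSE
passes_homozygosity <- function(column, threshold = 0.90) {
  counts <- column_counts(column)
  depth <- sum(counts)
  if (depth <= 0) return(FALSE)
  max(counts) / depth >= threshold
}

column_counts <- function(column) {
  if (is.data.frame(column)) {
    stopifnot(nrow(column) == 1L)
    counts <- as.numeric(column[1, BASES])
  } else {
    counts <- setNames(numeric(4), BASES)
    counts[names(column)] <- column
  }
  names(counts) <- BASES
  counts
}

#' Identify informative interspecies SNV positions
#'
#' Compares three single-species pileups — two pure human samples (e.g.
#' fibroblast and iPSC) and one pure chimpanzee sample — and keeps a position
#' iff (i) depth is at least `min_depth` in all three, (ii) all three are
#' homozygous (major allele at least `threshold`), and (iii) the two human
#' samples share the same major allele while the chimpanzee major allele
#' differs. The result is the set of positions at which a read's base reveals
#' its species of origin.
#'
#' @param hf,hi pileups of the two pure human samples.
#' @param cl pileup of the pure chimpanzee sample (aligned to the human
#'   reference).
#' @param min_depth minimum depth in each of the three pileups (default 10).
#' @param threshold homozygosity threshold (default 0.90).
#' @return data.frame `transcript, pos0, human_base, chimp_base`, ordered;
#'   possibly empty. Swapping `hf` and `hi` gives the identical set.
#' @export
find_informative <- function(hf, hi, cl, min_depth = 10, threshold = 0.90) {
  a <- pileup_calls(hf); b <- pileup_calls(hi); c_ <- pileup_calls(cl)
  m <- merge(merge(a, b, by = c("transcript", "pos0"),
                   suffixes = c("_hf", "_hi")),
             c_, by = c("transcript", "pos0"))
  keep <- m$depth_hf >= min_depth & m$depth_hi >= min_depth & m$depth >= min_depth &
    m$freq_hf >= threshold & m$freq_hi >= threshold & m$freq >= threshold &
    m$base_hf == m$base_hi & m$base != m$base_hf
  out <- data.frame(transcript = m$transcript[keep], pos0 = m$pos0[keep],
                    human_base = m$base_hf[keep], chimp_base = m$base[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$transcript, out$pos0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# vectorized per-row major-allele call over a whole pileup
pileup_calls <- function(pileup) {
  counts <- as.matrix(pileup[, BASES, drop = FALSE])
  depth <- rowSums(counts)
  i <- max.col(counts, ties.method = "first")   # first maximum: A<C<G<T order
  data.frame(transcript = pileup$transcript, pos0 = pileup$pos0,
             depth = depth, base = BASES[i],
             freq = ifelse(depth > 0, counts[cbind(seq_len(nrow(counts)), i)] / depth, 0),
             stringsAsFactors = FALSE)
}

#' Read and write informative positions as BED
#'
#' One row per position, 0-based half-open, with the diagnostic alleles in
#' the name field: `transcript  pos0  pos0+1  HUMANBASE>CHIMPBASE`.
#'
#' @param positions data.frame `transcript, pos0, human_base, chimp_base`.
#' @param path file path.
#' @return `write_informative_bed` returns `path` invisibly;
#'   `read_informative_bed` returns the positions data.frame.
#' @export
#' @examples
#' f <- tempfile(fileext = ".bed")
#' write_informative_bed(
#'   data.frame(transcript = "tx1", pos0 = 41L,
#'              human_base = "A", chimp_base = "G"), f)
#' readLines(f)   # "tx1\t41\t42\tA>G"
write_informative_bed <- function(positions, path) {
  stopifnot(all(c("transcript", "pos0", "human_base", "chimp_base")
                %in% names(positions)))
  if (any(positions$human_base == positions$chimp_base))
    stop_snv("informative position with identical human and chimp base")
  bed <- data.table(
    chrom = positions$transcript,
    start = as.integer(positions$pos0),
    end = as.integer(positions$pos0) + 1L,
    name = paste0(positions$human_base, ">", positions$chimp_base))
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_informative_bed
#' @export
read_informative_bed <- function(path) {
  bed <- fread(path, sep = "\t", header = FALSE,
               col.names = c("chrom", "start", "end", "name"))
  bad <- which(!grepl("^[ACGT]>[ACGT]$", bed$name))
  if (length(bad))
    stop_snv("malformed allele name field in ", path, " at line ", bad[1],
             ": '", bed$name[bad[1]], "'")
  hb <- substr(bed$name, 1, 1)
  cb <- substr(bed$name, 3, 3)
  same <- which(hb == cb)
  if (length(same))
    stop_snv("human and chimp allele identical in ", path, " at line ", same[1])
  if (any(bed$end != bed$start + 1L))
    stop_snv("informative-position BED must have single-base intervals (",
             path, ")")
  data.frame(transcript = bed$chrom, pos0 = bed$start,
             human_base = hb, chimp_base = cb, stringsAsFactors = FALSE)
}
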