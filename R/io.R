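#' Read and write transcript references as FASTA
#'
#' Thin wrappers around Biostrings keeping the package's internal
#' representation (a named character vector) at the interface.
#'
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @return `write_fasta` returns `path` invisibly; `read_fasta` returns a
#'   named character vector.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write simulated reads as FASTQ
#'
#' Qualities are constant, Sanger-scaled from the simulator's error rate
#' (`Q = round(-10 log10 e)`, capped at 40; Q40 when the error rate is 0).
#'
#' @param placements placements table from [sample_reads()].
#' @param path output FASTQ path.
#' @param error_rate per-base error rate used to derive the constant quality.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(placements, path, error_rate = 0) {
  q <- if (error_rate > 0) min(40L, as.integer(round(-10 * log10(error_rate)))) else 40L
  qchar <- rawToChar(as.raw(q + 33L))
  qual <- strrep(qchar, placements$length)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", placements$read_id, "\n", placements$seq,
                    "\n+\n", qual), con)
  invisible(path)
}

#' Read and write read-placement tables
#'
#' Placements are the simulator's alignment records: tab-separated with
#' header `read_id species transcript start0 length seq`, 0-based starts.
#'
#' @param placements placements table.
#' @param path file path.
#' @return `write_placements` returns `path` invisibly; `read_placements`
#'   returns a data.table.
#' @export
write_placements <- function(placements, path) {
  need <- c("read_id", "species", "transcript", "start0", "length", "seq")
  stopifnot(all(need %in% names(placements)))
  fwrite(as.data.table(placements)[, need, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' @rdname write_placements
#' @export
read_placements <- function(path) {
  pl <- fread(path, sep = "\t", colClasses = list(
    character = c("read_id", "species", "transcript", "seq"),
    integer = c("start0", "length")))
  need <- c("read_id", "species", "transcript", "start0", "length", "seq")
  if (!all(need %in% names(pl)))
    stop_snv("placement file ", path, " lacks required columns: ",
             paste(setdiff(need, names(pl)), collapse = ", "))
  pl
}

#' Write simulator ground truth to a directory
#'
#' Emits `truth_snv.bed` (informative-position format, see
#' [write_informative_bed()]) and `truth_abundance.tsv`.
#'
#' @param truth a `sim_truth`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_informative_bed(truth$snv, file.path(dir, "truth_snv.bed"))
  fwrite(truth$abundance, file.path(dir, "truth_abundance.tsv"), sep = "\t")
  invisible(dir)
}

# shared TSV helpers: ND encoding -------------------------------------------

nd_encode <- function(x, digits = 6) {
  ifelse(is.na(x), ND_TOKEN, formatC(x, digits = digits, format = "g"))
}

nd_decode <- function(x) {
  out <- suppressWarnings(as.numeric(ifelse(x == ND_TOKEN, NA, x)))
  bad <- which(!is.na(x) & x != ND_TOKEN & is.na(out))
  if (length(bad))
    stop_snv("non-numeric value that is not '", ND_TOKEN, "' at row ", bad[1])
  out
}
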