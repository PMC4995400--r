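#' Build per-position base counts from read placements
#'
#' Tallies, for every covered reference position, how many overlapping reads
#' show each base — the functional equivalent of a samtools pileup for the
#' simulator's ungapped placements, with no depth cap and no quality
#' filtering. Positions with zero depth are omitted.
#'
#' @param placements placements table (`read_id, species, transcript, start0,
#'   length, seq`), e.g. from [sample_reads()] or [read_placements()].
#' @param reference named character vector of reference sequences; used for
#'   coordinate validation (counts record the observed read base, not the
#'   reference base).
#' @param positions optional data.frame (`transcript, pos0`) restricting the
#'   pileup to those positions (like `mpileup -l`); much cheaper than a full
#'   pileup when only informative positions are needed.
#' @return data.frame `transcript, pos0, A, C, G, T`, ordered by transcript
#'   then position; one row per covered position.
#' @export
#' @examples
#' ref <- c(tx1 = "ACGTACGTAC")
#' pl <- data.frame(read_id = "r1", species = "human", transcript = "tx1",
#'                  start0 = 5L, length = 4L, seq = "CGTA")
#' build_pileup(pl, ref)
build_pileup <- function(placements, reference, positions = NULL) {
  pl <- as.data.table(placements)
  unknown <- setdiff(unique(pl$transcript), names(reference))
  if (length(unknown))
    stop_snv("placements reference unknown transcript(s): ",
             paste(head(unknown, 5), collapse = ", "))
  too_far <- pl$start0 + pl$length > nchar(reference)[pl$transcript] |
    pl$start0 < 0
  if (any(too_far))
    stop_snv("placement outside transcript bounds (first offender: read ",
             pl$read_id[which(too_far)[1]], ")")

  if (is.null(positions)) {
    # chunked so the exploded (position, base) table never exceeds ~10M rows
    chunk <- max(1L, floor(1e7 / max(pl$length)))
    starts <- seq(1L, nrow(pl), by = chunk)
    parts <- lapply(starts, function(s) {
      pc <- pl[s:min(s + chunk - 1L, nrow(pl))]
      obs <- data.table(
        transcript = rep(pc$transcript, pc$length),
        pos0 = rep(pc$start0, pc$length) + sequence(pc$length) - 1L,
        base = unlist(strsplit(pc$seq, "", fixed = TRUE), use.names = FALSE))
      obs <- obs[base %in% BASES]
      obs[, .N, by = .(transcript, pos0, base)]
    })
    counts <- rbindlist(parts)[, .(N = sum(N)), by = .(transcript, pos0, base)]
  } else {
    P <- as.data.table(positions)[, .(transcript, pos0)]
    pl[, `:=`(s0 = start0, e0 = start0 + length - 1L)]
    obs <- pl[P, on = .(transcript, s0 <= pos0, e0 >= pos0), nomatch = NULL,
              .(transcript, pos0 = i.pos0,
                base = substr(seq, i.pos0 - start0 + 1L, i.pos0 - start0 + 1L))]
    pl[, c("s0", "e0") := NULL]
    obs <- obs[base %in% BASES]
    counts <- obs[, .N, by = .(transcript, pos0, base)]
  }
  wide <- data.table::dcast(counts, transcript + pos0 ~ base,
                            value.var = "N", fill = 0L)
  for (b in BASES) if (!b %in% names(wide)) wide[, (b) := 0L]
  setorder(wide, transcript, pos0)
  as.data.frame(wide[, c("transcript", "pos0", BASES), with = FALSE])
}

#' Total depth of each pileup row
#' @param pileup a pileup data.frame.
#' @return integer vector of per-row depths (sum of the four base counts).
#' @export
pileup_depth <- function(pileup) {
  as.integer(rowSums(pileup[, BASES, drop = FALSE]))
}

#' Merge two pileups by element-wise addition
#'
#' Per-position counts are summed — the in-silico analogue of pooling two
#' read sets (e.g. the two mates of paired-end data) to increase depth.
#' Merging is commutative and the empty pileup is its identity.
#'
#' @param p1,p2 pileup data.frames over the same reference.
#' @return merged pileup data.frame.
#' @export
merge_pileups <- function(p1, p2) {
  both <- rbindlist(list(as.data.table(p1), as.data.table(p2)))
  if (nrow(both) == 0L) return(empty_pileup())
  merged <- both[, lapply(.SD, function(x) as.integer(sum(x))),
                 by = .(transcript, pos0), .SDcols = BASES]
  setorder(merged, transcript, pos0)
  as.data.frame(merged)
}

empty_pileup <- function() {
  data.frame(transcript = character(), pos0 = integer(),
             A = integer(), C = integer(), G = integer(), T = integer(),
             stringsAsFactors = FALSE)
}

#' Read and write pileup tables
#'
#' Tab-separated with header `transcript pos0 A C G T`; 0-based positions.
#' Writer and reader round-trip losslessly.
#'
#' @param pileup pileup data.frame.
#' @param path file path.
#' @return `write_pileup` returns `path` invisibly; `read_pileup` returns the
#'   pileup data.frame.
#' @export
write_pileup <- function(pileup, path) {
  fwrite(as.data.table(pileup)[, c("transcript", "pos0", BASES), with = FALSE],
         path, sep = "\t")
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  p <- fread(path, sep = "\t")
  need <- c("transcript", "pos0", BASES)
  if (!all(need %in% names(p)))
    stop_snv("pileup file ", path, " lacks columns: ",
             paste(setdiff(need, names(p)), collapse = ", "))
  if (any(vapply(p[, BASES, with = FALSE], function(x) any(x < 0), logical(1))))
    stop_snv("pileup file ", path, " contains negative counts")
  as.data.frame(p[, need, with = FALSE])
}
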