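# Shared fixture builders. Everything is generated in code; no stored data.

BASES4 <- c("A", "C", "G", "T")

# a pileup with every position of every reference covered at `depth`,
# all reads agreeing with the reference (the noise-free, saturating-depth
# limit of sequencing a pure sample)
perfect_pileup <- function(refs, depth = 20L) {
  rows <- lapply(names(refs), function(tx) {
    b <- strsplit(refs[[tx]], "")[[1]]
    m <- matrix(0L, length(b), 4, dimnames = list(NULL, BASES4))
    m[cbind(seq_along(b), match(b, BASES4))] <- as.integer(depth)
    data.frame(transcript = tx, pos0 = seq_along(b) - 1L,
               A = m[, "A"], C = m[, "C"], G = m[, "G"], T = m[, "T"],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# brute-force pileup: per-read, per-offset loop over a tally array
brute_pileup <- function(placements, refs) {
  tallies <- lapply(refs, function(s)
    matrix(0L, nchar(s), 4, dimnames = list(NULL, BASES4)))
  for (i in seq_len(nrow(placements))) {
    tx <- placements$transcript[i]
    s0 <- placements$start0[i]
    b <- strsplit(placements$seq[i], "")[[1]]
    for (k in seq_along(b)) {
      p <- s0 + k
      tallies[[tx]][p, b[k]] <- tallies[[tx]][p, b[k]] + 1L
    }
  }
  rows <- lapply(names(tallies), function(tx) {
    m <- tallies[[tx]]
    cov <- which(rowSums(m) > 0)
    if (!length(cov)) return(NULL)
    data.frame(transcript = tx, pos0 = cov - 1L,
               A = m[cov, "A"], C = m[cov, "C"], G = m[cov, "G"],
               T = m[cov, "T"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out[order(out$transcript, out$pos0), ]
}

# small default simulation used by several module tests
quick_sim <- function(n_transcripts = 20, length_mean = 600, length_sd = 0,
                      total_reads = 4e4, read_length = 100,
                      error_rate = 0, spike_fraction = 1,
                      spike_profile = "matched", bias_profile = "uniform",
                      degradation_rate = 0, seed = 99, ...) {
  cfg <- sim_config(n_transcripts = n_transcripts, length_mean = length_mean,
                    length_sd = length_sd, total_reads = total_reads,
                    read_length = read_length, error_rate = error_rate,
                    spike_fraction = spike_fraction,
                    spike_profile = spike_profile,
                    bias_profile = bias_profile,
                    degradation_rate = degradation_rate, seed = seed, ...)
  list(cfg = cfg, sim = gen_transcriptome(cfg))
}

# one-row pileup column from named counts, for operations taking a column
col_df <- function(...) {
  counts <- c(...)
  full <- setNames(rep(0L, 4), BASES4)
  full[names(counts)] <- counts
  data.frame(transcript = "tx", pos0 = 0L, A = full[["A"]], C = full[["C"]],
             G = full[["G"]], T = full[["T"]])
}
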