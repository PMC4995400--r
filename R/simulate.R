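#' Generate a paired human/chimpanzee transcriptome with ground truth
#'
#' Draws human transcript sequences with lengths from a normal distribution
#' (redrawn while shorter than the read length), then derives the chimpanzee
#' ortholog of each by substituting a different base at positions chosen
#' Bernoulli(`snv_rate`) per bp — substitutions only, no indels, emulating the
#' roughly 1-per-210-bp divergence between the two transcriptomes. Relative
#' abundances for the two human samples (A and B, related by the configured
#' fold changes) and for the spike RNA are drawn log-normal.
#'
#' @param config a [sim_config()].
#' @return a list with components `human` and `chimp` (named character vectors
#'   of sequences, names `tx0001`, ...) and `truth`, a `sim_truth` list with
#'   elements `snv` (data.frame `transcript, pos0, human_base, chimp_base`,
#'   0-based positions), `abundance` (data.frame `transcript, abundance_A,
#'   abundance_B, abundance_spike, fold_change`) and the generating `config`.
#' @export
#' @examples
#' sim <- gen_transcriptome(sim_config(n_transcripts = 5, seed = 42))
#' nchar(sim$human)
#' head(sim$truth$snv)
gen_transcriptome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_transcripts
  ids <- sprintf("tx%04d", seq_len(n))

  lens <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- as.integer(round(rnorm(length(todo), config$length_mean, config$length_sd)))
    lens[todo] <- draw
    todo <- todo[draw < config$read_length]
  }

  human <- character(n)
  chimp <- character(n)
  snv_list <- vector("list", n)
  for (i in seq_len(n)) {
    L <- lens[i]
    h <- sample(BASES, L, replace = TRUE)
    is_snv <- runif(L) < config$snv_rate
    pos <- which(is_snv)
    c_seq <- h
    if (length(pos)) {
      # substitute a uniformly chosen different base
      shift <- sample.int(3L, length(pos), replace = TRUE)
      c_seq[pos] <- BASES[(match(h[pos], BASES) + shift - 1L) %% 4L + 1L]
      snv_list[[i]] <- data.frame(
        transcript = ids[i], pos0 = pos - 1L,
        human_base = h[pos], chimp_base = c_seq[pos],
        stringsAsFactors = FALSE)
    }
    human[i] <- paste(h, collapse = "")
    chimp[i] <- paste(c_seq, collapse = "")
  }
  names(human) <- names(chimp) <- ids

  ab_A <- rlnorm(n, config$expression_mu, config$expression_sigma)
  fold <- rep(1, n)
  if (!is.null(config$de_spec))
    fold[config$de_spec[[1]]] <- config$de_spec[[2]]
  ab_B <- ab_A * fold
  ab_S <- switch(config$spike_profile,
    matched = ab_A,
    independent = rlnorm(n, config$expression_mu, config$expression_sigma))

  snv <- if (any(!vapply(snv_list, is.null, logical(1)))) {
    do.call(rbind, snv_list[!vapply(snv_list, is.null, logical(1))])
  } else {
    data.frame(transcript = character(), pos0 = integer(),
               human_base = character(), chimp_base = character(),
               stringsAsFactors = FALSE)
  }
  rownames(snv) <- NULL

  truth <- list(
    snv = snv,
    abundance = data.frame(
      transcript = ids,
      abundance_A = ab_A, abundance_B = ab_B, abundance_spike = ab_S,
      fold_change = fold, stringsAsFactors = FALSE),
    config = config)
  class(truth) <- "sim_truth"

  list(human = human, chimp = chimp, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", nrow(x$abundance), "transcripts,",
      nrow(x$snv), "SNV positions,",
      sprintf("spike %.2f\n", x$config$spike_fraction))
  invisible(x)
}

#' Per-molecule sampling weights for a spiked mixture
#'
#' Mixes the human sample's transcript abundances with the chimpanzee spike.
#' The spike comes from one batch: its per-transcript relative weights are
#' identical between samples A and B, and its total weight is
#' `spike_fraction` times the human total, so at spike fraction 0.25 one
#' chimpanzee read is expected per four human reads genome-wide.
#'
#' @param truth the `truth` component of [gen_transcriptome()].
#' @param config a [sim_config()]; `spike_fraction` is taken from here.
#' @param sample `"A"` or `"B"`.
#' @return data.frame `species, transcript, weight`; human weights sum to 1,
#'   chimpanzee weights sum to `spike_fraction`.
#' @export
gen_mixture <- function(truth, config, sample = c("A", "B")) {
  stopifnot(inherits(truth, "sim_truth"))
  sample <- match.arg(sample)
  if (config$spike_fraction < 0) stop_snv("spike_fraction must be >= 0")
  ab <- truth$abundance
  hum <- if (sample == "A") ab$abundance_A else ab$abundance_B
  hw <- hum / sum(hum)
  cw <- if (config$spike_fraction > 0) {
    config$spike_fraction * ab$abundance_spike / sum(ab$abundance_spike)
  } else {
    rep(0, nrow(ab))
  }
  rbind(
    data.frame(species = "human", transcript = ab$transcript, weight = hw,
               stringsAsFactors = FALSE),
    data.frame(species = "chimp", transcript = ab$transcript, weight = cw,
               stringsAsFactors = FALSE))
}

#' Survival weight of a fragment under 3'-anchored degradation
#'
#' Library preparation selects polyadenylated molecules by oligo-dT capture;
#' after partial RNase digestion a fragment is recovered only if the path from
#' its 3' side to the transcript 3' end is intact. With independent per-bp
#' cuts at rate `lambda` that survival probability is `exp(-lambda * d)`.
#'
#' @param d distance (bp) from the fragment's 3' side to the transcript 3'
#'   end; vectorized.
#' @param lambda per-bp cut rate (>= 0).
#' @return survival probabilities in `[0, 1]`, strictly decreasing in `d`
#'   when `lambda > 0`.
#' @export
#' @examples
#' degradation_weight(0:3 * 500, calibrate_degradation(0.7, 2000))
degradation_weight <- function(d, lambda) {
  if (any(d < 0)) stop_snv("d must be >= 0")
  if (lambda < 0) stop_snv("lambda must be >= 0")
  exp(-lambda * d)
}

#' Positional bias weight function
#'
#' Returns the positional weight profile as a function of the relative start
#' position u in [0, 1] (0 = 5' most start, 1 = 3' most). `"hexamer-like"`
#' is a mid-body hump (random-hexamer priming under-represents both ends);
#' `"nextera-like"` is a 5' ramp (tagmentation-style enrichment near the 5'
#' end). Both are smooth, strictly positive stand-ins for the qualitative
#' mechanism differences between library preparations.
#'
#' @param profile one of `"uniform"`, `"hexamer-like"`, `"nextera-like"`.
#' @return function mapping u in [0,1] to a positive weight.
#' @export
bias_profile_fun <- function(profile = c("uniform", "hexamer-like", "nextera-like")) {
  profile <- match.arg(profile)
  switch(profile,
    "uniform" = function(u) rep(1, length(u)),
    "hexamer-like" = function(u) 0.3 + sin(pi * u)^2,
    "nextera-like" = function(u) 0.4 + exp(-3 * u))
}

# Unnormalized weight over valid start positions 0..L-rl for one transcript.
start_weights <- function(L, config) {
  rl <- config$read_length
  n_start <- L - rl + 1L
  u <- if (n_start == 1L) 0 else (seq_len(n_start) - 1L) / (n_start - 1L)
  w <- bias_profile_fun(config$bias_profile)(u)
  if (config$degradation_rate > 0) {
    d <- L - ((seq_len(n_start) - 1L) + rl)   # 3' side to transcript 3' end
    w <- w * degradation_weight(d, config$degradation_rate)
  }
  w
}

#' Sample biased read placements from a spiked mixture
#'
#' Draws exactly `total_reads` single-end, sense-strand read placements. The
#' joint distribution over (species, transcript, start) is proportional to
#' mixture weight x positional bias x degradation survival; read sequences
#' are substrings of the species reference with independent per-base
#' substitution errors at `error_rate` (to a uniformly chosen different
#' base). Each placement carries its truth origin.
#'
#' @param references list with named character vectors `human` and `chimp`
#'   (as returned by [gen_transcriptome()]).
#' @param weights mixture weights from [gen_mixture()].
#' @param config a [sim_config()].
#' @param seed seed for this library; defaults to `config$seed + 1`. Pass
#'   distinct seeds to obtain independent libraries (e.g. technical
#'   replicates) from one mixture.
#' @return a data.table of placements with columns
#'   `read_id, species, transcript, start0, length, seq`.
#' @export
sample_reads <- function(references, weights, config, seed = NULL) {
  validate_sim_config(config)
  set.seed(if (is.null(seed)) config$seed + 1L else as.integer(seed))
  rl <- config$read_length
  w <- weights[weights$weight > 0, , drop = FALSE]
  if (nrow(w) == 0L) stop_snv("empty weight vector: nothing to sample from")

  refs <- list(human = references$human, chimp = references$chimp)
  lens <- nchar(refs$human)   # human and chimp orthologs have equal length
  if (any(!w$transcript %in% names(lens)))
    stop_snv("weights reference transcripts absent from the reference set")
  Lw <- lens[w$transcript]

  # per-category start-weight vectors and their totals
  sw <- lapply(seq_len(nrow(w)), function(i) start_weights(Lw[i], config))
  S <- vapply(sw, sum, numeric(1))
  p <- w$weight * S
  n_cat <- as.integer(rmultinom(1, config$total_reads, p))

  out <- vector("list", nrow(w))
  for (i in which(n_cat > 0L)) {
    n <- n_cat[i]
    ns <- length(sw[[i]])
    # inverse-CDF sampling of start positions (much faster than sample(prob=))
    s0 <- if (ns == 1L) rep(0L, n) else {
      cum <- cumsum(sw[[i]])
      findInterval(runif(n) * cum[ns], cum)
    }
    out[[i]] <- data.table(
      species = w$species[i], transcript = w$transcript[i], start0 = s0)
  }
  pl <- rbindlist(out)
  pl[, len := rl]
  seqs <- character(nrow(pl))
  tx_idx <- match(pl$transcript, names(refs$human))
  for (sp in c("human", "chimp")) {
    k <- which(pl$species == sp)
    if (length(k))
      seqs[k] <- substring(refs[[sp]][tx_idx[k]],
                           pl$start0[k] + 1L, pl$start0[k] + rl)
  }

  if (config$error_rate > 0) {
    n_err <- rbinom(length(seqs), rl, config$error_rate)
    one <- which(n_err == 1L)
    if (length(one)) {
      pos <- sample.int(rl, length(one), replace = TRUE)
      seqs[one] <- mutate_base_at(seqs[one], pos)
    }
    multi <- which(n_err >= 2L)
    for (i in multi) {
      for (p1 in sample.int(rl, n_err[i]))
        seqs[i] <- mutate_base_at(seqs[i], p1)
    }
  }

  pl[, seq_ := seqs]
  pl[, read_id := paste0("r", seq_len(.N))]
  setnames(pl, c("len", "seq_"), c("length", "seq"))
  data.table::setcolorder(pl, c("read_id", "species", "transcript",
                                "start0", "length", "seq"))
  pl[]
}

# substitute the base at 1-based position pos of each string with a
# uniformly chosen different base (vectorized)
mutate_base_at <- function(s, pos) {
  old <- substr(s, pos, pos)
  shift <- sample.int(3L, length(s), replace = TRUE)
  new <- BASES[(match(old, BASES) + shift - 1L) %% 4L + 1L]
  substr(s, pos, pos) <- new
  s
}

#' Expected species-summed SNV read counts per transcript
#'
#' Deterministic counterpart of [sample_reads()] followed by allele counting:
#' for each transcript it returns the expected number of human and chimpanzee
#' reads overlapping its informative positions, under the configured mixture
#' weights, bias profile and degradation. Useful for Poisson-resampling
#' technical replicates without simulating individual reads.
#'
#' @inheritParams sample_reads
#' @param positions data.frame of informative positions
#'   (`transcript, pos0, ...`), e.g. the truth SNV table.
#' @return data.frame `transcript, e_human, e_chimp` of expected summed
#'   counts (reads x loci overlaps) per transcript.
#' @export
expected_snv_counts <- function(references, weights, config, positions) {
  validate_sim_config(config)
  rl <- config$read_length
  lens <- nchar(references$human)
  w <- weights[weights$weight > 0, , drop = FALSE]
  sw <- lapply(w$transcript, function(tx) start_weights(lens[[tx]], config))
  S <- vapply(sw, sum, numeric(1))
  pcat <- w$weight * S
  pcat <- pcat / sum(pcat)
  e_reads <- config$total_reads * pcat   # expected reads per (species, tx)

  pos_by_tx <- split(positions$pos0, positions$transcript)
  e_sum <- numeric(nrow(w))
  for (i in seq_len(nrow(w))) {
    tx <- w$transcript[i]
    pos <- pos_by_tx[[tx]]
    if (is.null(pos)) next
    swi <- sw[[i]] / S[i]
    ns <- length(swi)
    # P(read covers locus p) = sum of start probs over starts in [p-rl+1, p]
    cum <- c(0, cumsum(swi))
    lo <- pmax(pos - rl + 1L, 0L)
    hi <- pmin(pos, ns - 1L)
    cov <- ifelse(hi >= lo, cum[hi + 2L] - cum[lo + 1L], 0)
    e_sum[i] <- e_reads[i] * sum(cov)
  }
  dt <- data.table(species = w$species, transcript = w$transcript, e = e_sum)
  wide <- data.table::dcast(dt, transcript ~ species, value.var = "e", fill = 0)
  for (col in c("human", "chimp"))
    if (!col %in% names(wide)) wide[, (col) := 0]
  out <- data.frame(transcript = wide$transcript,
                    e_human = wide$human, e_chimp = wide$chimp,
                    stringsAsFactors = FALSE)
  out[order(out$transcript), , drop = FALSE]
}
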