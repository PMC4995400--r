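#' Simulator configuration
#'
#' Bundles every knob of the paired-transcriptome read simulator. Defaults
#' describe the reference experimental design: transcripts around 2.9 kb,
#' interspecies substitutions at one per 210 bp (about 14 per transcript),
#' log-normal expression, an equal-mass chimpanzee spike, 150 bp single-end
#' reads, and a small per-base substitution error.
#'
#' @param n_transcripts number of transcripts (genes); one transcript per gene.
#' @param length_mean,length_sd transcript length distribution (bp); drawn
#'   normal and rounded, redrawn while below `read_length`.
#' @param snv_rate per-bp probability that the chimpanzee base differs from the
#'   human base (default 1/210).
#' @param expression_mu,expression_sigma meanlog and sdlog of the log-normal
#'   relative abundances of the human transcripts.
#' @param de_spec differential expression between samples B and A: a
#'   two-column data.frame `(transcript_index, fold_change)`; transcripts not
#'   listed have fold change 1.
#' @param spike_fraction chimpanzee:human mass ratio of the spike (e.g. 1.0 or
#'   0.25).
#' @param spike_profile `"independent"` draws the chimpanzee spike's
#'   per-transcript abundances from their own log-normal (the spike RNA comes
#'   from a different cell type); `"matched"` sets each transcript's spike
#'   abundance proportional to its human sample-A abundance.
#' @param total_reads reads per simulated library.
#' @param read_length read length in bp (single-end, sense strand).
#' @param error_rate per-base substitution probability (uniform over the three
#'   other bases).
#' @param bias_profile positional weight on read start sites: `"uniform"`,
#'   `"hexamer-like"` (mid-body hump, random-hexamer priming style) or
#'   `"nextera-like"` (5' ramp, tagmentation style).
#' @param degradation_rate per-bp cut rate \eqn{\lambda}; a fragment whose 3'
#'   side lies `d` bp from the transcript 3' end survives oligo-dT capture
#'   with probability `exp(-lambda * d)`. 0 disables degradation.
#' @param seed integer seed; identical configurations (including seed) give
#'   byte-identical outputs.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [gen_transcriptome()], [sample_reads()], [calibrate_degradation()]
#' @export
#' @examples
#' cfg <- sim_config(n_transcripts = 50, total_reads = 2e4, seed = 1)
sim_config <- function(n_transcripts = 200,
                       length_mean = 2940, length_sd = 600,
                       snv_rate = 1 / 210,
                       expression_mu = 1, expression_sigma = 1,
                       de_spec = NULL,
                       spike_fraction = 1.0,
                       spike_profile = c("independent", "matched"),
                       total_reads = 1e5,
                       read_length = 150,
                       error_rate = 0.001,
                       bias_profile = c("uniform", "hexamer-like", "nextera-like"),
                       degradation_rate = 0,
                       seed = 1L) {
  spike_profile <- match.arg(spike_profile)
  bias_profile <- match.arg(bias_profile)
  cfg <- list(
    n_transcripts = as.integer(n_transcripts),
    length_mean = length_mean, length_sd = length_sd,
    snv_rate = snv_rate,
    expression_mu = expression_mu, expression_sigma = expression_sigma,
    de_spec = de_spec,
    spike_fraction = spike_fraction,
    spike_profile = spike_profile,
    total_reads = as.integer(total_reads),
    read_length = as.integer(read_length),
    error_rate = error_rate,
    bias_profile = bias_profile,
    degradation_rate = degradation_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is_count(cfg$n_transcripts) || cfg$n_transcripts < 1)
    stop_snv("n_transcripts must be a positive integer")
  if (!is_count(cfg$total_reads) || cfg$total_reads < 1)
    stop_snv("total_reads must be a positive integer")
  if (!is_count(cfg$read_length) || cfg$read_length < 1)
    stop_snv("read_length must be a positive integer")
  if (cfg$snv_rate < 0 || cfg$snv_rate >= 1)
    stop_snv("snv_rate must lie in [0, 1)")
  if (cfg$spike_fraction < 0)
    stop_snv("spike_fraction must be >= 0")
  if (cfg$error_rate < 0 || cfg$error_rate >= 0.5)
    stop_snv("error_rate must lie in [0, 0.5)")
  if (cfg$degradation_rate < 0)
    stop_snv("degradation_rate must be >= 0")
  if (!is.null(cfg$de_spec)) {
    de <- cfg$de_spec
    if (!is.data.frame(de) || ncol(de) < 2)
      stop_snv("de_spec must be a data.frame with columns (transcript_index, fold_change)")
    if (any(de[[1]] < 1 | de[[1]] > cfg$n_transcripts))
      stop_snv("de_spec transcript indices out of range")
    if (any(de[[2]] <= 0))
      stop_snv("de_spec fold changes must be positive")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      x$n_transcripts, "transcripts,",
      sprintf("snv_rate %.4g,", x$snv_rate),
      sprintf("spike %.2f (%s),", x$spike_fraction, x$spike_profile),
      x$total_reads, "reads x", x$read_length, "bp,",
      sprintf("error %.3g, bias '%s', lambda_deg %.3g, seed %d\n",
              x$error_rate, x$bias_profile, x$degradation_rate, x$seed))
  invisible(x)
}

#' Calibrate the degradation rate from a target loss fraction
#'
#' Partial RNase digestion removes the 5' ends of a known fraction of
#' molecules from oligo-dT capture (about 70% of the 28S band in the reference
#' degradation condition). For an exponential per-bp cut model the survival of
#' a fragment whose 3' side lies `length` bp from the transcript 3' end is
#' `exp(-lambda * length)`; solving `1 - exp(-lambda * length) = p_lost`
#' gives the rate.
#'
#' @param p_lost fraction of full-length molecules that lose 5' capture
#'   (default 0.7).
#' @param length reference molecule length in bp.
#' @return per-bp degradation rate \eqn{\lambda}.
#' @export
#' @examples
#' calibrate_degradation(0.7, 2000) # ~ 6.02e-4
calibrate_degradation <- function(p_lost = 0.7, length = 2000) {
  stopifnot(p_lost >= 0, p_lost < 1, length > 0)
  -log(1 - p_lost) / length
}
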