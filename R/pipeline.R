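#' Pipeline configuration
#'
#' Parameters for an end-to-end run: the simulator configuration plus the
#' method thresholds (pileup depth 10, homozygosity 0.90, count cutoff 40,
#' discordance factor 2). Unknown keys are rejected.
#'
#' @param sim a [sim_config()] describing the simulated experiment.
#' @param min_depth minimum three-way pileup depth for SNV discovery.
#' @param homozygosity_threshold major-allele frequency for homozygosity.
#' @param count_cutoff per-species summed-count cutoff for ratio reporting.
#' @param discordance_factor fold-difference threshold for discordance.
#' @param seed global seed; every stage derives its stream from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            min_depth = 10,
                            homozygosity_threshold = 0.90,
                            count_cutoff = 40,
                            discordance_factor = 2,
                            seed = sim$seed) {
  stopifnot(inherits(sim, "sim_config"))
  if (min_depth < 1) stop_snv("min_depth must be >= 1")
  if (homozygosity_threshold <= 0.5 || homozygosity_threshold > 1)
    stop_snv("homozygosity_threshold must lie in (0.5, 1]")
  if (count_cutoff < 0) stop_snv("count_cutoff must be >= 0")
  if (discordance_factor < 1) stop_snv("discordance_factor must be >= 1")
  structure(list(sim = sim, min_depth = min_depth,
                 homozygosity_threshold = homozygosity_threshold,
                 count_cutoff = count_cutoff,
                 discordance_factor = discordance_factor,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `min_depth`, `homozygosity_threshold`, `count_cutoff`,
#' `discordance_factor`, `seed` and a `sim:` block whose keys are the
#' [sim_config()] arguments. Unknown keys in either block are an error.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  unknown <- setdiff(names(sim_args), names(formals(sim_config)))
  if (length(unknown))
    stop_snv("unknown sim config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(sim_args$de_spec))
    sim_args$de_spec <- as.data.frame(sim_args$de_spec)
  top <- y[setdiff(names(y), "sim")]
  unknown <- setdiff(names(top),
                     setdiff(names(formals(pipeline_config)), "sim"))
  if (length(unknown))
    stop_snv("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, c(list(sim = do.call(sim_config, sim_args)), top))
}

#' Run the full simulate-to-evaluate workflow
#'
#' Executes, in order: transcriptome simulation; pure-library read sampling
#' for the two human samples and the chimpanzee sample; pileup; informative-
#' position discovery; mixed-library sampling for spiked samples A and B;
#' allele counting; per-transcript SNV ratios, cutoff and differential
#' expression; and evaluation (coverage flattening, SNV-vs-unnormalized
#' discordance). Every declared output file is written under `outdir`
#' together with a JSON manifest of parameters, package version and output
#' digests. Reruns with the same configuration are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created; must be empty or absent).
#' @param quiet suppress stage messages.
#' @return invisibly, a list with the main in-memory results (`truth`,
#'   `informative`, `ratios_A`, `ratios_B`, `folds`, `flatness`,
#'   `discordance`, `manifest`).
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  say <- function(...) if (!quiet) message("[snvspike] ", ...)
  scfg <- config$sim
  pth <- function(f) file.path(outdir, f)

  say("simulate: ", scfg$n_transcripts, " transcripts")
  sim <- gen_transcriptome(scfg)
  write_fasta(sim$human, pth("human.fa"))
  write_fasta(sim$chimp, pth("chimp.fa"))
  write_sim_truth(sim$truth, outdir)

  ab <- sim$truth$abundance
  pure_w <- function(species, abund) data.frame(
    species = species, transcript = ab$transcript,
    weight = abund / sum(abund), stringsAsFactors = FALSE)

  say("pure libraries + pileups (HF, HI, CL)")
  pure <- list(
    hf = pure_w("human", ab$abundance_A),
    hi = pure_w("human", ab$abundance_B),
    cl = pure_w("chimp", ab$abundance_spike))
  pileups <- list()
  for (i in seq_along(pure)) {
    nm <- names(pure)[i]
    pl <- sample_reads(sim, pure[[i]], scfg, seed = config$seed + 10L + i)
    pileups[[nm]] <- build_pileup(pl, sim$human)
    write_pileup(pileups[[nm]], pth(paste0(nm, ".pileup.tsv")))
  }

  say("discover informative positions")
  informative <- find_informative(pileups$hf, pileups$hi, pileups$cl,
                                  min_depth = config$min_depth,
                                  threshold = config$homozygosity_threshold)
  write_informative_bed(informative, pth("informative.bed"))
  say("  ", nrow(informative), " informative positions")

  say("mixed libraries (samples A, B), counting")
  counts <- list(); mixed_pileups <- list()
  for (s in c("A", "B")) {
    w <- gen_mixture(sim$truth, scfg, s)
    pl <- sample_reads(sim, w, scfg,
                       seed = config$seed + 20L + match(s, c("A", "B")))
    mixed_pileups[[s]] <- build_pileup(pl, sim$human)
    counts[[s]] <- count_alleles(mixed_pileups[[s]], informative)
    write_allele_counts(counts[[s]], pth(paste0("counts_", s, ".tsv")))
  }

  say("normalize: per-transcript ratios, cutoff ", config$count_cutoff,
      ", differential expression")
  ratios <- lapply(counts, function(x)
    apply_cutoff(transcript_ratio(x), config$count_cutoff))
  for (s in c("A", "B"))
    write_ratios(ratios[[s]], pth(paste0("ratios_", s, ".tsv")))
  folds <- differential_expression(ratios$A, ratios$B)
  write_folds(folds, pth("folds.tsv"))

  say("evaluate: flattening + discordance vs unnormalized folds")
  flat <- flatten_profile(mixed_pileups$A, informative, counts$A)
  fwrite(flat$report, pth("flatness.tsv"), sep = "\t")
  fwrite(flat$profile, pth("flatness_profile.tsv"), sep = "\t")

  tr <- lapply(counts, transcript_ratio)
  shared <- merge(tr$A, tr$B, by = "transcript", suffixes = c("_A", "_B"))
  unnorm <- setNames(unnormalized_fold(shared$n_human_A, shared$n_human_B,
                                       sum(tr$A$n_human), sum(tr$B$n_human)),
                     shared$transcript)
  disc <- discordance_count(setNames(folds$fold, folds$transcript), unnorm,
                            factor = config$discordance_factor)

  manifest <- list(
    package = "snvspike",
    version = as.character(packageVersion("snvspike")),
    seed = config$seed,
    parameters = list(
      min_depth = config$min_depth,
      homozygosity_threshold = config$homozygosity_threshold,
      count_cutoff = config$count_cutoff,
      discordance_factor = config$discordance_factor,
      sim = unclass(scfg)[setdiff(names(scfg), "de_spec")]),
    n_informative = nrow(informative),
    discordance = disc,
    outputs = as.list(tools::md5sum(list.files(outdir, full.names = TRUE))))
  names(manifest$outputs) <- basename(names(manifest$outputs))
  jsonlite::write_json(manifest, pth("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", outdir)
  invisible(list(truth = sim$truth, informative = informative,
                 ratios_A = ratios$A, ratios_B = ratios$B, folds = folds,
                 flatness = flat$report, discordance = disc,
                 manifest = manifest))
}

#' Validate a file against one of the package's formats
#'
#' Schema and invariant checks with line-numbered diagnostics.
#'
#' @param path file to check.
#' @param kind one of `"fasta"`, `"bed"`, `"pileup"`, `"counts"`,
#'   `"matrix"`.
#' @return list `valid` (logical) and `messages` (character diagnostics,
#'   empty when valid).
#' @export
validate_formats <- function(path, kind = c("fasta", "bed", "pileup",
                                            "counts", "matrix")) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop_snv("cannot read ", path)
  msgs <- character()
  res <- tryCatch({
    switch(kind,
      fasta = {
        x <- read_fasta(path)
        if (!length(x)) msgs <- "empty FASTA"
        if (anyDuplicated(names(x))) msgs <- c(msgs, "duplicated sequence ids")
      },
      bed = { read_informative_bed(path) },
      pileup = {
        p <- fread(path, sep = "\t")
        need <- c("transcript", "pos0", BASES)
        miss <- setdiff(need, names(p))
        if (length(miss)) {
          msgs <- paste("missing column(s):", paste(miss, collapse = ", "))
        } else {
          cm <- as.matrix(p[, BASES, with = FALSE])
          bad <- which(rowSums(cm < 0) > 0)
          if (length(bad))
            msgs <- paste0("negative count at line ", bad[1] + 1L)
          if ("depth" %in% names(p)) {
            off <- which(p$depth != rowSums(cm))
            if (length(off))
              msgs <- c(msgs, paste0("depth != sum of base counts at line ",
                                     off[1] + 1L))
          }
        }
      },
      counts = {
        x <- read_allele_counts(path)
        bad <- which(x$n_human < 0 | x$n_chimp < 0 | x$n_other < 0)
        if (length(bad)) msgs <- paste0("negative count at line ", bad[1] + 1L)
      },
      matrix = { read_count_matrix(path) })
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(res)) msgs <- c(msgs, res)
  list(valid = length(msgs) == 0L, messages = msgs)
}
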