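test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(snv_rate = 1), "snv_rate")
  expect_error(sim_config(snv_rate = -0.1), "snv_rate")
  expect_error(sim_config(spike_fraction = -1), "spike_fraction")
  expect_error(sim_config(error_rate = 0.5), "error_rate")
  expect_error(sim_config(n_transcripts = 0), "n_transcripts")
  expect_error(sim_config(de_spec = data.frame(i = 999, f = 2),
                          n_transcripts = 10), "indices")
})

test_that("chimp sequences differ from human exactly at truth SNVs, substitutions only", {
  qs <- quick_sim(n_transcripts = 10, length_mean = 500, seed = 3)
  sim <- qs$sim
  expect_identical(nchar(sim$human), nchar(sim$chimp))
  for (tx in names(sim$human)) {
    h <- strsplit(sim$human[[tx]], "")[[1]]
    c_ <- strsplit(sim$chimp[[tx]], "")[[1]]
    diff_pos <- which(h != c_) - 1L
    truth <- sim$truth$snv[sim$truth$snv$transcript == tx, ]
    expect_identical(diff_pos, truth$pos0)
    expect_identical(h[diff_pos + 1L], truth$human_base)
    expect_identical(c_[diff_pos + 1L], truth$chimp_base)
  }
  expect_true(all(sim$truth$snv$human_base != sim$truth$snv$chimp_base))
})

test_that("snv_rate = 0 gives identical references; density matches the rate", {
  qs0 <- quick_sim(n_transcripts = 5, snv_rate = 0)
  expect_identical(qs0$sim$human, qs0$sim$chimp)
  expect_identical(nrow(qs0$sim$truth$snv), 0L)

  # 1,000 transcripts of 2,100 bp at 1/210 per bp: ~10 SNVs per transcript
  cfg <- sim_config(n_transcripts = 1000, length_mean = 2100, length_sd = 0,
                    snv_rate = 1 / 210, seed = 5)
  sim <- gen_transcriptome(cfg)
  per_tx <- table(factor(sim$truth$snv$transcript,
                         levels = names(sim$human)))
  expected <- 2100 / 210
  se <- sqrt(2100 * (1 / 210) * (1 - 1 / 210) / 1000)
  expect_lt(abs(mean(per_tx) - expected), 3 * se)
})

test_that("identical seeds give byte-identical FASTA and placements", {
  qs1 <- quick_sim(seed = 12, n_transcripts = 5, total_reads = 2000)
  qs2 <- quick_sim(seed = 12, n_transcripts = 5, total_reads = 2000)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(qs1$sim$human, f1); write_fasta(qs2$sim$human, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  w <- gen_mixture(qs1$sim$truth, qs1$cfg, "A")
  p1 <- sample_reads(qs1$sim, w, qs1$cfg)
  p2 <- sample_reads(qs2$sim, w, qs2$cfg)
  expect_identical(p1, p2)
})

test_that("mixture weights respect the spike fraction and shared batch", {
  qs <- quick_sim(n_transcripts = 8, spike_profile = "independent",
                  spike_fraction = 0.25,
                  de_spec = data.frame(i = 1:2, f = c(4, 0.5)))
  wA <- gen_mixture(qs$sim$truth, qs$cfg, "A")
  wB <- gen_mixture(qs$sim$truth, qs$cfg, "B")
  ch <- wA$species == "chimp"
  expect_equal(sum(wA$weight[ch]) / sum(wA$weight[!ch]), 0.25)
  # chimp profile identical between samples (same spike batch)
  expect_equal(wA$weight[ch], wB$weight[ch])
  # human profiles differ by the configured fold changes
  hA <- wA$weight[!ch]; hB <- wB$weight[!ch]
  fc <- (hB / hA) * (sum(qs$sim$truth$abundance$abundance_B) /
                       sum(qs$sim$truth$abundance$abundance_A))
  expect_equal(fc[1:2], c(4, 0.5))
  # no spike: zero chimp weight
  cfg0 <- sim_config(n_transcripts = 8, spike_fraction = 0, seed = 99)
  w0 <- gen_mixture(qs$sim$truth, cfg0, "A")
  expect_identical(sum(w0$weight[w0$species == "chimp"]), 0)
})

test_that("degradation weight follows the exponential survival law", {
  expect_equal(degradation_weight(0:5 * 100, 0), rep(1, 6))
  expect_equal(degradation_weight(0, 0.01), 1)
  # calibration: full-length survival 0.3 at 2 kb
  lam <- calibrate_degradation(0.7, 2000)
  expect_equal(lam, -log(0.3) / 2000, tolerance = 1e-12)
  expect_equal(degradation_weight(2000, lam), 0.3)
  w <- degradation_weight(seq(0, 3000, by = 50), lam)
  expect_true(all(diff(w) < 0))
  expect_error(degradation_weight(-1, 0.1), "d must")
})

test_that("sample_reads: count conservation, noiseless substrings, species ratio", {
  qs <- quick_sim(n_transcripts = 10, total_reads = 10000,
                  spike_fraction = 0.25, error_rate = 0)
  w <- gen_mixture(qs$sim$truth, qs$cfg, "A")
  pl <- sample_reads(qs$sim, w, qs$cfg)
  expect_identical(nrow(pl), 10000L)
  # error_rate = 0: every read equals its source reference substring
  refs <- list(human = qs$sim$human, chimp = qs$sim$chimp)
  src <- vapply(seq_len(nrow(pl)), function(i)
    substr(refs[[pl$species[i]]][[pl$transcript[i]]],
           pl$start0[i] + 1L, pl$start0[i] + pl$length[i]), character(1))
  expect_identical(pl$seq, src)
  # spike conservation: chimp:human read ratio near 0.25 (3 binomial SE)
  p <- 0.25 / 1.25
  n_chimp <- sum(pl$species == "chimp")
  se <- sqrt(p * (1 - p) * 10000)
  expect_lt(abs(n_chimp - p * 10000), 3 * se)
  expect_error(sample_reads(qs$sim, w[w$weight < 0, ], qs$cfg), "empty")
})

test_that("uniform bias and equal weights give multinomially uniform transcript counts", {
  qs <- quick_sim(n_transcripts = 10, length_mean = 500, length_sd = 0,
                  total_reads = 100000, spike_fraction = 0, seed = 21)
  ab <- qs$sim$truth$abundance
  w <- data.frame(species = "human", transcript = ab$transcript,
                  weight = 1 / nrow(ab))
  pl <- sample_reads(qs$sim, w, qs$cfg)
  obs <- table(factor(pl$transcript, levels = ab$transcript))
  chi <- chisq.test(obs, p = rep(0.1, 10))
  expect_gt(chi$p.value, 0.001)
})

test_that("batch identity: chimp per-transcript counts agree between samples A and B", {
  qs <- quick_sim(n_transcripts = 10, length_mean = 500, length_sd = 0,
                  total_reads = 50000, spike_fraction = 1,
                  spike_profile = "independent",
                  de_spec = data.frame(i = 1:3, f = c(5, 0.2, 3)))
  wA <- gen_mixture(qs$sim$truth, qs$cfg, "A")
  wB <- gen_mixture(qs$sim$truth, qs$cfg, "B")
  plA <- sample_reads(qs$sim, wA, qs$cfg, seed = 1)
  plB <- sample_reads(qs$sim, wB, qs$cfg, seed = 2)
  cA <- table(factor(plA$transcript[plA$species == "chimp"],
                     levels = wA$transcript[1:10]))
  cB <- table(factor(plB$transcript[plB$species == "chimp"],
                     levels = wA$transcript[1:10]))
  # equal expectations: each pairwise difference within 3 SE of 0
  z <- (as.numeric(cA) - as.numeric(cB)) / sqrt(pmax(cA + cB, 1))
  expect_true(all(abs(z) < 3 + 1e-9))
})

test_that("expected_snv_counts matches empirical summed counts", {
  qs <- quick_sim(n_transcripts = 12, length_mean = 700, length_sd = 0,
                  total_reads = 150000, spike_fraction = 1,
                  bias_profile = "hexamer-like", seed = 31)
  w <- gen_mixture(qs$sim$truth, qs$cfg, "A")
  ex <- expected_snv_counts(qs$sim, w, qs$cfg, qs$sim$truth$snv)
  pl <- sample_reads(qs$sim, w, qs$cfg)
  pu <- build_pileup(pl, qs$sim$human, positions = qs$sim$truth$snv)
  cnt <- count_alleles(pu, qs$sim$truth$snv)
  tr <- transcript_ratio(cnt)
  m <- merge(ex, tr, by = "transcript")
  tot <- m$n_human + m$n_chimp
  etot <- m$e_human + m$e_chimp
  # per-transcript totals within 4 SE of expectation (sum of near-Poisson counts)
  expect_true(all(abs(tot - etot) < 4 * sqrt(etot)))
  # and globally unbiased to ~1%
  expect_equal(sum(tot) / sum(etot), 1, tolerance = 0.01)
})
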