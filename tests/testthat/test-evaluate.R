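test_that("cv: hand value, scale invariance, ND exclusion, errors", {
  expect_equal(cv(c(2, 2, 2)), 0)
  expect_equal(cv(c(1, 3)), 100 * sqrt(2) / 2)   # 70.71...
  x <- rlnorm(20)
  expect_equal(cv(3.7 * x), cv(x))
  expect_equal(cv(c(1, 3, NA)), cv(c(1, 3)))
  expect_error(cv(c(5)), "at least 2")
  expect_error(cv(c(-1, 1)), "mean is zero")
})

test_that("agreement: self, exact proportionality, Poisson replicates", {
  v <- setNames(rlnorm(50), paste0("g", 1:50))
  self <- agreement(v, v)
  expect_equal(self$mean_ratio, 1)
  expect_equal(self$cv, 0)
  expect_identical(self$n_genes, 50L)

  # 4x proportionality mirrors halving the spike twice: mean 4, cv 0
  prop <- agreement(4 * v, v)
  expect_equal(prop$mean_ratio, 4)
  expect_equal(prop$cv, 0)

  # ratio of independent Poisson-resampled SNV values at per-species depth
  # lambda = 150: E[ratio] ~ (1 + 1/150)^2 ~ 1.013
  set.seed(101)
  lam <- 150
  n <- 1000
  r1 <- rpois(n, lam) / pmax(rpois(n, lam), 1)
  r2 <- rpois(n, lam) / pmax(rpois(n, lam), 1)
  ag <- agreement(setNames(r1, paste0("g", 1:n)),
                  setNames(r2, paste0("g", 1:n)))
  expect_gt(ag$mean_ratio, 0.99)
  expect_lt(ag$mean_ratio, 1.04)

  # ND genes and unshared genes are excluded, n reports what was used
  v2 <- v; v2[1] <- NA
  expect_identical(agreement(v, v2)$n_genes, 49L)
  expect_error(agreement(v[1:2], v[3:4]), "at least 2")
})

test_that("correlation: exact lines and a hand-computed fixture", {
  x <- setNames(c(1, 2, 3, 4, 5), paste0("g", 1:5))
  expect_equal(correlation(2 * x, x)$pearson_r, 1)
  expect_equal(correlation(-x, x)$pearson_r, -1)
  y <- setNames(c(2, 1, 4, 3, 6), names(x))
  # hand covariance formula: r = cov(x, y) / (sd x * sd y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- correlation(x, y)
  expect_equal(got$pearson_r, r_hand, tolerance = 1e-12)
  expect_equal(got$r_squared, r_hand^2, tolerance = 1e-12)
  # symmetry and invariance to positive affine transforms
  expect_equal(correlation(y, x)$pearson_r, got$pearson_r)
  expect_equal(correlation(3 * x + 7, y)$pearson_r, got$pearson_r)
  # log transform drops nonpositive pairs
  xx <- setNames(c(-1, 1, 2, 3, 4), paste0("g", 1:5))
  expect_identical(correlation(xx, x, log_transform = TRUE)$n, 4L)
  expect_error(correlation(x[1:2], x[1:2]), "at least 3")
  expect_error(correlation(setNames(rep(1, 5), names(x)), x), "zero variance")
})

test_that("flatten_profile: exact cancellation in the expected-count limit", {
  # expected counts used directly (infinite-depth limit): every locus ratio
  # equals the abundance ratio, so snv_cv is exactly 0 while raw coverage
  # under a positional bias is not flat
  bias <- round(100 * (0.5 + sin(pi * seq(0, 1, length.out = 20))))
  mixed <- data.frame(transcript = "tx1", pos0 = 0:19,
                      A = as.integer(2 * bias), C = 0L,
                      G = as.integer(bias), T = 0L)
  pos <- data.frame(transcript = "tx1", pos0 = c(3L, 9L, 15L),
                    human_base = "A", chimp_base = "G")
  fl <- flatten_profile(mixed, pos)
  expect_equal(fl$report$snv_cv, 0)
  expect_gt(fl$report$raw_cv, 10)
  expect_identical(fl$report$n_loci, 3L)
  # profile table carries both series
  expect_identical(nrow(fl$profile), 20L)
  expect_identical(sum(!is.na(fl$profile$snv_ratio)), 3L)

  # a transcript with a single usable locus is skipped with a notice
  pos1 <- pos[1, ]
  expect_message(fl1 <- flatten_profile(mixed, pos1), "skipping")
  expect_identical(nrow(fl1$report), 0L)
})

test_that("shared positional bias flattens ratios but not raw coverage", {
  qs <- quick_sim(n_transcripts = 12, length_mean = 1200, length_sd = 0,
                  total_reads = 30000, read_length = 150,
                  bias_profile = "hexamer-like", error_rate = 0,
                  spike_fraction = 1, spike_profile = "matched", seed = 41)
  w <- gen_mixture(qs$sim$truth, qs$cfg, "A")
  pl <- sample_reads(qs$sim, w, qs$cfg)
  pu <- build_pileup(pl, qs$sim$human)
  fl <- flatten_profile(pu, qs$sim$truth$snv)
  rep5 <- fl$report[fl$report$n_loci >= 5, ]
  expect_gt(nrow(rep5), 5)
  expect_gt(mean(rep5$snv_cv < rep5$raw_cv), 0.95)
})

test_that("discordance is a strict threshold and symmetric", {
  f1 <- setNames(c(1, 2, 4, 8, NA), paste0("g", 1:5))
  f2 <- setNames(c(1, 2, 1, 4, 2), paste0("g", 1:5))
  expect_identical(discordance_count(f1, f1)$n_discordant, 0L)
  d <- discordance_count(f1, f2)
  expect_identical(d$n_discordant, 1L)   # only g3 (4 vs 1); g4 is exactly 2x
  expect_identical(d$n_compared, 4L)     # ND excluded
  expect_identical(discordance_count(f2, f1)$n_discordant, d$n_discordant)
  # boundary: exactly `factor`-fold is concordant
  expect_identical(
    discordance_count(setNames(2, "g"), setNames(1, "g"))$n_discordant, 0L)
  expect_identical(
    discordance_count(setNames(2.001, "g"), setNames(1, "g"))$n_discordant, 1L)
})

test_that("housekeeping CV comparison: identical replicates give all-zero CVs", {
  m <- matrix(rpois(200, 100) + 1L, 100, 2,
              dimnames = list(paste0("g", 1:100), c("r1", "r2")))
  m[, 2] <- m[, 1]
  sv <- matrix(rlnorm(100), 100, 2, dimnames = dimnames(m))
  sv[, 2] <- sv[, 1]
  res <- hk_cv_compare(m, sv, rownames(m))
  for (meth in c("UQ", "RLE", "TMM", "SNV"))
    expect_equal(max(res$cvs[[meth]]), 0)
  expect_identical(sort(res$summary$method), sort(c("UQ", "RLE", "TMM", "SNV")))
  expect_error(hk_cv_compare(m, sv, "nope"), "intersect")
})

test_that("a pure depth change leaves all four methods' CVs comparable", {
  # technical replicates differing only in sequencing depth (2.5x): every
  # method handles a global scale change, so no method should stand out
  set.seed(51)
  n <- 400
  mu <- rlnorm(n, log(300), 0.4)
  m <- cbind(r1 = rpois(n, mu), r2 = rpois(n, 2.5 * mu))
  rownames(m) <- paste0("g", seq_len(n))
  sv <- cbind(r1 = rpois(n, 300) / pmax(rpois(n, 300), 1),
              r2 = rpois(n, 750) / pmax(rpois(n, 750), 1))
  rownames(sv) <- rownames(m)
  res <- hk_cv_compare(m, sv, rownames(m))
  med <- setNames(res$summary$median, res$summary$method)
  expect_true(all(is.finite(med)))
  expect_lt(max(med), 2 * min(med))
})
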