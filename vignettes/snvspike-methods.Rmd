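---
title: "SNV internal-standard normalization: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNV internal-standard normalization: model, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvspike)
```

## The normalization model

A chimpanzee RNA aliquot is spiked into each human RNA sample before any
processing. Because the two transcriptomes differ by single-nucleotide
substitutions at roughly one per 210 bp, a read covering such a position can
be assigned to its species, and each transcript acquires an internal
reference that experienced exactly the same extraction, degradation,
fragmentation, priming, amplification and sequencing as the human molecules.

Let $h_{gl}$ and $c_{gl}$ be the human- and chimpanzee-allele read counts at
informative locus $l$ of gene $g$. The model assumes that any technical
distortion acts multiplicatively and locus-locally:
$E[h_{gl}] = b_{gl}\,a^H_g\,p_l$ and $E[c_{gl}] = b_{gl}\,a^C_g\,p_l$,
where $a^H_g, a^C_g$ are the human and spike abundances, $p_l$ the chance a
random fragment covers the locus, and $b_{gl}$ the cumulative technical bias
at that locus. The locus ratio $h_{gl}/c_{gl}$ estimates $a^H_g/a^C_g$ with
$b_{gl}$ and $p_l$ cancelled — this is the entire content of the method. The
transcript-level value sums counts over loci before dividing:

$$r_g = \frac{\sum_l h_{gl}}{\sum_l c_{gl}}.$$

Sum-then-divide pools coverage so that loci with a zero chimpanzee count do
not produce undefined values (a mean of per-locus ratios would either drop
them or blow up); it is also the natural inverse-variance-leaning pooling
when locus depths vary. Where a mean of per-locus ratios is genuinely wanted
— as a per-locus dispersion diagnostic — it appears only in
`flatten_profile()`.

Differential expression between samples 1 and 2 spiked from one batch is
$r^{(1)}_g / r^{(2)}_g$: the spike abundances cancel too, so no assumption
about the spike's own composition is needed beyond batch identity. Division
by zero at any stage yields the typed missing value ND (`NA` internally, the
literal `ND` in every TSV); ND propagates through folds and is excluded,
with the effective $n$ reported, from every summary statistic.

### Assumptions and when they fail

* **Substitution-only divergence.** Indels or isoform differences between
  the species would break the locus-local bias equality; the discovery
  filter (homozygous, biallelic, single-base) avoids such sites but cannot
  rescue transcripts whose spike counterpart is absent or structurally
  different — those yield ND or biased loci.
* **Locus-local multiplicative bias.** Biases that read *through* the
  allele itself (e.g. allele-specific secondary structure) would not cancel.
* **Shared batch.** Samples compared against each other must receive spike
  RNA from the same batch; the simulator enforces identical per-transcript
  spike weights across samples.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `snv_rate` | 1/210 | per bp | observed human–chimpanzee transcript divergence |
| `length_mean`, `length_sd` | 2940, 600 | bp | gives ~14 SNVs per transcript at `snv_rate`, the observed per-transcript density; matches typical mRNA lengths |
| `spike_fraction` | 1.0 | chimp:human mass ratio | equal-mass spike; 0.25 is the economy design whose ratios center on 4 |
| `min_depth` (discovery) | 10 | reads | below this, a 90% majority is indistinguishable from a heterozygote or error pileup |
| homozygosity threshold | 0.90 | major-allele fraction | tolerates up to 10% sequencing error while excluding heterozygous loci (~50%) |
| `count_cutoff` | 40 | reads per species | low-count ratios are noise-dominated; 40 reads ≈ RPKM 2.8 at typical depth |
| `error_rate` | 0.001 | per base | short-read substitution error scale |
| `degradation_rate` | 0 (off) | per bp | calibrate with `calibrate_degradation(0.7, 2000)` ≈ 6.0e-4 so 70% of 2-kb molecules lose 5′ capture, the reference partial-digestion condition |
| `trim_M`, `trim_A` (TMM) | 0.30, 0.05 | trim fractions | the published defaults of the weighted trimmed-mean method |

The count cutoff is applied to **both** species' summed counts
(`min(n_human, n_chimp) >= 40`, boundary inclusive). The denominator is the
more dangerous side — a small chimpanzee count makes the ratio variance
explode — so guarding only the human side would defeat the cutoff's purpose;
inclusivity at exactly 40 is fixed for testability.

## What the simulator emulates — and what it does not

`gen_transcriptome()` draws random human transcripts, plants substitutions
at `snv_rate`, and derives the chimpanzee orthologs; abundances are
log-normal with configurable fold changes between samples A and B, and the
spike profile is either independent (a different cell type, the realistic
case) or matched to the human sample (useful when an exact per-transcript
ratio is wanted). `sample_reads()` draws single-end sense-strand reads with
the joint distribution over (species, transcript, start) proportional to
mixture weight × positional bias × degradation survival, then applies
uniform substitution errors.

Positional bias profiles are fixed smooth stand-ins for mechanisms that are
only known qualitatively: `"hexamer-like"` is a mid-body hump
($0.3 + \sin^2 \pi u$ over relative start position $u$),
`"nextera-like"` a 5′ ramp ($0.4 + e^{-3u}$). Degradation is an
exponential survival weight $e^{-\lambda d}$ on the distance $d$ from a
fragment's 3′ side to the transcript 3′ end, modeling oligo-dT capture that
requires an intact 3′ path; $\lambda$ is calibrated from a stated fraction
of full-length molecules lost rather than from any measured cut-rate data.

Not modeled: paired-end inserts, quality-score-dependent errors, PCR
duplicates, rRNA contamination, isoforms, indels, mapping ambiguity.
Consequently, passing tests show that the *statistical machinery* of the
method behaves as claimed under controlled biases — they do not certify
performance on real libraries, where mapping artifacts and isoform structure
add failure modes the simulator excludes by construction.

## Numerical and design choices

* **Coordinates** are 0-based internally and in BED output (half-open);
  pileup TSVs use 0-based `pos0`.
* **Tie-breaking** in `major_allele()` follows the fixed base order
  A < C < G < T; a tie can never pass the 90% homozygosity rule anyway.
* **Start-position sampling** uses inverse-CDF lookup on the cumulative
  weight vector (`findInterval`), which is deterministic under the
  configuration seed and O(n log L).
* **Pileups** have no depth cap and no quality filtering (simulated reads
  carry none); full-transcript pileups are built in bounded-size chunks,
  and a position-restricted mode reproduces exactly the full pileup's
  columns at those positions (proven in tests).
* **RLE factor convention.** All three baseline normalizers return
  *residual* factors with geometric mean 1, to be used as
  `count / (libsize × factor)`. The median-of-ratios statistic is therefore
  divided by library size inside `size_factors_rle()`; the absolute
  DESeq-style size factor is `factor × libsize`. This makes UQ, RLE and TMM
  interchangeable in `normalize_matrix()` and lets all three cancel a pure
  library-size change — the property the housekeeping-CV comparison relies
  on. Tests verify equality with DESeq2's estimator on the absolute scale
  and with edgeR's TMM directly.
* **TMM reference selection** is the sample whose upper-quartile/library-size
  statistic is closest to the mean of that statistic; weights are the
  delta-method inverse variances; genes must be positive in both sample and
  reference.
* **Agreement "mean"** is the mean of per-gene ratios (not the ratio of
  means): the replicate-agreement plot is built from per-gene values, and
  the mean-of-ratios is the statistic that is exactly 1 under perfect
  agreement gene by gene. With Poisson counts it carries a small positive
  bias of order $1/\bar{c}$ from the random denominator, visible as values
  slightly above 1 at finite depth.
* **Flatness metric.** Coverage flattening is usually shown visually; as a
  scalar we use the within-transcript CV of per-position depth (raw) versus
  the CV of per-locus SNV ratios (normalized). The metric is
  artifact-defined and labeled as such in outputs.
* **Housekeeping genes** for the method comparison are, in simulation, the
  genes with true fold change 1 — the simulator's stand-in for an external
  stable-gene catalog.

## Problem sizes used in validation

The acceptance computations run at desk scale, chosen so every directional
margin is at least twofold: spike-ratio recovery uses 2,000 transcripts at
~2.9M reads (mean summed per-species counts ≥ 200) averaged over 10
simulations; replicate agreement Poisson-resamples expected counts
(≥ 150 per species) for 2,000 transcripts × 10 simulations; discovery
false-positive checks run 20 seeds at ~100× depth with 1% error;
bias-cancellation and degradation contrasts use 300 transcripts at ~3,000×
summed depth; flattening uses 25 transcripts at ~1,300× position depth.

## Known limitations

* Mean-of-ratio statistics are reported without bias correction; at summed
  counts near the cutoff the $1/\bar c$ ratio bias is ~2–3%.
* The per-position allele counting treats overlapping loci on one read as
  independent observations, which mildly overdisperses transcript-level
  ratios relative to a read-level model (spacing 210 bp vs 150 bp reads
  keeps the effect small).
* `find_informative()` discovers from pileup majorities, not genotype
  likelihoods; at depths just above 10 its error tolerance is a hard 90%
  threshold, not a calibrated posterior.
* The baselines are global scalers by design; their role here is
  comparison, not recommendation.
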