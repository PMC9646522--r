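---
title: "Modelling neutral somatic mutation rates and testing mutational burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling neutral somatic mutation rates and testing mutational burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Most somatic mutations in a tumour are neutral passengers. Driver mutations
— those under positive selection — recur across tumours, so a genomic
element harbouring drivers accumulates more mutations across a cohort than
the neutral rate predicts. Turning that intuition into a test requires an
accurate neutral model, which is hard because the somatic mutation rate
varies over orders of magnitude along the genome: at kilobase scale it
tracks epigenomic organisation (replication timing, chromatin state), and
at base-pair scale it tracks the trinucleotide sequence context of
mutational processes.

`mutburden` separates the two scales:

1. **Regional model.** For every 10-kb bin $R$ the package predicts the
   mean $\mu_R$ and variance $\sigma^2_R$ of the neutral SNV count from
   per-bin feature matrices (epigenomic tracks averaged in 100-bp windows,
   plus sequence-derived rows).
2. **Context model.** Genome-wide maximum-likelihood probabilities
   $p_{aX \to Yb}$ for the 192 strand-specific trinucleotide mutation
   categories distribute those mutations to individual positions. Within a
   region the probabilities are renormalised so that all possible SNVs of
   the region sum to 1.

Conceptually, mutations arise in region $R$ at an unknown rate drawn from a
Gamma distribution with mean $\mu_R$ and variance $\sigma^2_R$, and are
then assigned to positions by context. Marginally, the count over any set
$I$ of possible SNVs is closed-form negative binomial:

$$\sum_I M_{i,aX\to Yb} \sim
\mathrm{NB}\!\left(\alpha_R,\;
\frac{1}{1 + C_{\mathrm{SNV}}\,\theta_R \sum_I p_{R,aX\to Yb}}\right),
\qquad
\alpha_R = \mu_R^2/\sigma_R^2,\;\; \theta_R = \sigma_R^2/\mu_R,$$

with mean $C_{\mathrm{SNV}}\,\mu_R \sum_I p$. The scaling factor
$C_{\mathrm{SNV}}$ adapts a trained map to a target cohort of different
size, estimated from a putatively neutral mutation class (synonymous SNVs
excluding TP53, or low-impact missense SNVs for targeted panels that lack
synonymous calls). Sets spanning several regions are handled by exact
discrete convolution of the per-region distributions; the burden p-value is
the upper tail $P(X \ge \mathrm{observed})$.

# The regional rate model

The regional model is a small convolutional network coupled to a Gaussian
process:

* **Network.** Two convolution blocks (ReLU) over the window axis, global
  average pooling, then a dense projection to a 16-dimensional embedding
  and a linear head. It is trained full-batch with Adam on mean squared
  error against the observed per-bin counts, with early stopping on a
  validation split. Convolutions and backpropagation are implemented
  directly as matrix operations (`im2col`), which is entirely adequate at
  the scale of thousands of bins and keeps the package dependency-free.
* **GP head.** With the network frozen, an exact Gaussian process with an
  isotropic RBF kernel and learned observation noise is fitted to the
  embeddings of the training bins (hyperparameters by marginal likelihood,
  L-BFGS with analytic gradients). Beyond 2,000 training bins a seeded
  random subset is used; desk-scale studies never reach that regime.

**From count variance to rate variance.** The GP is fitted to counts, so
its noise term absorbs both Poisson counting noise and genuine rate
dispersion. Reporting that total as $\sigma^2_R$ would double-count the
Poisson part (the negative binomial adds it back) and, worse, a
homoscedastic noise estimate badly miscalibrates intervals across bins of
different rate. The package therefore decomposes: count variance
$= \mu + \theta\mu$, with the Gamma rate-dispersion scale $\theta$ fitted
by negative binomial maximum likelihood on the validation bins. The
reported variance is $\sigma^2_R = v_R + \hat\theta\,\mu_R$, where $v_R$ is
the epistemic GP variance of the mean. On generative synthetic data the
resulting central 95% Gamma intervals cover the latent regional rate at
nominal level (an acceptance test).

**Cross-validation.** QC-passing bins are partitioned uniformly at random
into five equal folds. Each fold is predicted by a model trained (80%) and
validated (20%) on the other four folds only, so no bin is ever scored by
a model that saw it. Maps trained with the optional flanking-count inputs
(SNV counts in the 100-kb regions flanking each bin, log1p-transformed and
scaled by cohort size) are refused by the megabase-scale benchmark, since
flanking counts leak observed data between neighbouring bins;
`varianceExplained(..., scale = "1Mb")` directs the user to a flankless
map. Accuracy is summarised as the squared Pearson correlation between
predicted and observed counts, at native 10-kb resolution or summed within
1-Mb windows.

**QC.** A bin fails when more than 10% of its bases are undefined, more
than 20% of its track signal is missing, or it overlaps a user-supplied
exclusion set. Thresholds are configurable; reasons are recorded per bin.
Sex chromosomes are excluded by default because the observed X count
depends on the sex composition of a cohort.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `binSize` | 10,000 bp | regional resolution of the rate map |
| `windowBp` | 100 bp | track-averaging window inside a bin |
| `embeddingDim` | 16 | embedding passed from the network to the GP |
| `convFilters`, `kernelWidths` | (12, 12), (5, 5) | network capacity; desk-scale defaults |
| `epochs`, `lr`, `patience` | 200, 0.01, 25 | Adam schedule and early stopping |
| `flankBp` | 100,000 bp | flanking-count window (optional input) |
| `maxCoding` | 100 | hypermutator threshold (coding mutations/sample); promoter/UTR scans conventionally relax to 3,000 |
| `minAC` | 5 | population allele count at which a germline blacklist entry removes a record |
| FDR / Bonferroni | 0.1 / 0.05 | significance thresholds on adjusted burdens |

All randomness (fold assignment, splits, initialisation, Monte Carlo)
derives from explicit integer seeds recorded in outputs.

# Numerical choices and degenerate inputs

* Null distributions are truncated where the upper-tail mass falls below
  $10^{-12}$; convolution is exact direct polynomial multiplication (the
  shared-q case reproduces NB additivity to $10^{-10}$).
* Under-dispersed predictions ($\sigma^2 \le \mu$, possible from the GP)
  are clamped to $\sigma^2 = \mu(1+10^{-6})$ and flagged; predicted means
  and variances are floored at $10^{-6}$.
* A query set with zero probability mass yields a point mass at zero and
  p-value 1; p-values below $10^{-300}$ are reported as that bound.
* Positions whose trinucleotide contains an undefined base carry no
  context probability: they are excluded from region normalisation, and
  query entries there contribute zero mass with a warning.
* Monte Carlo enrichment CIs use parametric double resampling (expected
  counts from the null; observed counts from a dispersion-matched NB
  re-centred at the observation) with the ratio denominator floored at 0.5.
* Multiple mutations of one sample at one position collapse to one by
  default (`countRecurrent` restores raw counting); elements where one
  sample contributes several qualifying mutations are flagged and can be
  dropped (`dropMultiSample`), mirroring the usual treatment of splice
  burdens.
* Indel burdens reuse the region's SNV dispersion with a uniform position
  probability and a separate scaling factor; results are explicitly
  flagged as approximate, since no indel context model is fitted.

# Design choices where the design was open

* **Coordinates.** Everything internal is a `GRanges` (1-based, closed),
  the Bioconductor idiom; BED (0-based half-open) and VCF/MAF (1-based)
  dialects are converted at the I/O boundary only.
* **Context estimator scale.** The MLE denominator is genome-wide context
  occurrences over the included intervals. Because region probabilities
  are renormalised within each region, every downstream quantity is
  invariant to the estimator's overall scale — a property the test suite
  asserts directly, which also makes the estimator robust to the exact
  choice of denominator intervals.
* **Strandedness.** The 192 categories are strand-specific on the
  reference strand (64 contexts × 3 alternate alleles), not
  pyrimidine-collapsed.
* **"Nucleotide content" row.** Implemented as the fraction of defined
  (non-N) bases per window; the GC row is GC among defined bases.
* **Track standardisation.** Per-track standardisation statistics are
  computed on training bins and stored with each model; all-missing
  windows are imputed to zero at averaging time and the per-bin
  missingness fraction feeds QC.
* **Sample assignment in the simulator.** Neutral mutations are assigned
  uniformly to samples — the marginal model constrains totals only — so
  per-sample statistics of simulated cohorts should not be
  over-interpreted.
* **Power analysis.** Power is evaluated at the per-element significance
  level supplied by the user; passing a genome-wide-corrected level gives
  the conservative variant.

# What the simulator emulates — and what it does not

`synthReference`, `synthTracks`, `synthCohort`, `spikeDrivers` generate,
respectively: i.i.d. genomes at a target GC content; tracks that are
monotone transforms of a smooth (AR(1)) latent regional rate plus Gaussian
noise; cohorts drawn from the model's own generative process
(Gamma-distributed per-bin rates, Poisson counts, multinomial allocation
to positions by context, uniform sample assignment); and spiked driver
mutations carried independently by each sample with probability $f$.

Default study conditions used throughout the tests: 10-kb bins, three
informative tracks at 100-bp step with noise 0.2, mean per-bin rates of
tens to hundreds of SNVs, and Gamma rate-dispersion scale
$\theta = 2$ ($\sigma^2 = 2\mu$) — strong overdispersion of the kind seen
in somatic counts, and large enough to be statistically identifiable at a
few hundred bins. Problem sizes were chosen as the smallest at which each
property is statistically decidable: genomes of 1–10 Mb (100–1,000 bins),
single-fold trainings of 200–500 bins, 500 neutral elements for
calibration, $10^6$ SNVs for context recovery and $10^5$ draws for the
distribution oracles.

Passing tests on these data show that the statistical machinery is
faithful to its own generative model. They do not show that real tumour
cohorts satisfy that model: real epigenomic tracks are not monotone
transforms of the true rate; mutational processes vary between samples
(signatures, hypermutation) rather than allocating uniformly; indels and
structural events have their own context preferences; and driver selection
is not a uniform spike over a query set. Cohort-level hygiene (hypermutator
removal, germline blacklist filtering) mitigates but does not remove such
violations.

# Known limitations

* The network and GP are desk-scale: genome-wide human maps with hundreds
  of tracks would need mini-batching and a sparse GP; the architecture
  here fixes the interface (feature matrix in, 16-dim embedding and
  mean/variance out), not production capacity.
* The indel null is an explicit approximation (uniform positions, SNV
  dispersion).
* Functional categories (synonymous, missense, low-impact missense, …)
  are accepted as upstream annotation and never computed.
* One context table and one map serve a whole cohort; per-sample
  signatures are out of scope.

# A minimal run

```{r example, eval = FALSE}
library(mutburden)
library(GenomicRanges)

ref <- synthReference(c(chr1 = 2e6), gc = 0.41, seed = 1)
tracks <- synthTracks(ref, nTracks = 3, noise = 0.2, meanRate = 100,
                      seed = 2)
bins <- attr(tracks, "bins")
counts <- rpois(length(bins), attr(tracks, "latentRate"))

feats <- binFeatures(bins, tracks, ref)
bins <- assignFolds(qcFilter(bins, ref, missingFrac = feats$missingFrac),
                    k = 5, seed = 3)
map <- buildRateMap(bins, feats$features, counts,
                    rateModelConfig(seed = 4))
varianceExplained(map, counts)

cohort <- synthCohort(map, randomContextTable(ref, seed = 5), ref,
                      nSamples = 100, seed = 6)
table <- fitContextProbs(cohort, ref)
elements <- GRangesList(candidate = GRanges("chr1",
                                            IRanges(500001, 501000)))
testElements(cohort, map, table, ref, elements = elements,
             ciSims = 1000, seed = 7)
```
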