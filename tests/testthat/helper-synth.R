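suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(Biostrings)
})

# A self-consistent synthetic study: reference, latent-rate-driven tracks,
# truth rate map (the generative parameters), and a random context table.
# dispersion is the Gamma rate-dispersion scale theta (sigma2 = theta * mu),
# the strong overdispersion typical of somatic counts.
makeScenario <- function(genomeLength = 2e6, gc = 0.41, nTracks = 3,
                         noise = 0.2, meanRate = 100, dispersion = 2,
                         binSize = 10000, seed = 1L) {
  ref <- synthReference(c(chr1 = genomeLength), gc = gc, seed = seed)
  tracks <- synthTracks(ref, nTracks = nTracks, noise = noise,
                        meanRate = meanRate, binSize = binSize,
                        seed = seed + 1L)
  bins <- attr(tracks, "bins")
  mu <- attr(tracks, "latentRate")
  s2 <- dispersion * mu
  mcols(bins)$mu <- mu
  mcols(bins)$sigma2 <- s2
  mcols(bins)$qc_pass <- rep(TRUE, length(bins))
  map <- RateMap(bins, cohortLabel = "synthetic")
  table <- randomContextTable(ref, seed = seed + 2L)
  list(ref = ref, tracks = tracks, bins = bins, map = map, table = table,
       mu = mu, s2 = s2, latent = attr(tracks, "latentValue"))
}

# truth rate map over externally built bins (no sequence needed)
makeTruthMap <- function(nBins, mu, s2, binSize = 10000, chrom = "chr1") {
  bins <- GRanges(chrom, IRanges(start = (seq_len(nBins) - 1L) * binSize + 1L,
                                 width = binSize))
  mcols(bins)$mu <- mu
  mcols(bins)$sigma2 <- s2
  mcols(bins)$qc_pass <- rep(TRUE, nBins)
  RateMap(bins)
}

# minimal cohort from parallel vectors
makeCohort <- function(chrom, pos, ref, alt, sample = NULL, category = "other",
                       mclass = NULL, nSamples = NULL) {
  n <- length(pos)
  chrom <- rep_len(chrom, n)
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  if (is.null(sample)) sample <- paste0("s", seq_len(n))
  sample <- rep_len(sample, n)
  if (is.null(mclass))
    mclass <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
                     ifelse(nchar(alt) > 1, "insertion", "deletion"))
  gr <- GRanges(chrom, IRanges(pos, width = rep(1L, n)))
  mcols(gr) <- DataFrame(sample = sample, ref = ref, alt = alt,
                         mclass = mclass,
                         category = rep_len(category, n))
  MutationCohort(gr, nSamples = nSamples)
}

# uniform context table: every category has the same probability
uniformContextTable <- function(reference, prob = 1e-3) {
  tab <- randomContextTable(reference, seed = 1L)
  tb <- contextProbs(tab)
  tb$prob <- ifelse(tb$occurrences > 0, prob, 0)
  methods::new("ContextTable", table = tb, nMutationsFit = 0L,
               cohortLabel = "uniform")
}

# constant-signal TrackSet covering the chromosomes of a reference
constantTracks <- function(reference, nChromatin = 3, nReplication = 1,
                           value = 0.5, step = 100L) {
  lens <- referenceLengths(reference)
  mk <- function(v) lapply(lens, function(L)
    rep(v, as.integer(ceiling(L / step))))
  n <- nChromatin + nReplication
  values <- lapply(seq_len(n), function(i) mk(value))
  names(values) <- paste0("t", seq_len(n))
  TrackSet(values,
           kinds = c(rep("chromatin", nChromatin),
                     rep("replication_timing", nReplication)),
           steps = step)
}
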