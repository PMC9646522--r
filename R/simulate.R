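#' Generate a synthetic reference genome
#'
#' Independent bases with `P(G) + P(C) = gc` (split evenly between G and C,
#' and between A and T). Deterministic given `seed`.
#'
#' @param lengths named integer vector of chromosome lengths (a single
#'   unnamed value becomes one chromosome `chr1`).
#' @param gc GC content in `[0, 1)` (strictly below 1; 0 yields an A/T-only
#'   genome).
#' @param seed integer seed.
#' @return `DNAStringSet`.
#' @export
synthReference <- function(lengths, gc = 0.41, seed = 1L) {
  stopifnot(all(lengths > 0), gc >= 0, gc < 1)
  if (is.null(names(lengths)))
    names(lengths) <- paste0("chr", seq_along(lengths))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- withr::with_seed(seed, {
    vapply(lengths, function(L)
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""),
      character(1))
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(lengths)
  out
}

#' Generate synthetic signal tracks driven by a latent regional rate
#'
#' Draws a smooth latent per-bin log-rate (an AR(1) process along each
#' chromosome), maps it through `rateFun` to the latent regional rate, and
#' emits `nTracks` tracks that are monotone transforms of the latent value
#' plus Gaussian noise, at a fixed native step. The latent rate is stored in
#' the `"latentRate"` attribute for truth-based tests (with the per-bin
#' latent value in `"latentValue"`).
#'
#' @param reference `DNAStringSet` reference genome.
#' @param nTracks number of tracks (the last is labelled replication
#'   timing, the rest chromatin).
#' @param noise standard deviation of the per-element Gaussian track noise
#'   (the latent value has unit variance).
#' @param rateFun function latent value -> regional rate mean (default
#'   `function(u) meanRate * exp(0.5*u) / mean(exp(0.5*u))`).
#' @param meanRate target mean per-bin rate for the default `rateFun`.
#' @param binSize bin width in bp.
#' @param step native track step in bp.
#' @param ar AR(1) coefficient of the latent process across bins.
#' @param seed integer seed.
#' @return A [TrackSet-class] with attributes `"latentRate"`, `"latentValue"`
#'   and `"bins"` (the `GRanges` the latent refers to).
#' @export
synthTracks <- function(reference, nTracks = 4, noise = 0.3, rateFun = NULL,
                        meanRate = 100, binSize = 10000, step = 100,
                        ar = 0.5, seed = 1L) {
  stopifnot(nTracks >= 1)
  bins <- tileGenomeBins(reference, binSize, dropSexChroms = FALSE)
  nb <- length(bins)
  latent <- withr::with_seed(seed, {
    u <- numeric(nb)
    chroms <- as.character(GenomicRanges::seqnames(bins))
    for (ch in unique(chroms)) {
      ii <- which(chroms == ch)
      e <- stats::rnorm(length(ii), 0, sqrt(1 - ar^2))
      u[ii] <- as.numeric(stats::filter(e, ar, method = "recursive"))
    }
    u
  })
  if (is.null(rateFun))
    rateFun <- function(u) meanRate * exp(0.5 * u) / mean(exp(0.5 * u))
  rate <- rateFun(latent)
  perBin <- binSize %/% step
  lens <- referenceLengths(reference)
  values <- withr::with_seed(seed + 1L, {
    lapply(seq_len(nTracks), function(t) {
      slope <- 0.5 + 0.5 * t / nTracks     # distinct monotone transforms
      vv <- lapply(names(lens), function(ch) {
        n <- as.integer(ceiling(lens[[ch]] / step))
        ii <- which(as.character(GenomicRanges::seqnames(bins)) == ch)
        base <- rep(slope * latent[ii], each = perBin)
        v <- rep(NA_real_, n)
        v[seq_along(base)] <- base +
          if (noise > 0) stats::rnorm(length(base), 0, noise) else 0
        v
      })
      names(vv) <- names(lens)
      vv
    })
  })
  names(values) <- paste0("track", seq_len(nTracks))
  kinds <- c(rep("chromatin", max(nTracks - 1L, 1L)),
             if (nTracks > 1L) "replication_timing")
  ts <- TrackSet(values, kinds = kinds, steps = step)
  attr(ts, "latentRate") <- rate
  attr(ts, "latentValue") <- latent
  attr(ts, "bins") <- bins
  ts
}

#' A random context table for simulation studies
#'
#' Category probabilities drawn i.i.d. from an exponential distribution and
#' scaled so the genome-wide mean per-position mutation probability is of
#' realistic magnitude; occurrences are taken from the supplied reference.
#'
#' @param reference `DNAStringSet` whose context occurrences fill the table.
#' @param meanProb mean per-category probability (default 1e-3).
#' @param seed integer seed.
#' @return A [ContextTable-class].
#' @export
randomContextTable <- function(reference, meanProb = 1e-3, seed = 1L) {
  occ <- rep(countContextOccurrences(reference), each = 3L)
  prob <- withr::with_seed(seed, stats::rexp(192, rate = 1 / meanProb))
  prob <- pmin(prob, 0.3)
  prob[occ == 0] <- 0
  tb <- contextScaffold()
  tb$count <- 0L
  tb$occurrences <- occ
  tb$prob <- prob
  tb$zero_context <- occ == 0
  new("ContextTable", table = tb, nMutationsFit = 0L,
      cohortLabel = "synthetic")
}

#' Simulate a neutral cohort from the generative model
#'
#' The generative process the burden null is derived from: in each bin a
#' latent rate `lambda ~ Gamma(shape = mu^2/sigma2, scale = C*sigma2/mu)` is
#' drawn, the bin's mutation count is `Poisson(lambda)`, and mutations are
#' allocated to positions and alternate alleles multinomially according to
#' the normalised context probabilities of the bin. Records are assigned
#' uniformly to samples. Marginally the per-bin count is negative binomial
#' with mean `C*mu` and variance `C*mu + C^2*sigma2`.
#'
#' @param map a [RateMap-class] supplying per-bin `mu` and `sigma2`.
#' @param table a [ContextTable-class].
#' @param reference `DNAStringSet` reference genome.
#' @param nSamples number of samples.
#' @param C cohort scaling factor of the simulation.
#' @param categoryProbs optional named probability vector used to label
#'   records with functional categories (labels are independent of
#'   position).
#' @param seed integer seed.
#' @return A [MutationCohort-class].
#' @export
synthCohort <- function(map, table, reference, nSamples = 100, C = 1,
                        categoryProbs = NULL, seed = 1L) {
  bins <- rateBins(map)
  ok <- which(S4Vectors::mcols(bins)$qc_pass)
  mu <- S4Vectors::mcols(bins)$mu
  s2 <- S4Vectors::mcols(bins)$sigma2
  idx <- referenceContextIndex(reference)
  prob <- table@table$prob
  sc <- contextScaffold()
  ctxOfCat <- rep(0:63, each = 3L)

  res <- withr::with_seed(seed, {
    perBin <- vector("list", length(ok))
    for (k in seq_along(ok)) {
      b <- ok[k]
      shape <- mu[b]^2 / s2[b]
      scale <- C * s2[b] / mu[b]
      lambda <- stats::rgamma(1, shape = shape, scale = scale)
      cnt <- stats::rpois(1, lambda)
      if (cnt == 0) next
      ch <- as.character(GenomicRanges::seqnames(bins))[b]
      span <- GenomicRanges::start(bins)[b]:GenomicRanges::end(bins)[b]
      ctx <- idx[[ch]][span]
      keep <- !is.na(ctx)
      span <- span[keep]; ctx <- ctx[keep]
      nPerCtx <- tabulate(ctx + 1L, 64L)
      w <- nPerCtx[ctxOfCat + 1L] * prob          # weight per category
      if (sum(w) <= 0) next
      nPerCat <- as.integer(stats::rmultinom(1, cnt, w))
      # positions grouped by context for uniform sampling within context
      ord <- order(ctx)
      spanS <- span[ord]
      starts <- c(0L, cumsum(nPerCtx))            # offsets into spanS
      cat192 <- rep(seq_len(192L), nPerCat)
      cx <- ctxOfCat[cat192]
      off <- vapply(which(nPerCat > 0), function(cc) {
        list(starts[ctxOfCat[cc] + 1L] +
               sample.int(nPerCtx[ctxOfCat[cc] + 1L], nPerCat[cc],
                          replace = TRUE))
      }, vector("list", 1))
      pick <- spanS[unlist(off)]
      perBin[[k]] <- list(chrom = rep(ch, cnt), pos = pick, cat192 = cat192)
    }
    perBin <- perBin[!vapply(perBin, is.null, logical(1))]
    chromL <- unlist(lapply(perBin, `[[`, "chrom"))
    posL <- unlist(lapply(perBin, `[[`, "pos"))
    catL <- unlist(lapply(perBin, `[[`, "cat192"))
    if (is.null(posL)) { chromL <- character(0); posL <- integer(0)
                         catL <- integer(0) }
    nrec <- length(posL)
    samples <- if (nrec) paste0("s", sample.int(nSamples, nrec,
                                                replace = TRUE))
               else character(0)
    cats <- if (!is.null(categoryProbs) && nrec)
      sample(names(categoryProbs), nrec, replace = TRUE,
             prob = categoryProbs) else rep("other", nrec)
    list(chrom = chromL, pos = posL, cat192 = catL, sample = samples,
         category = cats)
  })
  gr <- GenomicRanges::GRanges(res$chrom,
                               IRanges::IRanges(res$pos, width = 1L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    sample = res$sample, ref = sc$X[res$cat192], alt = sc$alt[res$cat192],
    mclass = rep("SNV", length(gr)), category = res$category)
  MutationCohort(gr, nSamples = nSamples, cancerLabel = "synthetic")
}

#' Spike driver mutations into a cohort
#'
#' Each sample independently carries one driver mutation, drawn uniformly
#' from the query set, with probability `f` (the carrier frequency). Spiked
#' records are flagged in the `spiked` metadata column.
#'
#' @param cohort a [MutationCohort-class].
#' @param querySet data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param f carrier frequency in `[0, 1]`.
#' @param seed integer seed.
#' @return A [MutationCohort-class] including the spiked records.
#' @export
spikeDrivers <- function(cohort, querySet, f, seed = 1L) {
  stopifnot(f >= 0, f <= 1)
  if (f > 0 && (is.null(querySet) || nrow(querySet) == 0))
    stop("empty query set with positive carrier frequency")
  gr <- mutationRecords(cohort)
  if (is.null(S4Vectors::mcols(gr)$spiked))
    S4Vectors::mcols(gr)$spiked <- rep(FALSE, length(gr))
  if (f == 0)
    return(MutationCohort(gr, nSamples = nSamples(cohort),
                          cancerLabel = cancerLabel(cohort)))
  ns <- nSamples(cohort)
  res <- withr::with_seed(seed, {
    carrier <- which(stats::runif(ns) < f)
    pick <- sample.int(nrow(querySet), length(carrier), replace = TRUE)
    list(carrier = carrier, pick = pick)
  })
  if (!length(res$carrier))
    return(MutationCohort(gr, nSamples = ns,
                          cancerLabel = cancerLabel(cohort)))
  qs <- querySet[res$pick, , drop = FALSE]
  add <- GenomicRanges::GRanges(qs$chrom, IRanges::IRanges(qs$pos,
                                                           width = 1L))
  S4Vectors::mcols(add) <- S4Vectors::DataFrame(
    sample = paste0("s", res$carrier), ref = qs$ref, alt = qs$alt,
    mclass = rep("SNV", nrow(qs)),
    category = rep("other", nrow(qs)), spiked = rep(TRUE, nrow(qs)))
  MutationCohort(c(gr, add), nSamples = ns,
                 cancerLabel = cancerLabel(cohort))
}

#' Monte Carlo power analysis over a carrier-frequency grid
#'
#' For each carrier frequency `f`, simulates `nSim` cohorts: a neutral count
#' drawn from the element's null and a spiked count `Binomial(nSamples, f)`
#' (one driver per carrier, uniform over the query set, hence always inside
#' it), then computes the burden p-value of the total. Power is the fraction
#' of simulations with `p < alpha`, reported with its binomial Monte Carlo
#' standard error.
#'
#' @param querySet data.frame with columns `chrom`, `pos`, `alt` (and
#'   optionally `ref`).
#' @param map a [RateMap-class].
#' @param table a [ContextTable-class].
#' @param reference `DNAStringSet` reference genome.
#' @param fGrid carrier frequencies to evaluate.
#' @param nSamples cohort size.
#' @param alpha per-element significance level (a genome-wide-corrected
#'   level may be supplied instead for the conservative variant).
#' @param nSim simulations per grid point (>= 100 recommended for the
#'   reported standard errors).
#' @param C cohort scaling factor.
#' @param seed integer seed.
#' @return data.frame with `f`, `power`, `se`, `alpha`, `nSim`, `seed`.
#' @export
powerCurve <- function(querySet, map, table, reference, fGrid, nSamples,
                       alpha = 0.05, nSim = 200, C = 1, seed = 1L) {
  stopifnot(all(fGrid >= 0), all(fGrid <= 1), nSim >= 1)
  null <- .querySetNull(querySet, map, table, reference, C)
  pow <- se <- numeric(length(fGrid))
  for (k in seq_along(fGrid)) {
    f <- fGrid[k]
    ps <- withr::with_seed(seed + k, {
      neutral <- sample.int(length(pmfValues(null)), nSim, replace = TRUE,
                            prob = pmfValues(null)) - 1L
      spiked <- stats::rbinom(nSim, nSamples, f)
      vapply(neutral + spiked, function(o)
        as.numeric(burdenPvalue(null, o)), numeric(1))
    })
    pow[k] <- mean(ps < alpha)
    se[k] <- sqrt(pow[k] * (1 - pow[k]) / nSim)
  }
  data.frame(f = fGrid, power = pow, se = se, alpha = alpha, nSim = nSim,
             seed = seed)
}

# convolved null of a query set (shared by powerCurve and tests)
.querySetNull <- function(querySet, map, table, reference, C = 1) {
  bins <- rateBins(map)
  qcBins <- bins[S4Vectors::mcols(bins)$qc_pass]
  muV <- S4Vectors::mcols(qcBins)$mu
  s2V <- S4Vectors::mcols(qcBins)$sigma2
  wIndex <- .positionWeightIndex(reference, table)
  ctxIdx <- referenceContextIndex(reference)
  prob192 <- table@table$prob
  qgr <- GenomicRanges::GRanges(querySet$chrom,
                                IRanges::IRanges(querySet$pos, width = 1L))
  binOf <- GenomicRanges::findOverlaps(qgr, qcBins, select = "first")
  keep <- !is.na(binOf)
  qs <- querySet[keep, , drop = FALSE]; binOf <- binOf[keep]
  pcat <- vapply(seq_len(nrow(qs)), function(r) {
    ctx <- ctxIdx[[qs$chrom[r]]][qs$pos[r]]
    refc <- .baseCodeTable[utf8ToInt(
      .refBaseAt(reference, qs$chrom[r], qs$pos[r])) + 1L]
    altc <- encodeBases(qs$alt[r])
    cid <- categoryId(ctx, refc, altc)
    if (is.na(cid)) 0 else prob192[cid]
  }, numeric(1))
  nulls <- lapply(unique(binOf), function(b) {
    ch <- as.character(GenomicRanges::seqnames(qcBins))[b]
    tot <- .intervalWeight(wIndex, ch, GenomicRanges::start(qcBins)[b],
                           GenomicRanges::end(qcBins)[b])
    pm <- if (tot > 0) min(sum(pcat[binOf == b]) / tot, 1) else 0
    singleRegionNull(muV[b], s2V[b], C, pm)
  })
  convolveNulls(nulls)
}
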