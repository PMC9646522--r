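#' Negative binomial parameters of the neutral null in one region
#'
#' The neutral count over a query set with context probability mass `pmass`
#' in a region with predicted rate mean `mu` and variance `sigma2`,
#' under a cohort scaling factor `C`, is negative binomial with shape
#' `alpha = mu^2/sigma2`, scale `theta = sigma2/mu` and success parameter
#' `q = 1/(1 + C*theta*pmass)`, so that the mean is `C*mu*pmass`. A
#' Gaussian-process prediction can be under-dispersed (`sigma2 <= mu`); in
#' that case `sigma2` is clamped to `mu*(1+1e-6)` (the Poisson-like limit)
#' and the result is flagged.
#'
#' @param mu predicted regional rate mean (> 0).
#' @param sigma2 predicted regional rate variance (> 0).
#' @param C cohort scaling factor (> 0).
#' @param pmass query probability mass within the region, in `[0, 1]`.
#' @return List with `alpha`, `theta`, `q`, `mean` and logical `clamped`.
#' @export
nbFromRate <- function(mu, sigma2, C, pmass) {
  if (mu <= 0) stop("mu must be positive")
  if (C <= 0) stop("C must be positive")
  if (pmass < 0 || pmass > 1) stop("pmass must lie in [0, 1]")
  clamped <- FALSE
  if (sigma2 <= mu * (1 + 1e-6)) {
    sigma2 <- mu * (1 + 1e-6)
    clamped <- TRUE
  }
  alpha <- mu^2 / sigma2
  theta <- sigma2 / mu
  q <- 1 / (1 + C * theta * pmass)
  list(alpha = alpha, theta = theta, q = q, mean = C * mu * pmass,
       clamped = clamped)
}

#' Negative binomial null over a query set in one region
#'
#' Probability mass function of
#' `NB(alpha, q)` with `P(X=k) = Gamma(k+alpha)/(Gamma(alpha) k!) *
#' q^alpha * (1-q)^k`, truncated where the upper-tail mass drops below
#' `1e-12`. `pmass = 0` yields a point mass at zero.
#'
#' @inheritParams nbFromRate
#' @return A [NullPMF-class].
#' @export
singleRegionNull <- function(mu, sigma2, C, pmass) {
  nb <- nbFromRate(mu, sigma2, C, pmass)
  if (nb$mean == 0)
    return(NullPMF(1, tail = 0, mean = 0, alphaTotal = nb$alpha))
  K <- stats::qnbinom(1e-12, size = nb$alpha, prob = nb$q,
                      lower.tail = FALSE) + 1L
  pmf <- stats::dnbinom(0:K, size = nb$alpha, prob = nb$q)
  tail <- stats::pnbinom(K, size = nb$alpha, prob = nb$q, lower.tail = FALSE)
  NullPMF(pmf, tail = tail, mean = nb$mean, alphaTotal = nb$alpha)
}

#' Exact convolution of null distributions
#'
#' Exact discrete convolution of independent per-region nulls (the null of a
#' multi-region element or gene set). The support is truncated where the
#' cumulative upper tail falls below `1e-12`; the exact mean adds and, when
#' all components are negative binomial, the total shape is carried along.
#'
#' @param nulls list of [NullPMF-class] objects (length >= 1).
#' @return A [NullPMF-class].
#' @export
convolveNulls <- function(nulls) {
  stopifnot(length(nulls) >= 1L)
  if (is(nulls, "NullPMF")) nulls <- list(nulls)
  acc <- pmfValues(nulls[[1]])
  tailAcc <- nulls[[1]]@tail
  for (i in seq_along(nulls)[-1]) {
    b <- pmfValues(nulls[[i]])
    tailAcc <- tailAcc + nulls[[i]]@tail
    n <- length(acc) + length(b) - 1L
    out <- numeric(n)
    for (j in seq_along(acc))
      if (acc[j] > 0)
        out[j:(j + length(b) - 1L)] <- out[j:(j + length(b) - 1L)] + acc[j] * b
    # truncate where the remaining tail is negligible
    cum <- cumsum(out)
    K <- which(cum >= cum[n] - 1e-13)[1]
    acc <- out[seq_len(max(K, 1L))]
  }
  m <- sum(vapply(nulls, nullMean, numeric(1)))
  a <- vapply(nulls, function(x) x@alphaTotal, numeric(1))
  aTot <- if (anyNA(a)) NA_real_ else sum(a)
  NullPMF(acc, tail = max(1 - sum(acc), 0), mean = m, alphaTotal = aTot)
}

#' Upper-tail burden p-value
#'
#' `P(X >= observed)` under the null; by construction `p = 1` when
#' `observed = 0`. Values below `1e-300` are reported as `1e-300` with
#' attribute `"below"` set (a bound, not an estimate).
#'
#' @param null a [NullPMF-class].
#' @param observed observed mutation count (>= 0).
#' @return p-value in `(0, 1]`.
#' @export
burdenPvalue <- function(null, observed) {
  stopifnot(observed >= 0)
  if (observed == 0) return(1)
  pmf <- pmfValues(null)
  K <- length(pmf) - 1L
  p <- if (observed > K) null@tail
       else sum(pmf[(observed + 1L):(K + 1L)]) + null@tail
  p <- min(p, 1)
  if (p < 1e-300) {
    p <- 1e-300
    attr(p, "below") <- TRUE
  }
  p
}

#' Null for indel burdens in one region
#'
#' Indels reuse the region's SNV rate dispersion: the null is negative
#' binomial with `alpha`, `theta` from the SNV map, a uniform position
#' probability `pmass = nQuery/nRegion`, and a separate indel scaling factor
#' `C`. This is an approximation (no indel context model) and results built
#' from it are flagged accordingly.
#'
#' @param nQuery number of queried positions in the region.
#' @param nRegion number of positions in the region.
#' @param mu,sigma2 the region's SNV rate parameters.
#' @param C indel scaling factor (observed/expected indels over neutral
#'   regions).
#' @return A [NullPMF-class].
#' @export
indelNull <- function(nQuery, nRegion, mu, sigma2, C) {
  stopifnot(nQuery >= 0, nRegion >= 1, nQuery <= nRegion)
  singleRegionNull(mu, sigma2, C, nQuery / nRegion)
}

#' Cohort scaling factor from a neutral mutation class
#'
#' Adapts a trained rate map to a new cohort: `C` is the ratio of the number
#' of observed neutral-class mutations in the target cohort to the number
#' expected under the training map. The default neutral class is synonymous
#' SNVs excluding TP53 (where some synonymous mutations are under
#' selection); targeted panels, which lack synonymous calls, use
#' low-impact missense SNVs (CADD phred below 15, annotated upstream as
#' category `"low_impact_missense"`).
#'
#' @param cohort the target [MutationCohort-class].
#' @param expected expected count of the neutral class under the training
#'   map at `C = 1` (with the same element exclusions applied).
#' @param mode `"synonymous_excl_TP53"` or `"low_impact_missense"`.
#' @param excludeElements optional `GRanges`/`GRangesList` of elements whose
#'   records are excluded (e.g. TP53); required exclusions are the caller's
#'   responsibility since annotation is upstream input.
#' @return Scaling factor `C > 0`.
#' @export
scalingFactor <- function(cohort, expected,
                          mode = c("synonymous_excl_TP53",
                                   "low_impact_missense"),
                          excludeElements = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(expected) || length(expected) != 1L || expected <= 0)
    stop("expected must be a single positive number")
  gr <- mutationRecords(cohort)
  cls <- if (mode == "synonymous_excl_TP53") "synonymous"
         else "low_impact_missense"
  sel <- S4Vectors::mcols(gr)$mclass == "SNV" &
    S4Vectors::mcols(gr)$category == cls
  if (!is.null(excludeElements)) {
    ex <- if (is(excludeElements, "GRangesList"))
      unlist(excludeElements) else excludeElements
    sel <- sel & GenomicRanges::countOverlaps(gr, ex) == 0
  }
  observed <- sum(sel)
  if (observed == 0)
    stop("no observed ", cls, " SNVs; the cohort is too small to estimate ",
         "a scaling factor - supply one explicitly")
  observed / expected
}

#' Monte Carlo confidence interval for mutation enrichment
#'
#' Parametric double resampling: expected counts are drawn from the null and
#' observed counts from a dispersion-matched negative binomial re-centred at
#' the observed count; the 2.5/97.5 percentiles of their ratio (denominator
#' floored at 0.5) give the 95% CI. Deterministic given `seed`.
#'
#' @param observed observed count.
#' @param null a [NullPMF-class].
#' @param nSim number of simulations (default 10000, must be > 0).
#' @param seed integer seed.
#' @return Numeric `c(lo, hi)`.
#' @export
enrichmentCI <- function(observed, null, nSim = 10000, seed = 1L) {
  if (nSim < 1) stop("nSim must be positive")
  if (nullMean(null) <= 0) stop("null mean must be positive")
  pmf <- pmfValues(null)
  withr::with_seed(seed, {
    E <- sample.int(length(pmf), nSim, replace = TRUE, prob = pmf) - 1L
    O <- if (observed == 0) rep(0L, nSim)
         else if (is.finite(null@alphaTotal) && null@alphaTotal > 0)
           stats::rnbinom(nSim, size = null@alphaTotal, mu = observed)
         else stats::rpois(nSim, observed)
    r <- O / pmax(E, 0.5)
    stats::quantile(r, c(0.025, 0.975), names = FALSE)
  })
}

#' Decompose excess mutations across functional categories
#'
#' The share of the total excess (observed minus expected) contributed by
#' each category, with negative per-category excesses floored at zero and
#' flagged; shares sum to 1. Confidence intervals use the same Monte Carlo
#' double-resampling scheme as [enrichmentCI()].
#'
#' @param observed named integer vector of observed counts per category.
#' @param nulls named list of [NullPMF-class] nulls per category.
#' @param nSim Monte Carlo simulations for the CIs (0 skips CIs).
#' @param seed integer seed.
#' @return data.frame with `category`, `observed`, `expected`, `excess`,
#'   `share`, `lo`, `hi` and logical `floored`.
#' @export
excessDecomposition <- function(observed, nulls, nSim = 10000, seed = 1L) {
  stopifnot(length(observed) >= 1L, length(observed) == length(nulls))
  cats <- names(observed)
  expected <- vapply(nulls, nullMean, numeric(1))
  rawExcess <- observed - expected
  floored <- rawExcess < 0
  excess <- pmax(rawExcess, 0)
  tot <- sum(excess)
  if (tot <= 0) stop("total excess is not positive")
  share <- excess / tot
  lo <- hi <- rep(NA_real_, length(cats))
  if (nSim > 0) {
    sims <- withr::with_seed(seed, {
      vapply(seq_along(cats), function(i) {
        pmf <- pmfValues(nulls[[i]])
        E <- sample.int(length(pmf), nSim, replace = TRUE, prob = pmf) - 1L
        a <- nulls[[i]]@alphaTotal
        O <- if (observed[i] == 0) rep(0L, nSim)
             else if (is.finite(a) && a > 0)
               stats::rnbinom(nSim, size = a, mu = observed[i])
             else stats::rpois(nSim, observed[i])
        pmax(O - E, 0)
      }, numeric(nSim))
    })
    tots <- rowSums(sims)
    ok <- tots > 0
    for (i in seq_along(cats)) {
      sh <- sims[ok, i] / tots[ok]
      qs <- stats::quantile(sh, c(0.025, 0.975), names = FALSE)
      lo[i] <- qs[1]; hi[i] <- qs[2]
    }
  }
  data.frame(category = cats, observed = as.numeric(observed),
             expected = expected, excess = excess, share = share,
             lo = lo, hi = hi, floored = floored, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Multiple-testing adjustment of burden p-values
#'
#' Benjamini-Hochberg step-up (with monotonicity enforcement) or Bonferroni
#' (`min(1, m*p)`), as implemented by [stats::p.adjust()]. The conventional
#' significance thresholds are FDR q < 0.1 and Bonferroni alpha < 0.05.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted q-values.
#' @export
adjustPvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = method)
}

#' Burden-test candidate elements against a rate map
#'
#' For each element, builds the exact neutral null by convolving the
#' per-region negative binomial distributions of the element's footprint
#' (whole-interval mode: every possible SNV in the element; mutation-set
#' mode: a supplied list of specific substitutions), counts matching cohort
#' mutations, and reports p-value, BH q-value, enrichment
#' (observed/expected) with Monte Carlo 95% CI, and excess
#' (observed - expected). Portions of an element falling in QC-failing bins
#' are excluded and flagged.
#'
#' @param cohort a [MutationCohort-class] (already scaled conceptually by
#'   `C`: the scaling factor rescales the null, not the data).
#' @param map a [RateMap-class].
#' @param table a [ContextTable-class].
#' @param reference `DNAStringSet` reference genome.
#' @param elements named `GRangesList` (whole-interval mode), or `NULL` when
#'   `querySets` is given.
#' @param querySets named list of data.frames with columns `chrom`, `pos`,
#'   `alt` (mutation-set mode).
#' @param C cohort scaling factor.
#' @param mutClass `"SNV"` or `"indel"` (indel mode uses the uniform-position
#'   approximation of [indelNull()] and flags its rows).
#' @param countRecurrent count several mutations of one sample at one
#'   position separately (default FALSE: collapsed to one).
#' @param dropMultiSample drop elements where a single sample contributes
#'   more than one qualifying mutation (default FALSE: flagged only).
#' @param ciSims Monte Carlo simulations for enrichment CIs (0 skips CIs).
#' @param seed integer seed for the Monte Carlo CIs.
#' @return data.frame with one row per element: `name`, `observed`,
#'   `expected`, `p`, `q`, `enrichment`, `ci_lo`, `ci_hi`, `excess`,
#'   `multi_per_sample`, `qc_excluded`, `approx_indel`.
#' @export
testElements <- function(cohort, map, table, reference, elements = NULL,
                         querySets = NULL, C = 1,
                         mutClass = c("SNV", "indel"),
                         countRecurrent = FALSE, dropMultiSample = FALSE,
                         ciSims = 0, seed = 1L) {
  mutClass <- match.arg(mutClass)
  if (is.null(elements) == is.null(querySets))
    stop("supply exactly one of elements or querySets")
  bins <- rateBins(map)
  ok <- S4Vectors::mcols(bins)$qc_pass
  qcBins <- bins[ok]
  muV <- S4Vectors::mcols(qcBins)$mu
  s2V <- S4Vectors::mcols(qcBins)$sigma2
  gr <- mutationRecords(cohort)
  isSNV <- S4Vectors::mcols(gr)$mclass == "SNV"
  recs <- if (mutClass == "SNV") gr[isSNV] else gr[!isSNV]

  wIndex <- NULL
  ctxIdx <- NULL
  if (mutClass == "SNV") wIndex <- .positionWeightIndex(reference, table)

  if (!is.null(elements)) {
    names(elements) <- names(elements) %||% paste0("element_",
                                                   seq_along(elements))
    items <- names(elements)
  } else {
    items <- names(querySets) %||% paste0("query_", seq_along(querySets))
    ctxIdx <- referenceContextIndex(reference)
    prob192 <- table@table$prob
  }

  n <- length(items)
  out <- data.frame(name = items, observed = NA_integer_,
                    expected = NA_real_, p = NA_real_, q = NA_real_,
                    enrichment = NA_real_, ci_lo = NA_real_,
                    ci_hi = NA_real_, excess = NA_real_,
                    multi_per_sample = FALSE, qc_excluded = FALSE,
                    approx_indel = mutClass == "indel",
                    stringsAsFactors = FALSE)

  for (i in seq_len(n)) {
    if (!is.null(elements)) {
      iv <- GenomicRanges::reduce(elements[[i]])
      hits <- GenomicRanges::findOverlaps(iv, qcBins)
      if (!length(hits)) stop("element '", items[i],
                              "' lies entirely in QC-failing bins")
      covered <- GenomicRanges::pintersect(
        iv[S4Vectors::queryHits(hits)], qcBins[S4Vectors::subjectHits(hits)])
      out$qc_excluded[i] <-
        sum(GenomicRanges::width(covered)) < sum(GenomicRanges::width(iv))
      binIdx <- S4Vectors::subjectHits(hits)
      nulls <- vector("list", length(binIdx))
      for (j in seq_along(binIdx)) {
        b <- binIdx[j]
        ch <- as.character(GenomicRanges::seqnames(qcBins))[b]
        if (mutClass == "SNV") {
          tot <- .intervalWeight(wIndex, ch, GenomicRanges::start(qcBins)[b],
                                 GenomicRanges::end(qcBins)[b])
          w <- .intervalWeight(wIndex, ch, GenomicRanges::start(covered)[j],
                               GenomicRanges::end(covered)[j])
          pm <- if (tot > 0) min(w / tot, 1) else 0
          nulls[[j]] <- singleRegionNull(muV[b], s2V[b], C, pm)
        } else {
          nulls[[j]] <- indelNull(GenomicRanges::width(covered)[j],
                                  GenomicRanges::width(qcBins)[b],
                                  muV[b], s2V[b], C)
        }
      }
      null <- convolveNulls(nulls)
      sel <- GenomicRanges::countOverlaps(recs, covered) > 0
    } else {
      qs <- querySets[[i]]
      need <- c("chrom", "pos", "alt")
      if (!all(need %in% colnames(qs)))
        stop("query set must have columns chrom, pos, alt")
      key <- paste(qs$chrom, qs$pos, qs$alt)
      if (anyDuplicated(key)) stop("duplicate entries in query set '",
                                   items[i], "'")
      qgr <- GenomicRanges::GRanges(qs$chrom,
                                    IRanges::IRanges(qs$pos, width = 1L))
      binOf <- GenomicRanges::findOverlaps(qgr, qcBins, select = "first")
      if (all(is.na(binOf))) stop("query set '", items[i],
                                  "' lies entirely in QC-failing bins")
      out$qc_excluded[i] <- anyNA(binOf)
      keep <- !is.na(binOf)
      qs <- qs[keep, , drop = FALSE]; binOf <- binOf[keep]
      pcat <- vapply(seq_len(nrow(qs)), function(r) {
        ctx <- ctxIdx[[qs$chrom[r]]][qs$pos[r]]
        refc <- .baseCodeTable[utf8ToInt(
          .refBaseAt(reference, qs$chrom[r], qs$pos[r])) + 1L]
        altc <- encodeBases(qs$alt[r])
        cid <- categoryId(ctx, refc, altc)
        if (is.na(cid)) 0 else prob192[cid]
      }, numeric(1))
      ub <- unique(binOf)
      nulls <- lapply(ub, function(b) {
        ch <- as.character(GenomicRanges::seqnames(qcBins))[b]
        if (is.null(wIndex))
          wIndex <<- .positionWeightIndex(reference, table)
        tot <- .intervalWeight(wIndex, ch, GenomicRanges::start(qcBins)[b],
                               GenomicRanges::end(qcBins)[b])
        pm <- if (tot > 0) min(sum(pcat[binOf == b]) / tot, 1) else 0
        singleRegionNull(muV[b], s2V[b], C, pm)
      })
      null <- convolveNulls(nulls)
      rkey <- paste(as.character(GenomicRanges::seqnames(recs)),
                    GenomicRanges::start(recs),
                    S4Vectors::mcols(recs)$alt)
      sel <- rkey %in% paste(qs$chrom, qs$pos, qs$alt)
    }

    hitRecs <- recs[sel]
    mc <- S4Vectors::mcols(hitRecs)
    if (!countRecurrent && length(hitRecs)) {
      dupkey <- paste(mc$sample, as.character(
        GenomicRanges::seqnames(hitRecs)), GenomicRanges::start(hitRecs))
      hitRecs <- hitRecs[!duplicated(dupkey)]
      mc <- S4Vectors::mcols(hitRecs)
    }
    obs <- length(hitRecs)
    out$multi_per_sample[i] <- obs > 0 && anyDuplicated(mc$sample) > 0
    out$observed[i] <- obs
    out$expected[i] <- nullMean(null)
    out$p[i] <- as.numeric(burdenPvalue(null, obs))
    out$enrichment[i] <- if (nullMean(null) > 0) obs / nullMean(null) else 0
    out$excess[i] <- obs - nullMean(null)
    if (ciSims > 0 && nullMean(null) > 0) {
      ci <- enrichmentCI(obs, null, nSim = ciSims, seed = seed + i)
      out$ci_lo[i] <- ci[1]; out$ci_hi[i] <- ci[2]
    }
  }
  if (dropMultiSample) out <- out[!out$multi_per_sample, , drop = FALSE]
  out$q <- adjustPvalues(out$p, "BH")
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
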