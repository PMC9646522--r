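test_that("NB parameters follow the closed-form construction", {
  nb <- nbFromRate(mu = 2, sigma2 = 4, C = 1, pmass = 1)
  expect_equal(nb$alpha, 1)
  expect_equal(nb$theta, 2)
  expect_equal(nb$q, 1 / 3)
  expect_equal(nb$mean, 2)
  expect_false(nb$clamped)

  # the mean identity mean = C * mu * pmass
  nb <- nbFromRate(2, 4, 1, 0.5)
  expect_equal(nb$mean, 1)
  expect_equal(nb$alpha * nb$theta * 1 * 0.5, nb$mean, tolerance = 1e-12)

  # under-dispersion is clamped and flagged
  nb <- nbFromRate(3, 2, 1, 1)
  expect_true(nb$clamped)
  expect_equal(nb$theta, 1 + 1e-6)

  expect_error(nbFromRate(0, 1, 1, 1), "mu")
  expect_error(nbFromRate(1, 1, 1, 1.5), "pmass")
  expect_error(nbFromRate(1, 1, 0, 1), "C")
})

test_that("the mean identity holds across random parameter draws", {
  set.seed(99)
  for (i in 1:50) {
    mu <- runif(1, 0.01, 50)
    sigma2 <- mu * runif(1, 1.01, 5)
    C <- runif(1, 0.1, 3)
    pm <- runif(1)
    nb <- nbFromRate(mu, sigma2, C, pm)
    expect_equal(nb$mean, C * mu * pm, tolerance = 1e-9)
    expect_equal(nb$alpha * nb$theta * C * pm, nb$mean, tolerance = 1e-9)
    null <- singleRegionNull(mu, sigma2, C, pm)
    expect_equal(nullMean(null),
                 sum(pmfValues(null) * (seq_along(pmfValues(null)) - 1)),
                 tolerance = 1e-6)
  }
})

test_that("single-region null matches closed forms", {
  # alpha = 1, q = 1/3: geometric with P(0) = 1/3
  null <- singleRegionNull(2, 4, 1, 1)
  expect_equal(pmfValues(null)[1], 1 / 3, tolerance = 1e-12)
  expect_equal(as.numeric(burdenPvalue(null, 1)), 2 / 3, tolerance = 1e-10)

  # thinning limit: large alpha with mean 1 approaches Poisson(1)
  null <- singleRegionNull(1000, 1000 * (1 + 1e-6), 1, 0.001)
  p3 <- as.numeric(burdenPvalue(null, 3))
  expect_equal(p3, 1 - 2.5 * exp(-1), tolerance = 2e-3)

  # no queryable positions: point mass at zero
  null <- singleRegionNull(5, 10, 1, 0)
  expect_equal(pmfValues(null), 1)
  expect_equal(nullMean(null), 0)

  # truncation contract
  null <- singleRegionNull(10, 30, 1, 0.5)
  expect_lt(null@tail, 1e-12)
  expect_equal(sum(pmfValues(null)) + null@tail, 1, tolerance = 1e-9)
})

test_that("convolution is exact, associative, and matches NB additivity", {
  a <- singleRegionNull(4, 8, 1, 0.7)
  point <- convolveNulls(list(a))
  expect_equal(pmfValues(point), pmfValues(a))

  # convolving with a point mass at zero is the identity
  zero <- singleRegionNull(5, 10, 1, 0)
  conv <- convolveNulls(list(a, zero))
  expect_equal(pmfValues(conv)[seq_along(pmfValues(a))], pmfValues(a),
               tolerance = 1e-12)

  # shared-q additivity: NB(a1, q) + NB(a2, q) = NB(a1 + a2, q)
  # same theta*C*pmass for both regions gives a shared q
  n1 <- singleRegionNull(2, 4, 1, 0.5)   # alpha 1, theta 2
  n2 <- singleRegionNull(8, 16, 1, 0.5)  # alpha 4, theta 2
  conv <- convolveNulls(list(n1, n2))
  q <- 1 / (1 + 2 * 0.5)
  k <- seq_along(pmfValues(conv)) - 1
  expect_lt(max(abs(pmfValues(conv) - dnbinom(k, size = 5, prob = q))),
            1e-10)

  # order invariance and mean linearity
  n3 <- singleRegionNull(1, 3, 2, 0.2)
  c123 <- convolveNulls(list(n1, n2, n3))
  c321 <- convolveNulls(list(n3, n2, n1))
  L <- min(length(pmfValues(c123)), length(pmfValues(c321)))
  expect_lt(max(abs(pmfValues(c123)[1:L] - pmfValues(c321)[1:L])), 1e-10)
  expect_equal(nullMean(c123),
               nullMean(n1) + nullMean(n2) + nullMean(n3), tolerance = 1e-9)
})

test_that("burden p-values are upper tails, monotone, and bounded", {
  null <- singleRegionNull(5, 15, 1, 0.8)
  expect_equal(burdenPvalue(null, 0), 1)
  ps <- vapply(0:25, function(o) as.numeric(burdenPvalue(null, o)),
               numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
  expect_true(all(ps > 0 & ps <= 1))

  # beyond the truncated support the tail bound applies
  expect_lte(as.numeric(burdenPvalue(null, 10000)), 1e-12)
})

test_that("indel null uses uniform position probability", {
  full <- indelNull(100, 100, 5, 10, 1)
  expect_equal(nullMean(full), 5, tolerance = 1e-9)
  half <- indelNull(50, 100, 5, 10, 1)
  expect_equal(nullMean(half), 2.5, tolerance = 1e-9)
  expect_error(indelNull(101, 100, 5, 10, 1))
})

test_that("scaling factor is the observed/expected neutral-class ratio", {
  coh <- makeCohort("chr1", pos = seq_len(200), ref = "A", alt = "T",
                    sample = rep(paste0("s", 1:20), 10),
                    category = "synonymous", nSamples = 20L)
  expect_equal(scalingFactor(coh, expected = 100), 2.0)

  # TP53-style exclusion removes matching records from the numerator
  ex <- GRanges("chr1", IRanges(1, 100))
  expect_equal(scalingFactor(coh, expected = 100, excludeElements = ex), 1.0)

  # low-impact missense mode for targeted panels
  cohM <- makeCohort("chr1", pos = 1:50, ref = "A", alt = "T",
                     sample = rep("s1", 50),
                     category = "low_impact_missense", nSamples = 1L)
  expect_equal(scalingFactor(cohM, expected = 100,
                             mode = "low_impact_missense"), 0.5)

  expect_error(scalingFactor(cohM, expected = 100), "no observed")
  expect_error(scalingFactor(coh, expected = 0), "positive")
})

test_that("enrichment CIs straddle 1 under the null and are reproducible", {
  null <- singleRegionNull(200, 600, 1, 0.5)   # mean 100
  ci <- enrichmentCI(100, null, nSim = 5000, seed = 42)
  expect_lt(ci[1], 1)
  expect_gt(ci[2], 1)
  expect_identical(ci, enrichmentCI(100, null, nSim = 5000, seed = 42))
  expect_false(identical(ci, enrichmentCI(100, null, nSim = 5000,
                                          seed = 43)))
  expect_error(enrichmentCI(5, null, nSim = 0), "positive")
})

test_that("excess decomposition normalises shares with floored negatives", {
  n1 <- singleRegionNull(10, 30, 1, 1)   # mean 10
  n2 <- singleRegionNull(10, 30, 1, 1)
  # single category
  d <- excessDecomposition(c(cat1 = 20L), list(cat1 = n1), nSim = 0)
  expect_equal(d$share, 1)
  # equal excess splits evenly
  d <- excessDecomposition(c(a = 20L, b = 20L), list(a = n1, b = n2),
                           nSim = 1000, seed = 1)
  expect_equal(d$share, c(0.5, 0.5))
  expect_true(all(d$lo <= d$share & d$share <= d$hi))
  # negative excess floored, shares still sum to one
  d <- excessDecomposition(c(a = 30L, b = 2L), list(a = n1, b = n2),
                           nSim = 0)
  expect_true(d$floored[2])
  expect_equal(sum(d$share), 1, tolerance = 1e-9)
  # no positive total excess
  expect_error(excessDecomposition(c(a = 1L), list(a = n1), nSim = 0),
               "not positive")
})

test_that("multiple-testing adjustment matches the step-up construction", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjustPvalues(p, "BH"), rep(0.04, 4))
  expect_equal(adjustPvalues(0.03, "BH"), 0.03)
  expect_equal(adjustPvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjustPvalues(rep(0.2, 10), "bonferroni"), rep(1, 10))
  expect_error(adjustPvalues(c(0.5, 0)), "0, 1")
})

test_that("element tests report the full burden summary", {
  sc <- makeScenario(genomeLength = 3e5, meanRate = 60, seed = 21)
  coh <- synthCohort(sc$map, sc$table, sc$ref, nSamples = 40, seed = 22)

  els <- GRangesList(
    e1 = GRanges("chr1", IRanges(15001, 16000)),
    e2 = GRanges("chr1", IRanges(210001, 212000)))
  res <- testElements(coh, sc$map, sc$table, sc$ref, elements = els,
                      ciSims = 500, seed = 5)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$expected > 0))
  expect_equal(res$excess, res$observed - res$expected)
  expect_equal(res$enrichment, res$observed / res$expected)
  expect_equal(res$q, adjustPvalues(res$p, "BH"))

  # an element with no observed mutation: p = 1, enrichment 0
  none <- makeCohort("chr1", pos = 250000, ref = "A", alt = "T")
  res0 <- testElements(none, sc$map, sc$table, sc$ref,
                       elements = els["e1"])
  expect_equal(res0$p, 1)
  expect_equal(res0$observed, 0L)
  expect_equal(res0$enrichment, 0)

  # enrichment is the observed/expected ratio (e.g. 15 vs 2.62 ~ 5.7)
  expect_equal(round(15 / 2.62, 1), 5.7)
})

test_that("query-set mode tests specific substitutions only", {
  sc <- makeScenario(genomeLength = 1e5, meanRate = 50, seed = 31)
  pos <- c(5000, 5001, 60000)
  refb <- vapply(pos, function(p)
    as.character(subseq(sc$ref[["chr1"]], p, p)), character(1))
  alt <- vapply(refb, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                character(1))
  qs <- data.frame(chrom = "chr1", pos = pos, alt = unname(alt))
  # one record matches a query entry; one SNV elsewhere does not
  b2 <- as.character(subseq(sc$ref[["chr1"]], 70000, 70000))
  coh <- makeCohort("chr1", pos = c(pos[1], 70000),
                    ref = c(refb[1], b2),
                    alt = c(alt[1], setdiff(c("A", "C", "G", "T"), b2)[1]),
                    sample = c("s1", "s2"))
  res <- testElements(coh, sc$map, sc$table, sc$ref,
                      querySets = list(q = qs))
  expect_equal(res$observed, 1L)   # only the matching (pos, alt) counts
  expect_gt(res$expected, 0)

  # duplicates rejected
  expect_error(testElements(coh, sc$map, sc$table, sc$ref,
                            querySets = list(q = qs[c(1, 1), ])),
               "duplicate")
})

test_that("adding query entries never decreases the null mean", {
  sc <- makeScenario(genomeLength = 1e5, meanRate = 50, seed = 41)
  rp <- regionSNVProbs(sc$bins[3], sc$table, sc$ref)
  small <- rp[1:100, c("pos", "alt")]
  large <- rp[1:300, c("pos", "alt")]
  mSmall <- queryProbMass(small, rp)
  mLarge <- queryProbMass(large, rp)
  expect_gte(mLarge, mSmall)
  nS <- singleRegionNull(sc$mu[3], sc$s2[3], 1, mSmall)
  nL <- singleRegionNull(sc$mu[3], sc$s2[3], 1, mLarge)
  expect_gte(nullMean(nL), nullMean(nS))
})

test_that("per-sample recurrences collapse unless countRecurrent is set", {
  sc <- makeScenario(genomeLength = 1e5, meanRate = 50, seed = 51)
  pos <- 15005
  refb <- as.character(subseq(sc$ref[["chr1"]], pos, pos))
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  coh <- makeCohort("chr1", pos = c(pos, pos, pos),
                    ref = refb, alt = alt,
                    sample = c("s1", "s1", "s2"), nSamples = 2L)
  els <- GRangesList(e = GRanges("chr1", IRanges(15001, 15100)))
  res <- testElements(coh, sc$map, sc$table, sc$ref, elements = els)
  expect_equal(res$observed, 2L)    # s1 collapsed at the position
  resR <- testElements(coh, sc$map, sc$table, sc$ref, elements = els,
                       countRecurrent = TRUE)
  expect_equal(resR$observed, 3L)

  # drop option removes elements with multi-hit samples
  coh2 <- makeCohort("chr1", pos = c(15005, 15050), ref = "N", alt = "A",
                     sample = c("s1", "s1"), nSamples = 1L,
                     mclass = c("SNV", "SNV"))
  # use real reference bases so the records are valid SNVs
  rb <- vapply(c(15005, 15050), function(p)
    as.character(subseq(sc$ref[["chr1"]], p, p)), character(1))
  alts <- vapply(rb, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                 character(1))
  coh2 <- makeCohort("chr1", pos = c(15005, 15050), ref = rb, alt = alts,
                     sample = c("s1", "s1"), nSamples = 1L)
  res <- testElements(coh2, sc$map, sc$table, sc$ref, elements = els)
  expect_true(res$multi_per_sample)
  resD <- testElements(coh2, sc$map, sc$table, sc$ref, elements = els,
                       dropMultiSample = TRUE)
  expect_equal(nrow(resD), 0L)
})

test_that("indel-mode tests use the uniform-position approximation", {
  sc <- makeScenario(genomeLength = 1e5, meanRate = 50, seed = 61)
  coh <- makeCohort("chr1", pos = c(15005, 15010), ref = c("A", "AT"),
                    alt = c("AT", "A"), sample = c("s1", "s2"))
  els <- GRangesList(e = GRanges("chr1", IRanges(10001, 20000)))
  res <- testElements(coh, sc$map, sc$table, sc$ref, elements = els,
                      mutClass = "indel", C = 0.1)
  expect_true(res$approx_indel)
  expect_equal(res$observed, 2L)
  # whole-bin element: pmass 1, mean C * mu
  expect_equal(res$expected, 0.1 * sc$mu[2], tolerance = 1e-6)
})
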