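test_that("genome tiling drops partial bins and sex chromosomes", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", strrep("ACGT", 25000),      # 100,000 bp
               ">chr2", strrep("ACGT", 6250),       # 25,000 bp
               ">chr3", paste0(strrep("ACGT", 2499), "ACG"),  # 9,999 bp
               ">chrX", strrep("ACGT", 5000)), fa)
  ref <- loadReference(fa)
  bins <- tileGenomeBins(ref, 10000)
  tab <- table(as.character(seqnames(bins)))
  expect_equal(as.integer(tab[["chr1"]]), 10L)
  expect_equal(as.integer(tab[["chr2"]]), 2L)
  expect_false("chr3" %in% names(tab))
  expect_false("chrX" %in% names(tab))
  expect_true(all(width(bins) == 10000L))

  binsX <- tileGenomeBins(ref, 10000, dropSexChroms = FALSE)
  expect_true("chrX" %in% as.character(seqnames(binsX)))
})

test_that("QC flags N-rich bins, missing tracks and excluded regions", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", paste0(strrep("N", 5000), strrep("ACGT", 6250))),
             fa)                                     # 30 kb; bin1 half N
  ref <- loadReference(fa)
  bins <- tileGenomeBins(ref, 10000)
  qc <- qcFilter(bins, ref, missingFrac = c(0, 0.5, 0),
                 exclude = GRanges("chr1", IRanges(25000, 25001)))
  mc <- mcols(qc)
  expect_equal(mc$qc_pass, c(FALSE, FALSE, FALSE))
  expect_equal(mc$qc_reason,
               c("n_fraction", "track_missingness", "exclusion_bed"))

  qc2 <- qcFilter(bins[3], ref, missingFrac = 0)
  expect_true(mcols(qc2)$qc_pass)
})

test_that("fold assignment is balanced, seeded and QC-aware", {
  bins <- makeTruthMap(1000, rep(1, 1000), rep(2, 1000))@bins
  f1 <- assignFolds(bins, k = 5, seed = 11)
  tab <- table(mcols(f1)$fold)
  expect_equal(as.integer(tab), rep(200L, 5))

  # remainder rule: 1002 bins -> sizes {201, 201, 200, 200, 200}
  bins2 <- makeTruthMap(1002, rep(1, 1002), rep(2, 1002))@bins
  f2 <- assignFolds(bins2, k = 5, seed = 11)
  expect_equal(sort(as.integer(table(mcols(f2)$fold)), decreasing = TRUE),
               c(201L, 201L, 200L, 200L, 200L))

  # determinism and QC-failing bins keep NA
  f1b <- assignFolds(bins, k = 5, seed = 11)
  expect_identical(mcols(f1)$fold, mcols(f1b)$fold)
  mcols(bins2)$qc_pass[1:10] <- FALSE
  f3 <- assignFolds(bins2, k = 5, seed = 11)
  expect_true(all(is.na(mcols(f3)$fold[1:10])))

  few <- makeTruthMap(3, rep(1, 3), rep(2, 3))@bins
  expect_error(assignFolds(few, k = 5), "fewer")
})

test_that("variance explained is the squared Pearson correlation", {
  map <- makeTruthMap(50, mu = seq(10, 500, length.out = 50),
                      s2 = seq(20, 1000, length.out = 50))
  obs <- seq(10, 500, length.out = 50)
  expect_equal(varianceExplained(map, obs), 1)
  # affine invariance
  expect_equal(varianceExplained(map, 2 * obs + 7), 1)
  expect_error(varianceExplained(map, rep(5, 50)), "constant")
  small <- makeTruthMap(2, c(1, 2), c(2, 4))
  expect_error(varianceExplained(small, c(1, 2)), "fewer than 3")
})

test_that("the megabase benchmark refuses flanking-trained maps", {
  map <- makeTruthMap(400, mu = seq(5, 20, length.out = 400),
                      s2 = 2 * seq(5, 20, length.out = 400))
  mapFlank <- RateMap(map@bins, useFlanking = TRUE)
  set.seed(3)
  obs <- rpois(400, seq(5, 20, length.out = 400))
  expect_error(varianceExplained(mapFlank, obs, scale = "1Mb"),
               "without flanking")
  expect_no_error(varianceExplained(map, obs, scale = "1Mb"))
})

test_that("aggregation to megabase scale raises variance explained", {
  # truth-map predictions vs overdispersed counts, 20 seeds: summing the
  # 100 constituent bins averages counting noise away
  nBins <- 2000
  wins <- 0L; diffs <- numeric(20)
  for (s in 1:20) {
    set.seed(100 + s)
    latent <- as.numeric(filter(rnorm(nBins, 0, sqrt(1 - 0.25)), 0.5,
                                method = "recursive"))
    mu <- 100 * exp(0.5 * latent) / mean(exp(0.5 * latent))
    map <- makeTruthMap(nBins, mu, 2 * mu)
    obs <- rnbinom(nBins, size = mu / 2, mu = mu)
    r10 <- varianceExplained(map, obs, "10kb")
    r1m <- varianceExplained(map, obs, "1Mb")
    diffs[s] <- r1m - r10
    wins <- wins + (r1m >= r10)
  }
  expect_gt(mean(diffs), 0)
  expect_gte(wins, 16L)
})

test_that("rate maps round-trip through TSV with their sidecar", {
  map <- makeTruthMap(10, mu = 1:10, s2 = 2 * (1:10))
  f <- tempfile(fileext = ".tsv")
  writeRateMap(map, f)
  expect_true(file.exists(paste0(f, ".json")))
  map2 <- readRateMap(f)
  expect_equal(mcols(rateBins(map2))$mu, mcols(rateBins(map))$mu)
  expect_equal(start(rateBins(map2)), start(rateBins(map)))
})

# one small training shared by the remaining blocks
scTrain <- makeScenario(genomeLength = 2e6, nTracks = 3, noise = 0.1,
                        meanRate = 80, seed = 71)
countsTrain <- withr::with_seed(72,
  rpois(length(scTrain$mu), scTrain$mu))
fbTrain <- binFeatures(scTrain$bins, scTrain$tracks, scTrain$ref)
binsTrain <- assignFolds(qcFilter(scTrain$bins, scTrain$ref,
                                  missingFrac = fbTrain$missingFrac),
                         k = 5, seed = 73)
cfgTrain <- rateModelConfig(epochs = 120, lr = 0.02, patience = 25,
                            seed = 74)
modelTrain <- trainFold(fbTrain$features, countsTrain,
                        mcols(binsTrain)$fold, 0, cfgTrain)

test_that("training produces a deterministic model with the right contract", {
  expect_s3_class(modelTrain, "RateModel")
  expect_equal(modelTrain$heldoutFold, 0)
  expect_true(is.finite(modelTrain$valMSE))

  hold <- which(mcols(binsTrain)$fold == 0)
  feats <- fbTrain$features[, , hold, drop = FALSE]
  pr1 <- predictRate(modelTrain, feats)
  pr2 <- predictRate(modelTrain, feats)
  expect_identical(pr1, pr2)                      # pure function
  expect_true(all(pr1$sigma2 > 0))
  expect_true(all(pr1$mu > 0))
  expect_equal(nrow(rateEmbedding(modelTrain, feats)), 16L)

  # identical feature matrices give identical predictions
  two <- fbTrain$features[, , c(hold[1], hold[1]), drop = FALSE]
  prTwo <- predictRate(modelTrain, two)
  expect_equal(prTwo$mu[1], prTwo$mu[2])
  expect_equal(prTwo$sigma2[1], prTwo$sigma2[2])

  # track-manifest mismatch is refused
  bad <- feats
  dimnames(bad)[[1]] <- paste0("x", seq_len(dim(bad)[1]))
  expect_error(predictRate(modelTrain, bad), "mismatch")

  # zero-epoch configurations are rejected before training
  cfg0 <- cfgTrain; cfg0$epochs <- 0L
  expect_error(trainFold(fbTrain$features, countsTrain,
                         mcols(binsTrain)$fold, 0, cfg0), "epoch")
})

test_that("predicted rates are monotone in the driving track", {
  hold <- which(mcols(binsTrain)$fold == 0)
  pr <- predictRate(modelTrain, fbTrain$features[, , hold, drop = FALSE])
  rho <- cor(pr$mu, scTrain$latent[hold], method = "spearman")
  expect_gt(rho, 0.95)
})

test_that("map construction is leakage-free and covers all QC bins", {
  cfgFast <- rateModelConfig(epochs = 8, lr = 0.02, patience = 8, seed = 75)
  map <- buildRateMap(binsTrain, fbTrain$features, countsTrain, cfgFast,
                      cohortLabel = "synthetic")
  bins <- rateBins(map)
  expect_true(all(!is.na(mcols(bins)$mu[mcols(bins)$qc_pass])))
  expect_equal(sum(mcols(bins)$qc_pass), length(bins))
  # fold provenance: each bin predicted by the model holding out its fold
  models <- attr(map, "models")
  expect_equal(sort(as.integer(names(models))), 0:4)
  for (f in 0:4)
    expect_equal(models[[as.character(f)]]$heldoutFold, f)
  # flanking guard propagates through the map
  expect_false(map@useFlanking)
})

test_that("flanking-aware training consumes the flank inputs", {
  flank <- flankFeatures(binsTrain[1:40],
                         makeCohort("chr1", pos = c(5, 6, 7), ref = "A",
                                    alt = "T"))
  expect_equal(dim(flank), c(2L, 40L))
  cfgF <- rateModelConfig(epochs = 5, patience = 5, useFlanking = TRUE,
                          seed = 76)
  expect_error(trainFold(fbTrain$features, countsTrain,
                         mcols(binsTrain)$fold, 0, cfgF), "flank")
})
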