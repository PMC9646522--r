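#' Tile a reference genome into fixed-width bins
#'
#' Tiles each chromosome from its first base into non-overlapping bins of
#' `binSize` bp; a trailing partial bin is dropped. Sex chromosomes are
#' excluded by default because the mutation count observed on X depends on
#' the sex composition of a cohort.
#'
#' @param reference `DNAStringSet` reference genome.
#' @param binSize bin width in bp (default 10000).
#' @param dropSexChroms drop chrX/chrY (and X/Y) chromosomes (default TRUE).
#' @return `GRanges` of bins.
#' @export
tileGenomeBins <- function(reference, binSize = 10000, dropSexChroms = TRUE) {
  stopifnot(binSize > 0)
  lens <- referenceLengths(reference)
  if (dropSexChroms)
    lens <- lens[!names(lens) %in% c("chrX", "chrY", "X", "Y")]
  pieces <- lapply(names(lens), function(ch) {
    n <- lens[[ch]] %/% binSize
    if (n == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(ch, IRanges::IRanges(
      start = (seq_len(n) - 1L) * binSize + 1L, width = binSize))
  })
  out <- suppressWarnings(do.call(c, pieces))
  GenomeInfoDb::seqlengths(out) <-
    lens[GenomeInfoDb::seqlevels(out)]
  out
}

#' Quality-control filter for genome bins
#'
#' A bin fails QC when (a) more than `maxNFrac` of its bases are undefined
#' (N), (b) more than `maxMissingFrac` of its track signal is missing, or
#' (c) it overlaps a user-supplied exclusion set. Reasons are recorded
#' per bin.
#'
#' @param bins `GRanges` of bins.
#' @param reference `DNAStringSet` reference genome.
#' @param missingFrac per-bin track missingness fraction (from
#'   [binFeatures()]); `NULL` skips criterion (b).
#' @param exclude optional `GRanges` exclusion set.
#' @param maxNFrac maximum tolerated N fraction (default 0.1).
#' @param maxMissingFrac maximum tolerated track missingness (default 0.2).
#' @return `bins` with logical metadata column `qc_pass` and character
#'   `qc_reason` (`NA` for passing bins).
#' @export
qcFilter <- function(bins, reference, missingFrac = NULL, exclude = NULL,
                     maxNFrac = 0.1, maxMissingFrac = 0.2) {
  n <- length(bins)
  reason <- rep(NA_character_, n)
  chroms <- as.character(GenomicRanges::seqnames(bins))
  nfrac <- vapply(seq_len(n), function(i) {
    s <- Biostrings::subseq(reference[[chroms[i]]],
                            GenomicRanges::start(bins)[i],
                            GenomicRanges::end(bins)[i])
    Biostrings::letterFrequency(s, "N")[[1]] / GenomicRanges::width(bins)[i]
  }, numeric(1))
  reason[nfrac > maxNFrac] <- "n_fraction"
  if (!is.null(missingFrac)) {
    stopifnot(length(missingFrac) == n)
    hit <- is.na(reason) & missingFrac > maxMissingFrac
    reason[hit] <- "track_missingness"
  }
  if (!is.null(exclude) && length(exclude)) {
    hit <- GenomicRanges::countOverlaps(bins, exclude) > 0
    reason[is.na(reason) & hit] <- "exclusion_bed"
  }
  S4Vectors::mcols(bins)$qc_pass <- is.na(reason)
  S4Vectors::mcols(bins)$qc_reason <- reason
  bins
}

#' Assign cross-validation folds to QC-passing bins
#'
#' Uniformly random partition of the QC-passing bins into `k` folds whose
#' sizes differ by at most one, deterministic given `seed`. QC-failing bins
#' keep fold `NA`.
#'
#' @param bins `GRanges` with a logical `qc_pass` metadata column.
#' @param k number of folds (default 5, i.e. each fold holds 20% of bins).
#' @param seed integer seed.
#' @return `bins` with an integer `fold` column (values `0..k-1`).
#' @export
assignFolds <- function(bins, k = 5, seed = 1L) {
  ok <- which(S4Vectors::mcols(bins)$qc_pass)
  if (length(ok) < k) stop("fewer QC-passing bins (", length(ok),
                           ") than folds (", k, ")")
  fold <- rep(NA_integer_, length(bins))
  perm <- withr::with_seed(seed, sample(ok))
  fold[perm] <- rep(seq_len(k) - 1L, length.out = length(ok))
  S4Vectors::mcols(bins)$fold <- fold
  bins
}

#' Count cohort SNVs per bin
#'
#' @param bins `GRanges` of bins.
#' @param cohort a [MutationCohort-class].
#' @return Integer vector of SNV counts, one per bin.
#' @export
countBinSNVs <- function(bins, cohort) {
  gr <- mutationRecords(cohort)
  gr <- gr[S4Vectors::mcols(gr)$mclass == "SNV"]
  GenomicRanges::countOverlaps(bins, gr)
}

#' Rate-model configuration
#'
#' @param embeddingDim embedding dimension fed to the Gaussian process
#'   (default 16).
#' @param convFilters filters per convolution block (two blocks).
#' @param kernelWidths kernel width per convolution block, in windows.
#' @param epochs maximum training epochs (full-batch Adam).
#' @param lr Adam learning rate.
#' @param patience early-stopping patience on validation MSE, in epochs.
#' @param useFlanking include flanking mutation counts as model inputs.
#' @param anscombe train on Anscombe-transformed counts (default off; the
#'   loss is mean squared error on untransformed counts).
#' @param seed run seed; all randomness of fold splits and initialisation
#'   derives from it.
#' @return A named list of class `rateModelConfig`.
#' @export
rateModelConfig <- function(embeddingDim = 16, convFilters = c(12, 12),
                            kernelWidths = c(5, 5), epochs = 200, lr = 0.01,
                            patience = 25, useFlanking = FALSE,
                            anscombe = FALSE, seed = 1L) {
  stopifnot(embeddingDim >= 1, length(convFilters) == 2,
            length(kernelWidths) == 2)
  structure(list(embeddingDim = as.integer(embeddingDim),
                 convFilters = as.integer(convFilters),
                 kernelWidths = as.integer(kernelWidths),
                 epochs = as.integer(epochs), lr = lr,
                 patience = as.integer(patience),
                 useFlanking = isTRUE(useFlanking),
                 anscombe = isTRUE(anscombe), seed = as.integer(seed)),
            class = "rateModelConfig")
}

.trackHash <- function(features) paste(dimnames(features)[[1]], collapse = "|")

# NB-likelihood estimate of the Gamma rate-dispersion scale theta, given
# counts y with fitted means mu (count variance mu*(1 + theta))
.estimateTheta <- function(y, mu, upper = 100) {
  nll <- function(theta)
    -sum(stats::dnbinom(y, size = mu / theta, mu = mu, log = TRUE))
  # at theta -> 0 the NB degenerates to Poisson; compare against it
  opt <- stats::optimize(nll, c(1e-6, upper))
  pois <- -sum(stats::dpois(y, mu, log = TRUE))
  if (pois <= opt$objective) 0 else opt$minimum
}

.standardizeFeatures <- function(features, stats = NULL) {
  d <- dim(features)
  m <- features; dim(m) <- c(d[1], d[2] * d[3])
  if (is.null(stats)) {
    mu <- rowMeans(m)
    sd <- sqrt(rowMeans((m - mu)^2))
    sd[sd < 1e-12] <- 1
    stats <- list(mean = mu, sd = sd)
  }
  m <- (m - stats$mean) / stats$sd
  dim(m) <- d
  dimnames(m) <- dimnames(features)
  list(features = m, stats = stats)
}

.countsForward <- function(y, anscombe) if (anscombe) 2 * sqrt(y + 0.375) else y

#' Scaled flanking-count inputs for a set of bins
#'
#' Computes the left/right flanking SNV counts of every bin and returns them
#' log1p-transformed and scaled by cohort size (`log1p(count / nSamples)`),
#' the form in which the rate model consumes them.
#'
#' @param bins `GRanges` of bins.
#' @param cohort a [MutationCohort-class].
#' @param flankBp flank width in bp.
#' @return A 2 x N numeric matrix (rows `left`, `right`).
#' @export
flankFeatures <- function(bins, cohort, flankBp = 1e5) {
  n <- length(bins)
  out <- matrix(0, nrow = 2, ncol = n, dimnames = list(c("left", "right"),
                                                       NULL))
  for (i in seq_len(n))
    out[, i] <- flankingMutationCounts(bins[i], cohort, flankBp)
  log1p(out / max(nSamples(cohort), 1L))
}

#' Train the rate model for one held-out fold
#'
#' Excludes the held-out fold entirely, splits the remaining QC-passing bins
#' 80/20 into train/validation (seeded), trains the convolutional network on
#' mean squared error against observed counts with early stopping on
#' validation MSE, then freezes the network and fits a Gaussian process with
#' an RBF kernel and learned observation noise over the embeddings of the
#' training bins.
#'
#' @param features T x W x N feature array from [binFeatures()].
#' @param counts observed SNV count per bin (length N).
#' @param folds integer fold label per bin (`NA` for QC-failing bins).
#' @param heldoutFold the fold to exclude from training and validation.
#' @param config a [rateModelConfig()].
#' @param flank optional 2 x N matrix from [flankFeatures()] (required when
#'   `config$useFlanking` is TRUE).
#' @return An object of class `RateModel`.
#' @export
trainFold <- function(features, counts, folds, heldoutFold, config,
                      flank = NULL) {
  stopifnot(inherits(config, "rateModelConfig"))
  if (config$epochs < 1L) stop("config$epochs must be at least 1")
  if (config$useFlanking && is.null(flank))
    stop("config$useFlanking is TRUE but no flank matrix was supplied")
  if (!config$useFlanking) flank <- NULL
  pool <- which(!is.na(folds) & folds != heldoutFold)
  if (length(pool) < 5L) stop("too few training bins")
  seed <- config$seed + 1000L * (heldoutFold + 1L)
  shuf <- withr::with_seed(seed, sample(pool))
  nva <- max(1L, floor(0.2 * length(pool)))
  va <- shuf[seq_len(nva)]
  tr <- shuf[-seq_len(nva)]
  if (!length(va) || !length(tr)) stop("empty train or validation split")

  std <- .standardizeFeatures(features[, , tr, drop = FALSE])
  Xtr <- std$features
  Xva <- .standardizeFeatures(features[, , va, drop = FALSE],
                              std$stats)$features
  y <- .countsForward(counts, config$anscombe)
  ym <- mean(y[tr]); ysd <- stats::sd(y[tr]); if (!is.finite(ysd) || ysd <= 0) ysd <- 1
  ytr <- (y[tr] - ym) / ysd
  yva <- (y[va] - ym) / ysd
  extraTr <- if (is.null(flank)) NULL else flank[, tr, drop = FALSE]
  extraVa <- if (is.null(flank)) NULL else flank[, va, drop = FALSE]

  fit <- withr::with_seed(seed,
    .nnTrain(Xtr, extraTr, ytr, Xva, extraVa, yva, config))
  k1 <- config$kernelWidths[1]; k2 <- config$kernelWidths[2]
  embTr <- .nnForward(fit$par, Xtr, extraTr, k1, k2)$emb
  gp <- .gpFit(t(embTr), ytr, seed = seed)

  # Gamma-Poisson decomposition of the unexplained variance: counts have
  # variance mu + theta*mu (Poisson plus a Gamma-distributed rate with
  # scale theta). theta is fitted by NB maximum likelihood on the
  # validation bins; the in-sample residuals cannot be used because the
  # GP interpolates its training data.
  embVa <- .nnForward(fit$par, Xva, extraVa, k1, k2)$emb
  muVa <- ym + ysd * .gpPredict(gp, t(embVa))$mu
  if (config$anscombe) muVa <- pmax((muVa / 2)^2 - 0.375, 0)
  thetaHat <- .estimateTheta(counts[va], pmax(muVa, 1e-6))

  structure(list(par = fit$par, gp = gp, featStats = std$stats,
                 yMean = ym, ySd = ysd, thetaHat = thetaHat,
                 config = config,
                 heldoutFold = heldoutFold, valMSE = fit$val * ysd^2,
                 trackHash = .trackHash(features), seed = seed),
            class = "RateModel")
}

#' @export
print.RateModel <- function(x, ...) {
  cat("RateModel (held-out fold ", x$heldoutFold, ")\n", sep = "")
  cat("  embedding dim:", x$config$embeddingDim,
      " validation MSE:", signif(x$valMSE, 4), "\n")
  invisible(x)
}

#' Embeddings of bins under a trained rate model
#'
#' @param model a `RateModel` from [trainFold()].
#' @param features T x W x N feature array.
#' @param flank optional 2 x N flank matrix.
#' @return An `embeddingDim` x N matrix.
#' @export
rateEmbedding <- function(model, features, flank = NULL) {
  if (.trackHash(features) != model$trackHash)
    stop("track manifest mismatch: features were built with different tracks")
  X <- .standardizeFeatures(features, model$featStats)$features
  if (!model$config$useFlanking) flank <- NULL
  .nnForward(model$par, X, flank, model$config$kernelWidths[1],
             model$config$kernelWidths[2])$emb
}

#' Predict regional mutation-rate mean and variance
#'
#' Deterministic forward pass: network embedding followed by the Gaussian
#' process predictive distribution. The reported `sigma2` is the variance of
#' the regional *rate* (the parameter the negative binomial null consumes):
#' the epistemic Gaussian-process variance of the mean plus the fitted
#' Gamma-Poisson overdispersion `thetaHat * mu` (the fitted observation
#' noise decomposed into its Poisson and rate-dispersion parts, with the
#' Poisson part left out because the null adds it back). Means and variances
#' are clamped to at least `1e-6`.
#'
#' @inheritParams rateEmbedding
#' @return List with numeric vectors `mu` and `sigma2` (length N).
#' @export
predictRate <- function(model, features, flank = NULL) {
  emb <- rateEmbedding(model, features, flank)
  pr <- .gpPredict(model$gp, t(emb))
  mu <- model$yMean + model$ySd * pr$mu
  varEpi <- model$ySd^2 * pr$varEpi
  if (model$config$anscombe) {
    # delta-method back-transform of y' = 2*sqrt(y + 3/8)
    mu0 <- pmax(mu, 1e-3)
    varEpi <- varEpi * (mu0 / 2)^2
    mu <- (mu0 / 2)^2 - 0.375
  }
  mu <- pmax(mu, 1e-6)
  sigma2 <- varEpi + model$thetaHat * mu
  list(mu = mu, sigma2 = pmax(sigma2, 1e-6))
}

#' Build a genome-wide rate map under five-fold cross-validation
#'
#' Trains one model per fold and predicts every QC-passing bin with the model
#' whose held-out fold contains it, so no bin is ever predicted by a model
#' that saw it in training or validation. QC-failing bins are optionally
#' predicted by the fold-0 model and flagged `low_confidence`.
#'
#' @param bins `GRanges` with `qc_pass` and `fold` metadata columns.
#' @param features T x W x N feature array over `bins`.
#' @param counts observed SNV count per bin.
#' @param config a [rateModelConfig()].
#' @param flank optional 2 x N flank matrix (required when
#'   `config$useFlanking`).
#' @param predictFailing also predict QC-failing bins (flagged
#'   low-confidence; default TRUE).
#' @param cohortLabel,nTrainSamples provenance.
#' @return A [RateMap-class]; the trained per-fold models are attached as
#'   attribute `"models"`.
#' @export
buildRateMap <- function(bins, features, counts, config, flank = NULL,
                         predictFailing = TRUE, cohortLabel = "unknown",
                         nTrainSamples = NA_integer_) {
  folds <- S4Vectors::mcols(bins)$fold
  if (is.null(folds)) stop("bins carry no fold assignment; run assignFolds()")
  kset <- sort(unique(folds[!is.na(folds)]))
  n <- length(bins)
  mu <- rep(NA_real_, n); sigma2 <- rep(NA_real_, n)
  models <- list()
  for (f in kset) {
    model <- trainFold(features, counts, folds, f, config, flank)
    hold <- which(!is.na(folds) & folds == f)
    pr <- predictRate(model, features[, , hold, drop = FALSE],
                      if (is.null(flank)) NULL else flank[, hold, drop = FALSE])
    mu[hold] <- pr$mu; sigma2[hold] <- pr$sigma2
    models[[as.character(f)]] <- model
  }
  lowconf <- rep(FALSE, n)
  fail <- which(is.na(folds))
  if (predictFailing && length(fail)) {
    m0 <- models[[as.character(kset[1])]]
    pr <- predictRate(m0, features[, , fail, drop = FALSE],
                      if (is.null(flank)) NULL else flank[, fail, drop = FALSE])
    mu[fail] <- pr$mu; sigma2[fail] <- pr$sigma2
    lowconf[fail] <- TRUE
  }
  covered <- which(!is.na(folds))
  if (anyNA(mu[covered])) stop("uncovered QC-passing bin")
  out <- bins
  S4Vectors::mcols(out)$mu <- mu
  S4Vectors::mcols(out)$sigma2 <- sigma2
  S4Vectors::mcols(out)$low_confidence <- lowconf
  map <- RateMap(out, cohortLabel = cohortLabel,
                 nTrainSamples = nTrainSamples,
                 useFlanking = config$useFlanking,
                 config = unclass(config))
  attr(map, "models") <- models
  map
}

#' Variance explained by a rate map
#'
#' Squared Pearson correlation between predicted and observed SNV counts
#' over QC-passing bins, either at native bin resolution (`"10kb"`) or after
#' summing predictions and observations within 1-Mb windows (`"1Mb"`).
#' Aggregated evaluation of a map trained with flanking counts is refused:
#' flanking inputs leak observed counts between neighbouring bins, so the
#' megabase benchmark is only valid for flankless maps.
#'
#' @param map a [RateMap-class].
#' @param observed observed SNV count per bin of the map.
#' @param scale `"10kb"` (native bins) or `"1Mb"` (aggregated).
#' @param aggBp aggregation window for `"1Mb"` (default 1e6).
#' @return R-squared in `[0, 1]`.
#' @export
varianceExplained <- function(map, observed, scale = c("10kb", "1Mb"),
                              aggBp = 1e6) {
  scale <- match.arg(scale)
  bins <- rateBins(map)
  stopifnot(length(observed) == length(bins))
  ok <- S4Vectors::mcols(bins)$qc_pass
  pred <- S4Vectors::mcols(bins)$mu[ok]
  obs <- observed[ok]
  if (scale == "1Mb") {
    if (map@useFlanking)
      stop("aggregated benchmark requires a map trained without flanking ",
           "counts; rebuild with useFlanking = FALSE")
    grp <- paste(as.character(GenomicRanges::seqnames(bins))[ok],
                 (GenomicRanges::start(bins)[ok] - 1L) %/% aggBp)
    pred <- as.numeric(tapply(pred, grp, sum))
    obs <- as.numeric(tapply(obs, grp, sum))
  }
  if (length(obs) < 3L) stop("fewer than 3 regions")
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0)
    stop("variance explained undefined for constant counts")
  stats::cor(pred, obs)^2
}

#' Write / read a rate map as TSV plus JSON sidecar
#'
#' The TSV has columns `chrom`, `start` (1-based), `end` (inclusive), `mu`,
#' `sigma2`, `fold`, `qc_pass`, `low_confidence`; the sidecar
#' (`<path>.json`) records the configuration (including the seed), cohort
#' label and flanking flag.
#'
#' @param map a [RateMap-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeRateMap <- function(map, path) {
  bins <- rateBins(map)
  mc <- S4Vectors::mcols(bins)
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(bins)),
    start = GenomicRanges::start(bins), end = GenomicRanges::end(bins),
    mu = mc$mu, sigma2 = mc$sigma2, fold = mc$fold, qc_pass = mc$qc_pass,
    low_confidence = mc$low_confidence)
  data.table::fwrite(dt, path, sep = "\t")
  side <- list(cohortLabel = map@cohortLabel,
               nTrainSamples = map@nTrainSamples,
               useFlanking = map@useFlanking, config = map@config)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname writeRateMap
#' @export
readRateMap <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "chrom"))
  gr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$start, dt$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    mu = dt$mu, sigma2 = dt$sigma2, fold = dt$fold, qc_pass = dt$qc_pass,
    low_confidence = dt$low_confidence)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(cohortLabel = "unknown", nTrainSamples = NA_integer_,
                    useFlanking = FALSE, config = list())
  nts <- meta$nTrainSamples
  if (is.null(nts) || (is.character(nts) && !grepl("^[0-9]+$", nts)))
    nts <- NA_integer_
  RateMap(gr, cohortLabel = meta$cohortLabel %||% "unknown",
          nTrainSamples = nts,
          useFlanking = isTRUE(meta$useFlanking),
          config = as.list(meta$config))
}
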