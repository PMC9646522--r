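#' Average a signal track over non-overlapping windows of a region
#'
#' Computes, for each `windowBp`-wide window of `region`, the arithmetic mean
#' of the track signal over that window. Missing signal (`NA`) is excluded
#' from the mean; a window with no defined signal at all yields 0 and is
#' flagged in the `"allMissing"` attribute.
#'
#' @param values numeric signal vector for one chromosome, element `j`
#'   covering base pairs `[(j-1)*step + 1, j*step]`.
#' @param step native resolution of the signal in bp.
#' @param region a length-1 `GRanges` (its width must be divisible by
#'   `windowBp`; window boundaries must align with the signal step).
#' @param windowBp window width in bp.
#' @return Numeric vector of `width(region)/windowBp` window means, with a
#'   logical attribute `"allMissing"`.
#' @export
averageTrackInWindows <- function(values, step, region, windowBp) {
  stopifnot(length(region) == 1L)
  rs <- GenomicRanges::start(region)
  rw <- GenomicRanges::width(region)
  if (rw %% windowBp != 0L)
    stop("region width (", rw, ") not divisible by windowBp (", windowBp, ")")
  if ((rs - 1L) %% step != 0L || windowBp %% step != 0L)
    stop("window boundaries do not align with the track step (", step, " bp)")
  W <- rw %/% windowBp
  perWin <- windowBp %/% step
  i0 <- (rs - 1L) %/% step            # 0-based index of first element
  idx <- i0 + seq_len(W * perWin)
  v <- rep(NA_real_, W * perWin)
  ok <- idx <= length(values)
  v[ok] <- values[idx[ok]]
  m <- matrix(v, nrow = perWin, ncol = W)
  defined <- colSums(!is.na(m))
  out <- colSums(m, na.rm = TRUE) / pmax(defined, 1L)
  allMissing <- defined == 0L
  out[allMissing] <- 0
  attr(out, "allMissing") <- allMissing
  out
}

#' Sequence-derived feature rows for a region
#'
#' Two per-window rows computed from the reference genome: the fraction of
#' defined (non-N) bases, and the GC fraction among defined bases (0 when no
#' base in the window is defined).
#'
#' @param reference `DNAStringSet` reference genome.
#' @param region a length-1 `GRanges` within a chromosome.
#' @param windowBp window width in bp (must divide the region width).
#' @return A 2 x W numeric matrix with rows `nt_content` and `gc_content`.
#' @export
sequenceRows <- function(reference, region, windowBp) {
  stopifnot(length(region) == 1L)
  chrom <- as.character(GenomicRanges::seqnames(region))
  if (!chrom %in% names(reference)) stop("chromosome not in reference: ", chrom)
  rs <- GenomicRanges::start(region)
  re <- GenomicRanges::end(region)
  if (rs < 1L || re > length(reference[[chrom]]))
    stop("region outside chromosome bounds")
  rw <- re - rs + 1L
  if (rw %% windowBp != 0L) stop("region width not divisible by windowBp")
  W <- rw %/% windowBp
  seqstr <- Biostrings::subseq(reference[[chrom]], rs, re)
  wins <- Biostrings::DNAStringSet(seqstr,
    start = (seq_len(W) - 1L) * windowBp + 1L, width = windowBp)
  freq <- Biostrings::letterFrequency(wins, letters = c("A", "C", "G", "T"))
  defined <- rowSums(freq)
  gc <- rowSums(freq[, c("C", "G"), drop = FALSE])
  out <- rbind(nt_content = defined / windowBp,
               gc_content = ifelse(defined > 0, gc / defined, 0))
  colnames(out) <- NULL
  out
}

#' Build the feature matrix of one bin
#'
#' Assembles the tracks-by-windows matrix consumed by the rate model: the
#' chromatin tracks (in `TrackSet` order), then replication-timing tracks,
#' then the two sequence-derived rows. Under the conventional whole-genome
#' configuration (723 chromatin + 10 replication tracks, 10-kb bins, 100-bp
#' windows) the matrix is 735 x 100.
#'
#' @param region a length-1 `GRanges` of width `binSize`.
#' @param tracks a [TrackSet-class].
#' @param reference `DNAStringSet` reference genome.
#' @param windowBp window width in bp (default 100).
#' @return A T x W numeric matrix with row names; attribute
#'   `"missingFrac"` gives the fraction of track entries that had no defined
#'   signal before imputation.
#' @export
buildFeatureMatrix <- function(region, tracks, reference, windowBp = 100) {
  stopifnot(is(tracks, "TrackSet"), length(region) == 1L)
  chrom <- as.character(GenomicRanges::seqnames(region))
  ord <- order(match(tracks@kinds,
                     c("chromatin", "replication_timing", "sequence_derived")))
  miss <- 0L; tot <- 0L
  rows <- lapply(ord, function(i) {
    vals <- tracks@values[[i]][[chrom]]
    if (is.null(vals))
      stop("track '", tracks@trackNames[i], "' missing chromosome ", chrom)
    r <- averageTrackInWindows(vals, tracks@steps[i], region, windowBp)
    miss <<- miss + sum(attr(r, "allMissing"))
    tot <<- tot + length(r)
    as.numeric(r)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- tracks@trackNames[ord]
  sq <- sequenceRows(reference, region, windowBp)
  out <- rbind(m, sq)
  attr(out, "missingFrac") <- if (tot) miss / tot else 0
  out
}

#' Build feature matrices for many bins
#'
#' Vectorised wrapper around [buildFeatureMatrix()] returning a
#' T x W x N array plus per-bin track missingness fractions (used by QC).
#'
#' @inheritParams buildFeatureMatrix
#' @param bins `GRanges` of equal-width bins.
#' @return List with `features` (T x W x N array) and `missingFrac`
#'   (length-N numeric).
#' @export
binFeatures <- function(bins, tracks, reference, windowBp = 100) {
  n <- length(bins)
  stopifnot(n >= 1L)
  first <- buildFeatureMatrix(bins[1], tracks, reference, windowBp)
  arr <- array(NA_real_, dim = c(nrow(first), ncol(first), n),
               dimnames = list(rownames(first), NULL, NULL))
  missingFrac <- numeric(n)
  arr[, , 1] <- first
  missingFrac[1] <- attr(first, "missingFrac")
  if (n > 1L) for (i in 2:n) {
    m <- buildFeatureMatrix(bins[i], tracks, reference, windowBp)
    arr[, , i] <- m
    missingFrac[i] <- attr(m, "missingFrac")
  }
  list(features = arr, missingFrac = missingFrac)
}

#' SNV counts in the regions flanking a bin
#'
#' Counts cohort SNVs in the `flankBp` regions immediately left and right of
#' a focal bin (an optional model input that captures local rate information
#' not explained by the tracks). Flanks are clipped at chromosome edges and
#' the focal bin's own mutations are never counted.
#'
#' @param region a length-1 `GRanges`, the focal bin.
#' @param cohort a [MutationCohort-class].
#' @param flankBp flank width in bp (default 1e5).
#' @return Integer vector `c(left, right)`.
#' @export
flankingMutationCounts <- function(region, cohort, flankBp = 1e5) {
  stopifnot(length(region) == 1L)
  gr <- mutationRecords(cohort)
  gr <- gr[S4Vectors::mcols(gr)$mclass == "SNV"]
  chrom <- as.character(GenomicRanges::seqnames(region))
  rs <- GenomicRanges::start(region)
  re <- GenomicRanges::end(region)
  onChrom <- as.character(GenomicRanges::seqnames(gr)) == chrom
  pos <- GenomicRanges::start(gr)[onChrom]
  left <- sum(pos >= max(1L, rs - flankBp) & pos < rs)
  right <- sum(pos > re & pos <= re + flankBp)
  c(left = left, right = right)
}

#' Read a track manifest
#'
#' A manifest is a TSV with columns `name`, `path`, `kind` and `step` fixing
#' the track row order of the model input. Each track file is a bedGraph (or
#' binned tabular chrom/start/end/value file) at the declared fixed step;
#' spans absent from the file become `NA` (missing-signal sentinel).
#'
#' @param path manifest TSV path.
#' @param seqlens named integer vector of chromosome lengths (see
#'   [referenceLengths()]).
#' @return A [TrackSet-class].
#' @export
readTrackManifest <- function(path, seqlens) {
  if (!file.exists(path)) stop("track manifest not found: ", path)
  man <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("name", "path", "kind", "step")
  if (!all(need %in% colnames(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(path)
  values <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    if (!file.exists(p)) stop("track file not found for track '",
                              man$name[i], "': ", man$path[i])
    readBinnedTrack(p, step = man$step[i], seqlens = seqlens)
  })
  names(values) <- man$name
  TrackSet(values, kinds = man$kind, steps = man$step)
}

#' Read one bedGraph track into fixed-step per-chromosome vectors
#'
#' @param path bedGraph path (may be gzipped).
#' @param step fixed step of the track in bp; every span in the file must
#'   align to it.
#' @param seqlens named chromosome lengths.
#' @return Named list chromosome -> numeric vector (`NA` where the file has
#'   no signal).
#' @export
readBinnedTrack <- function(path, step, seqlens) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- lapply(names(seqlens), function(ch) {
    n <- as.integer(ceiling(seqlens[[ch]] / step))
    v <- rep(NA_real_, n)
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    if (length(g)) {
      s <- GenomicRanges::start(g); e <- GenomicRanges::end(g)
      if (any((s - 1L) %% step != 0L | e %% step != 0L & e != seqlens[[ch]]))
        stop("track span not aligned to declared step in ", path)
      for (k in seq_along(g)) {
        j <- ((s[k] - 1L) %/% step + 1L):min(n, (e[k] - 1L) %/% step + 1L)
        v[j] <- S4Vectors::mcols(g)$score[k]
      }
    }
    v
  })
  names(out) <- names(seqlens)
  out
}
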