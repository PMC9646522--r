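#' Count genome-wide trinucleotide context occurrences
#'
#' Counts, over the supplied intervals, how many positions carry each of the
#' 64 trinucleotide contexts `aXb` (reference strand). Positions at
#' chromosome edges (no flanking base) and positions whose trinucleotide
#' contains an undefined base are skipped, so the counts sum to the number
#' of positions with a fully defined trinucleotide.
#'
#' @param reference `DNAStringSet` reference genome.
#' @param intervals `GRanges` of included intervals; `NULL` means all
#'   chromosomes end to end.
#' @return Integer vector of length 64 (named `aXb`), ordered by context id.
#' @export
countContextOccurrences <- function(reference, intervals = NULL) {
  idx <- referenceContextIndex(reference)
  counts <- integer(64)
  if (is.null(intervals)) {
    for (ch in names(idx)) {
      v <- idx[[ch]]
      counts <- counts + tabulate(v + 1L, 64L)
    }
  } else {
    chroms <- as.character(GenomicRanges::seqnames(intervals))
    for (i in seq_along(intervals)) {
      v <- idx[[chroms[i]]]
      if (is.null(v)) stop("chromosome not in reference: ", chroms[i])
      pos <- GenomicRanges::start(intervals)[i]:GenomicRanges::end(intervals)[i]
      counts <- counts + tabulate(v[pos] + 1L, 64L)
    }
  }
  sc <- contextScaffold()
  ctxnames <- paste0(sc$a, sc$X, sc$b)[seq(1, 192, by = 3)]
  stats::setNames(counts, ctxnames)
}

#' Fit the 192-category context mutation probabilities by maximum likelihood
#'
#' The maximum-likelihood estimate of the genome-wide probability that a
#' position with context `aXb` carries an `X>Y` mutation is the cohort count
#' of SNVs of that category divided by the genome-wide number of `aXb`
#' positions. Categories whose context never occurs get probability 0.
#' Only SNVs are used; SNVs at undefined trinucleotides are dropped with a
#' logged count.
#'
#' @param cohort a [MutationCohort-class].
#' @param reference `DNAStringSet` reference genome.
#' @param intervals optional `GRanges` restricting the occurrence denominator
#'   (conventionally the QC-passing autosomal bins). The downstream
#'   within-region normalisation is invariant to this choice of scale.
#' @param pseudocount additive smoothing count (default 0, pure MLE).
#' @return A [ContextTable-class].
#' @export
fitContextProbs <- function(cohort, reference, intervals = NULL,
                            pseudocount = 0) {
  gr <- mutationRecords(cohort)
  gr <- gr[S4Vectors::mcols(gr)$mclass == "SNV"]
  if (!length(gr)) stop("cohort contains no SNVs")
  occ3 <- rep(countContextOccurrences(reference, intervals), each = 3L)

  idx <- referenceContextIndex(reference)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  pos <- GenomicRanges::start(gr)
  ctx <- rep(NA_integer_, length(gr))
  for (ch in unique(chroms)) {
    sel <- chroms == ch
    ctx[sel] <- idx[[ch]][pos[sel]]
  }
  refc <- .baseCodeTable[utf8ToInt(paste(S4Vectors::mcols(gr)$ref,
                                         collapse = "")) + 1L]
  altc <- .baseCodeTable[utf8ToInt(paste(S4Vectors::mcols(gr)$alt,
                                         collapse = "")) + 1L]
  cat192 <- categoryId(ctx, refc, altc)
  drop <- is.na(cat192)
  if (any(drop))
    message("fitContextProbs: dropped ", sum(drop),
            " SNV(s) at undefined trinucleotides")
  counts <- tabulate(cat192[!drop], 192L)

  tb <- contextScaffold()
  tb$count <- counts
  tb$occurrences <- occ3
  tb$prob <- ifelse(occ3 > 0, (counts + pseudocount) / occ3, 0)
  tb$zero_context <- occ3 == 0
  if (any(tb$prob > 1)) stop("estimated probability above 1; check inputs")
  new("ContextTable", table = tb, nMutationsFit = sum(!drop),
      cohortLabel = cancerLabel(cohort))
}

#' Normalised per-position substitution probabilities within a region
#'
#' Every possible single-base substitution in the region (positions with a
#' defined trinucleotide, three alternate alleles each) gets the genome-wide
#' probability of its category, and the entries are normalised so their sum
#' over the whole region is exactly 1. Positions whose trinucleotide
#' contains an undefined base are excluded.
#'
#' @param region a length-1 `GRanges`.
#' @param table a [ContextTable-class].
#' @param reference `DNAStringSet` reference genome.
#' @return data.frame with columns `pos` (1-based), `ref`, `alt`, `prob`.
#' @export
regionSNVProbs <- function(region, table, reference) {
  stopifnot(length(region) == 1L, is(table, "ContextTable"))
  chrom <- as.character(GenomicRanges::seqnames(region))
  if (!chrom %in% names(reference)) stop("chromosome not in reference: ", chrom)
  ctxAll <- contextIds(as.character(reference[[chrom]]))
  pos <- GenomicRanges::start(region):GenomicRanges::end(region)
  ctx <- ctxAll[pos]
  keep <- !is.na(ctx)
  if (!any(keep)) stop("region has no position with a defined trinucleotide")
  pos <- pos[keep]; ctx <- ctx[keep]
  prob <- table@table$prob
  sc <- contextScaffold()
  rows <- rep(ctx * 3L, each = 3L) + rep(1:3, length(ctx))
  out <- data.frame(pos = rep(pos, each = 3L),
                    ref = sc$X[rows], alt = sc$alt[rows],
                    prob = prob[rows], stringsAsFactors = FALSE)
  tot <- sum(out$prob)
  if (tot <= 0) stop("region has zero total context probability")
  out$prob <- out$prob / tot
  out
}

#' Probability mass of a query set within one region
#'
#' Sums the normalised region probabilities over a set of `(pos, alt)` query
#' entries. Entries absent from the region probabilities (positions with an
#' undefined trinucleotide) contribute 0 with a warning; duplicate entries
#' are rejected.
#'
#' @param query data.frame with columns `pos` and `alt`.
#' @param probs data.frame from [regionSNVProbs()].
#' @return Total probability mass in `[0, 1]`.
#' @export
queryProbMass <- function(query, probs) {
  if (!nrow(query)) return(0)
  key <- paste(query$pos, query$alt)
  if (anyDuplicated(key)) stop("duplicate (pos, alt) entries in query")
  pkey <- paste(probs$pos, probs$alt)
  m <- match(key, pkey)
  if (anyNA(m))
    warning(sum(is.na(m)), " query entr(ies) fall at undefined ",
            "trinucleotides and contribute no mass")
  sum(probs$prob[m], na.rm = TRUE)
}

#' Write / read a context table as TSV plus JSON sidecar
#'
#' @param table a [ContextTable-class].
#' @param path output TSV path (192 rows: `a`, `X`, `b`, `alt`, `count`,
#'   `occurrences`, `prob`).
#' @return `path`, invisibly.
#' @export
writeContextTable <- function(table, path) {
  tb <- table@table
  data.table::fwrite(tb[, c("a", "X", "b", "alt", "count", "occurrences",
                            "prob")], path, sep = "\t")
  jsonlite::write_json(list(nMutationsFit = table@nMutationsFit,
                            cohortLabel = table@cohortLabel),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeContextTable
#' @export
readContextTable <- function(path) {
  tb <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  sc <- contextScaffold()
  m <- match(paste(sc$a, sc$X, sc$b, sc$alt),
             paste(tb$a, tb$X, tb$b, tb$alt))
  if (anyNA(m)) stop("context table file does not cover all 192 categories")
  tb <- tb[m, , drop = FALSE]
  tb$zero_context <- tb$occurrences == 0
  rownames(tb) <- NULL
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(nMutationsFit = NA_integer_, cohortLabel = "unknown")
  new("ContextTable", table = tb,
      nMutationsFit = as.integer(meta$nMutationsFit),
      cohortLabel = as.character(meta$cohortLabel))
}

#' Total context probability weight of each bin
#'
#' Sums the (unnormalised) context-category probabilities over every
#' possible SNV of each bin: the expected SNV count of the bin under the
#' table's genome-wide scale. Useful to construct table-consistent rate
#' maps and expected neutral-class counts.
#'
#' @param bins `GRanges` of bins.
#' @param table a [ContextTable-class].
#' @param reference `DNAStringSet` reference genome.
#' @return Numeric vector, one weight per bin.
#' @export
binContextWeights <- function(bins, table, reference) {
  wIndex <- .positionWeightIndex(reference, table)
  chroms <- as.character(GenomicRanges::seqnames(bins))
  vapply(seq_along(bins), function(i)
    .intervalWeight(wIndex, chroms[i], GenomicRanges::start(bins)[i],
                    GenomicRanges::end(bins)[i]), numeric(1))
}

# Per-chromosome cumulative position weights used for fast interval mass:
# weight of a position = sum of its 3 category probabilities (0 at undefined
# trinucleotides). Interval weight = cs[end+1] - cs[start], with cs padded by
# a leading 0.
.positionWeightIndex <- function(reference, table) {
  prob <- table@table$prob
  wPerCtx <- prob[seq(1, 192, 3)] + prob[seq(2, 192, 3)] + prob[seq(3, 192, 3)]
  idx <- referenceContextIndex(reference)
  lapply(idx, function(v) {
    w <- wPerCtx[v + 1L]
    w[is.na(w)] <- 0
    c(0, cumsum(w))
  })
}

.intervalWeight <- function(wIndex, chrom, start, end) {
  cs <- wIndex[[chrom]]
  if (is.null(cs)) stop("chromosome not in weight index: ", chrom)
  cs[end + 1L] - cs[start]
}
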