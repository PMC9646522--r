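#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges GRangesList granges findOverlaps countOverlaps seqnames start end width
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
NULL

#' Cohort of somatic mutations
#'
#' Container for the somatic mutation records of a tumour cohort. Records are
#' held as a `GRanges` (1-based, width 1 at the variant anchor) with metadata
#' columns `sample`, `ref`, `alt`, `mclass` (one of `"SNV"`, `"insertion"`,
#' `"deletion"`) and an optional functional `category` (e.g. `"synonymous"`,
#' `"missense"`, `"pLoF"`, `"other"`).
#'
#' @slot records `GRanges` of mutation records.
#' @slot nSamples integer, number of samples in the cohort (at least the
#'   number of distinct sample identifiers among the records; samples without
#'   any mutation are allowed).
#' @slot cancerLabel free-text label of the cancer type.
#' @exportClass MutationCohort
setClass("MutationCohort",
  representation(records = "GRanges", nSamples = "integer",
                 cancerLabel = "character"))

setValidity("MutationCohort", function(object) {
  mc <- S4Vectors::mcols(object@records)
  need <- c("sample", "ref", "alt", "mclass")
  if (!all(need %in% colnames(mc)))
    return(paste("records must carry metadata columns:",
                 paste(need, collapse = ", ")))
  if (length(object@records)) {
    if (!all(mc$mclass %in% c("SNV", "insertion", "deletion")))
      return("mclass must be SNV, insertion or deletion")
    snv <- mc$mclass == "SNV"
    if (any(snv & (nchar(mc$ref) != 1L | nchar(mc$alt) != 1L |
                   mc$ref == mc$alt)))
      return("SNV records must have single, distinct ref and alt bases")
    ins <- mc$mclass == "insertion"
    if (any(ins & !(nchar(mc$ref) == 1L & nchar(mc$alt) > 1L)))
      return("insertions must have ref of length 1 and longer alt")
    del <- mc$mclass == "deletion"
    if (any(del & !(nchar(mc$alt) == 1L & nchar(mc$ref) > 1L)))
      return("deletions must have alt of length 1 and longer ref")
    ndistinct <- length(unique(mc$sample))
    if (object@nSamples < ndistinct)
      return("nSamples smaller than the number of distinct sample IDs")
  }
  if (length(object@nSamples) != 1L || is.na(object@nSamples) ||
      object@nSamples < 0L)
    return("nSamples must be a single non-negative integer")
  TRUE
})

#' Construct a MutationCohort
#'
#' @param records `GRanges` with metadata columns `sample`, `ref`, `alt`,
#'   `mclass` and optionally `category`.
#' @param nSamples number of samples; defaults to the number of distinct
#'   sample identifiers among the records.
#' @param cancerLabel free-text cancer label.
#' @return A [MutationCohort-class] object.
#' @export
MutationCohort <- function(records, nSamples = NULL, cancerLabel = "unknown") {
  if (is.null(S4Vectors::mcols(records)$category))
    S4Vectors::mcols(records)$category <- rep("other", length(records))
  if (is.null(nSamples))
    nSamples <- length(unique(S4Vectors::mcols(records)$sample))
  new("MutationCohort", records = records, nSamples = as.integer(nSamples),
      cancerLabel = as.character(cancerLabel))
}

#' Set of per-chromosome signal tracks
#'
#' Epigenomic (chromatin), replication-timing or sequence-derived signals at a
#' fixed native resolution per track. Values are stored per chromosome as
#' numeric vectors where element `j` covers base pairs
#' `[(j-1)*step + 1, j*step]`; missing signal is `NA`.
#'
#' @slot trackNames character vector of track names (fixed order).
#' @slot kinds per-track kind: `"chromatin"`, `"replication_timing"` or
#'   `"sequence_derived"`.
#' @slot steps per-track native resolution in bp.
#' @slot values list (one element per track) of named lists chromosome ->
#'   numeric vector.
#' @exportClass TrackSet
setClass("TrackSet",
  representation(trackNames = "character", kinds = "character",
                 steps = "integer", values = "list"))

setValidity("TrackSet", function(object) {
  n <- length(object@trackNames)
  if (length(object@kinds) != n || length(object@steps) != n ||
      length(object@values) != n)
    return("trackNames, kinds, steps and values must have equal length")
  if (!all(object@kinds %in%
           c("chromatin", "replication_timing", "sequence_derived")))
    return("unknown track kind")
  if (any(object@steps < 1L)) return("steps must be positive")
  if (anyDuplicated(object@trackNames)) return("duplicate track names")
  TRUE
})

#' Construct a TrackSet
#'
#' @param values list per track of named lists chromosome -> numeric vector.
#' @param kinds per-track kind (recycled).
#' @param steps per-track bp resolution (recycled).
#' @param trackNames track names; defaults to names of `values`.
#' @return A [TrackSet-class] object.
#' @export
TrackSet <- function(values, kinds = "chromatin", steps = 1L,
                     trackNames = names(values)) {
  n <- length(values)
  if (is.null(trackNames)) trackNames <- paste0("track", seq_len(n))
  new("TrackSet", trackNames = trackNames,
      kinds = rep_len(kinds, n), steps = as.integer(rep_len(steps, n)),
      values = unname(values))
}

#' Genome-wide trinucleotide mutation-context table
#'
#' Maximum-likelihood probabilities for the 192 strand-specific trinucleotide
#' mutation categories (64 contexts `aXb` times 3 alternate alleles, on the
#' reference strand; no pyrimidine collapsing) together with the genome-wide
#' occurrence count of each context.
#'
#' @slot table data.frame with 192 rows and columns `a`, `X`, `b`, `alt`,
#'   `count`, `occurrences`, `prob`, ordered by context index then alternate
#'   allele; rows with zero genomic occurrences have `prob = 0` and are
#'   flagged in `zero_context`.
#' @slot nMutationsFit number of SNVs used in the fit.
#' @slot cohortLabel cohort label.
#' @exportClass ContextTable
setClass("ContextTable",
  representation(table = "data.frame", nMutationsFit = "integer",
                 cohortLabel = "character"))

setValidity("ContextTable", function(object) {
  tb <- object@table
  if (nrow(tb) != 192L) return("context table must have exactly 192 rows")
  need <- c("a", "X", "b", "alt", "count", "occurrences", "prob")
  if (!all(need %in% colnames(tb)))
    return(paste("missing columns:", paste(setdiff(need, colnames(tb)),
                                           collapse = ", ")))
  if (any(tb$prob < 0 | tb$prob > 1)) return("probabilities outside [0,1]")
  persum <- tapply(tb$prob, rep(seq_len(64), each = 3), sum)
  if (any(persum > 1 + 1e-9))
    return("per-context probabilities must sum to at most 1")
  if (any(tb$occurrences == 0 & tb$prob != 0))
    return("zero-occurrence categories must have prob 0")
  TRUE
})

#' Kilobase-scale somatic mutation-rate map
#'
#' Per-bin predicted mean `mu` and predictive variance `sigma2` of the neutral
#' SNV count, with cross-validation fold provenance. Every QC-passing bin is
#' predicted exactly once, by a model whose training and validation sets
#' exclude that bin.
#'
#' @slot bins `GRanges` of bins with metadata columns `mu`, `sigma2`, `fold`,
#'   `qc_pass` and `low_confidence`.
#' @slot cohortLabel training cohort label.
#' @slot nTrainSamples number of samples in the training cohort.
#' @slot useFlanking whether flanking mutation counts were model inputs.
#' @slot config list of model configuration used (including seed).
#' @exportClass RateMap
setClass("RateMap",
  representation(bins = "GRanges", cohortLabel = "character",
                 nTrainSamples = "integer", useFlanking = "logical",
                 config = "list"))

setValidity("RateMap", function(object) {
  mc <- S4Vectors::mcols(object@bins)
  need <- c("mu", "sigma2", "fold", "qc_pass")
  if (!all(need %in% colnames(mc)))
    return(paste("bins must carry:", paste(need, collapse = ", ")))
  ok <- mc$qc_pass
  if (any(ok) && (any(mc$mu[ok] <= 0) || any(mc$sigma2[ok] <= 0)))
    return("mu and sigma2 must be positive on QC-passing bins")
  TRUE
})

#' Construct a RateMap
#'
#' @param bins `GRanges` with metadata columns `mu`, `sigma2`, `fold`,
#'   `qc_pass` (and optionally `low_confidence`).
#' @param cohortLabel,nTrainSamples,useFlanking,config provenance fields.
#' @return A [RateMap-class] object.
#' @export
RateMap <- function(bins, cohortLabel = "unknown", nTrainSamples = NA_integer_,
                    useFlanking = FALSE, config = list()) {
  mc <- S4Vectors::mcols(bins)
  if (is.null(mc$qc_pass)) S4Vectors::mcols(bins)$qc_pass <- rep(TRUE, length(bins))
  if (is.null(mc$fold)) S4Vectors::mcols(bins)$fold <- rep(NA_integer_, length(bins))
  if (is.null(mc$low_confidence))
    S4Vectors::mcols(bins)$low_confidence <- rep(FALSE, length(bins))
  new("RateMap", bins = bins, cohortLabel = as.character(cohortLabel),
      nTrainSamples = as.integer(nTrainSamples),
      useFlanking = isTRUE(useFlanking), config = config)
}

#' Discrete null distribution over mutation counts
#'
#' Probability mass function of the neutral null over counts `0..K`, truncated
#' where the remaining upper-tail mass falls below `1e-12`. Carries the exact
#' null mean and, where available, the total negative binomial shape (used to
#' re-centre dispersion-matched draws in Monte Carlo confidence intervals).
#'
#' @slot pmf numeric vector of probabilities for counts `0, 1, ..., K`.
#' @slot tail upper-tail mass beyond `K`.
#' @slot mean exact mean of the (untruncated) null.
#' @slot alphaTotal total NB shape, `NA` if the null is not a pure NB
#'   convolution.
#' @exportClass NullPMF
setClass("NullPMF",
  representation(pmf = "numeric", tail = "numeric", mean = "numeric",
                 alphaTotal = "numeric"))

setValidity("NullPMF", function(object) {
  if (length(object@pmf) < 1L) return("empty pmf")
  if (any(object@pmf < -1e-12)) return("negative probabilities")
  tot <- sum(object@pmf) + object@tail
  if (tot > 1 + 1e-9 || tot < 1 - 1e-9) return("pmf does not sum to 1")
  TRUE
})

NullPMF <- function(pmf, tail = 0, mean = NULL, alphaTotal = NA_real_) {
  pmf <- pmax(pmf, 0)
  if (is.null(mean)) mean <- sum(pmf * (seq_along(pmf) - 1)) # tail ignored
  new("NullPMF", pmf = pmf, tail = tail, mean = mean, alphaTotal = alphaTotal)
}

# ---- show methods -----------------------------------------------------------

setMethod("show", "MutationCohort", function(object) {
  mc <- S4Vectors::mcols(object@records)
  cat("MutationCohort [", object@cancerLabel, "]\n", sep = "")
  cat("  records:", length(object@records), "(",
      sum(mc$mclass == "SNV"), "SNV /", sum(mc$mclass != "SNV"), "indel )\n")
  cat("  samples:", object@nSamples, "\n")
})

setMethod("show", "TrackSet", function(object) {
  cat("TrackSet with", length(object@trackNames), "tracks\n")
  for (k in unique(object@kinds))
    cat("  ", k, ":", sum(object@kinds == k), "\n")
})

setMethod("show", "ContextTable", function(object) {
  cat("ContextTable (192 trinucleotide mutation categories) [",
      object@cohortLabel, "]\n", sep = "")
  cat("  fit on", object@nMutationsFit, "SNVs;",
      sum(object@table$prob > 0), "categories with non-zero probability\n")
})

setMethod("show", "RateMap", function(object) {
  mc <- S4Vectors::mcols(object@bins)
  cat("RateMap [", object@cohortLabel, "]\n", sep = "")
  cat("  bins:", length(object@bins), "(", sum(mc$qc_pass), "QC-passing )\n")
  if (any(mc$qc_pass))
    cat("  mean mu:", signif(mean(mc$mu[mc$qc_pass]), 4),
        " mean sigma2:", signif(mean(mc$sigma2[mc$qc_pass]), 4), "\n")
  cat("  flanking counts used:", object@useFlanking, "\n")
})

setMethod("show", "NullPMF", function(object) {
  cat("NullPMF over counts 0..", length(object@pmf) - 1L,
      " (tail ", format(object@tail, digits = 3), ")\n", sep = "")
  cat("  mean:", signif(object@mean, 6), "\n")
})

# ---- accessors --------------------------------------------------------------

#' Mutation records of a cohort
#' @param object a `MutationCohort`.
#' @return The records `GRanges`.
#' @export
setGeneric("mutationRecords", function(object) standardGeneric("mutationRecords"))
#' @export
setMethod("mutationRecords", "MutationCohort", function(object) object@records)

#' Number of samples in a cohort
#' @param object a `MutationCohort`.
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @export
setMethod("nSamples", "MutationCohort", function(object) object@nSamples)

#' Cancer label of a cohort or map
#' @param object a `MutationCohort` or `RateMap`.
#' @export
setGeneric("cancerLabel", function(object) standardGeneric("cancerLabel"))
#' @export
setMethod("cancerLabel", "MutationCohort", function(object) object@cancerLabel)
#' @export
setMethod("cancerLabel", "RateMap", function(object) object@cohortLabel)

#' Bins of a rate map
#' @param object a `RateMap`.
#' @export
setGeneric("rateBins", function(object) standardGeneric("rateBins"))
#' @export
setMethod("rateBins", "RateMap", function(object) object@bins)

#' Context-category table of a ContextTable
#' @param object a `ContextTable`.
#' @export
setGeneric("contextProbs", function(object) standardGeneric("contextProbs"))
#' @export
setMethod("contextProbs", "ContextTable", function(object) object@table)

#' Probability mass vector of a NullPMF
#' @param object a `NullPMF`.
#' @export
setGeneric("pmfValues", function(object) standardGeneric("pmfValues"))
#' @export
setMethod("pmfValues", "NullPMF", function(object) object@pmf)

#' Mean of a null distribution
#' @param object a `NullPMF`.
#' @export
setGeneric("nullMean", function(object) standardGeneric("nullMean"))
#' @export
setMethod("nullMean", "NullPMF", function(object) object@mean)

#' Track names of a TrackSet
#' @param object a `TrackSet`.
#' @export
setGeneric("trackNames", function(object) standardGeneric("trackNames"))
#' @export
setMethod("trackNames", "TrackSet", function(object) object@trackNames)

#' Track kinds of a TrackSet
#' @param object a `TrackSet`.
#' @export
setGeneric("trackKinds", function(object) standardGeneric("trackKinds"))
#' @export
setMethod("trackKinds", "TrackSet", function(object) object@kinds)
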