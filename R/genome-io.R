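#' Load a reference genome from FASTA
#'
#' Reads a (optionally gzipped) FASTA file into a `DNAStringSet`. Bases are
#' uppercased and any base other than A, C, G, T is mapped to N. Sequence
#' names are taken as the first whitespace-delimited word of each header.
#'
#' @param path path to a FASTA file.
#' @return A `DNAStringSet`, one element per chromosome.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTacgt"), fa)
#' ref <- loadReference(fa)
#' width(ref)
#' @export
loadReference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in FASTA: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome names in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty FASTA record: ",
         paste(names(seqs)[Biostrings::width(seqs) == 0L], collapse = ", "))
  chr <- toupper(as.character(seqs))
  chr <- gsub("[^ACGTN]", "N", chr)
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(seqs)
  out
}

#' Lengths of reference chromosomes
#'
#' @param reference a `DNAStringSet` from [loadReference()].
#' @return Named integer vector of chromosome lengths.
#' @export
referenceLengths <- function(reference) {
  stats::setNames(Biostrings::width(reference), names(reference))
}

.refBaseAt <- function(reference, chrom, pos) {
  substr(as.character(Biostrings::subseq(reference[[chrom]], pos, pos)), 1, 1)
}

#' Read somatic mutations into a cohort
#'
#' Reads a MAF-like TSV (columns `sample`, `chrom`, `pos`, `ref`, `alt` and
#' optionally `category`; 1-based positions by default) or a single-sample
#' VCF. Each record is classified as SNV, insertion or deletion; SNV
#' reference alleles are cross-checked against the reference genome and
#' records on chromosomes absent from the reference are dropped with a
#' logged count.
#'
#' @param path path to the mutation file (may be gzipped).
#' @param reference `DNAStringSet` reference genome.
#' @param format `"tsv"` or `"vcf"`.
#' @param coords coordinate dialect of a TSV file: `"1-based"` (default,
#'   MAF/VCF convention) or `"0-based"`.
#' @param onMismatch what to do when an SNV ref allele disagrees with the
#'   reference genome: `"drop"` (drop and log, default) or `"abort"`.
#' @param sample sample identifier used for VCF input (VCFs are read as
#'   single-sample files); defaults to the file basename.
#' @param nSamples cohort size; defaults to the number of distinct samples.
#' @param cancerLabel free-text cohort label.
#' @return A [MutationCohort-class].
#' @export
readMutations <- function(path, reference, format = c("tsv", "vcf"),
                          coords = c("1-based", "0-based"),
                          onMismatch = c("drop", "abort"),
                          sample = NULL, nSamples = NULL,
                          cancerLabel = "unknown") {
  format <- match.arg(format)
  coords <- match.arg(coords)
  onMismatch <- match.arg(onMismatch)
  if (!file.exists(path)) stop("mutation file not found: ", path)
  if (format == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = "chrom"))
    need <- c("sample", "chrom", "pos", "ref", "alt")
    if (!all(need %in% colnames(dt)))
      stop("missing columns: ", paste(setdiff(need, colnames(dt)),
                                      collapse = ", "))
    df <- data.frame(sample = as.character(dt$sample),
                     chrom = as.character(dt$chrom),
                     pos = as.integer(dt$pos),
                     ref = toupper(as.character(dt$ref)),
                     alt = toupper(as.character(dt$alt)),
                     stringsAsFactors = FALSE)
    df$category <- if ("category" %in% colnames(dt))
      as.character(dt$category) else "other"
    if (coords == "0-based") df$pos <- df$pos + 1L
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- vcfR::getFIX(v)
    if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1,
                                       dimnames = list(NULL, names(fx)))
    if (is.null(sample)) sample <- sub("\\.vcf(\\.gz)?$", "", basename(path))
    df <- data.frame(sample = sample,
                     chrom = as.character(fx[, "CHROM"]),
                     pos = as.integer(fx[, "POS"]),
                     ref = toupper(as.character(fx[, "REF"])),
                     alt = toupper(as.character(fx[, "ALT"])),
                     category = "other", stringsAsFactors = FALSE)
    # multi-allelic rows: one record per alternate allele
    multi <- grepl(",", df$alt)
    if (any(multi)) {
      alts <- strsplit(df$alt, ",", fixed = TRUE)
      df <- df[rep(seq_len(nrow(df)), lengths(alts)), ]
      df$alt <- unlist(alts)
    }
  }

  # chromosomes absent from the reference
  known <- df$chrom %in% names(reference)
  if (any(!known))
    message("readMutations: dropped ", sum(!known),
            " record(s) on chromosomes absent from the reference")
  df <- df[known, , drop = FALSE]

  len1r <- nchar(df$ref) == 1L
  len1a <- nchar(df$alt) == 1L
  mclass <- rep(NA_character_, nrow(df))
  mclass[len1r & len1a & df$ref != df$alt] <- "SNV"
  mclass[len1r & !len1a] <- "insertion"
  mclass[!len1r & len1a] <- "deletion"
  if (anyNA(mclass)) {
    bad <- which(is.na(mclass))
    message("readMutations: dropped ", length(bad),
            " malformed record(s) (ref/alt length rule)")
    df <- df[-bad, , drop = FALSE]
    mclass <- mclass[!is.na(mclass)]
  }
  df$mclass <- mclass

  # bounds + SNV ref cross-check
  lens <- referenceLengths(reference)
  inb <- df$pos >= 1L & df$pos <= lens[df$chrom]
  if (any(!inb)) {
    message("readMutations: dropped ", sum(!inb), " out-of-bounds record(s)")
    df <- df[inb, , drop = FALSE]
  }
  if (nrow(df)) {
    snv <- df$mclass == "SNV"
    if (any(snv)) {
      obs <- vapply(which(snv), function(i)
        .refBaseAt(reference, df$chrom[i], df$pos[i]), character(1))
      bad <- which(snv)[obs != df$ref[snv]]
      if (length(bad)) {
        if (onMismatch == "abort")
          stop("SNV reference mismatch at ", df$chrom[bad[1]], ":",
               df$pos[bad[1]], " (", length(bad), " record(s) in total)")
        message("readMutations: dropped ", length(bad),
                " SNV record(s) with reference mismatch")
        df <- df[-bad, , drop = FALSE]
      }
    }
  }

  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, width = 1L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    sample = df$sample, ref = df$ref, alt = df$alt, mclass = df$mclass,
    category = df$category)
  MutationCohort(gr, nSamples = nSamples, cancerLabel = cancerLabel)
}

#' Write a cohort to the MAF-like TSV format
#'
#' Writes `sample`, `chrom`, `pos` (1-based), `ref`, `alt`, `category`.
#' Re-reading the file with [readMutations()] yields identical records.
#'
#' @param cohort a [MutationCohort-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMutations <- function(cohort, path) {
  gr <- mutationRecords(cohort)
  mc <- S4Vectors::mcols(gr)
  dt <- data.table::data.table(
    sample = mc$sample,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr),
    ref = mc$ref, alt = mc$alt, category = mc$category)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Convert positions between VCF (1-based) and 0-based coordinates
#'
#' Self-inverse pair of helpers for the coordinate dialects used at the I/O
#' boundary.
#'
#' @param pos integer vector of positions.
#' @return Converted positions.
#' @export
fromVcfPos <- function(pos) as.integer(pos) - 1L

#' @rdname fromVcfPos
#' @export
toVcfPos <- function(pos) as.integer(pos) + 1L

#' Read candidate elements from BED
#'
#' Reads a BED3/BED4 file (0-based half-open, per the BED standard) into a
#' named `GRangesList`, one element per name. Overlapping or adjacent
#' intervals within a named element are merged; unnamed rows get
#' auto-generated names.
#'
#' @param path path to a BED file (may be gzipped).
#' @return A named `GRangesList`.
#' @export
readElements <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (any(GenomicRanges::width(gr) <= 0L))
    stop("empty interval (start >= end) in BED file")
  nm <- if (!is.null(S4Vectors::mcols(gr)$name)) S4Vectors::mcols(gr)$name
        else rep(NA_character_, length(gr))
  auto <- is.na(nm) | nm == ""
  nm[auto] <- paste0("element_", which(auto))
  grl <- GenomicRanges::GRangesList(lapply(split(gr, nm), function(g)
    GenomicRanges::reduce(GenomicRanges::granges(g))))
  grl[unique(nm)]
}

#' Remove hypermutated samples from a cohort
#'
#' Drops all records from samples whose number of coding mutations exceeds
#' `maxCoding` (cohorts of whole genomes conventionally use 100; a laxer
#' threshold such as 3000 suits promoter/UTR scans). A record is coding when
#' its functional category is one of `codingCategories`.
#'
#' @param cohort a [MutationCohort-class].
#' @param maxCoding maximum allowed number of coding mutations per sample.
#' @param codingCategories categories counted as coding.
#' @return Filtered [MutationCohort-class] with `nSamples` decremented by the
#'   number of removed samples.
#' @export
filterHypermutators <- function(cohort, maxCoding = 100,
                                codingCategories = c("synonymous", "missense",
                                                     "nonsense", "pLoF",
                                                     "activating")) {
  gr <- mutationRecords(cohort)
  if (!length(gr)) return(cohort)
  mc <- S4Vectors::mcols(gr)
  coding <- mc$category %in% codingCategories
  counts <- table(mc$sample[coding])
  bad <- names(counts)[counts > maxCoding]
  if (!length(bad)) return(cohort)
  keep <- !(mc$sample %in% bad)
  message("filterHypermutators: removed ", length(bad), " sample(s), ",
          sum(!keep), " record(s)")
  MutationCohort(gr[keep],
                 nSamples = nSamples(cohort) - length(bad),
                 cancerLabel = cancerLabel(cohort))
}

#' Remove likely germline variants using a population blacklist
#'
#' Drops records matching a blacklist entry (chrom, pos, ref, alt) whose
#' population allele count is at least `minAC` (default 5, the conventional
#' gnomAD cut-off). The blacklist is a local TSV with columns
#' `chrom`, `pos`, `ref`, `alt`, `ac` (1-based positions).
#'
#' @param cohort a [MutationCohort-class].
#' @param blacklist path to the blacklist TSV, or a data.frame.
#' @param minAC minimum allele count for exclusion.
#' @return Filtered [MutationCohort-class]; the number of removed records is
#'   logged.
#' @export
filterGermlineBlacklist <- function(cohort, blacklist, minAC = 5) {
  if (is.character(blacklist)) {
    if (!file.exists(blacklist)) stop("blacklist file not found: ", blacklist)
    blacklist <- as.data.frame(data.table::fread(
      blacklist, sep = "\t", header = TRUE,
      colClasses = list(character = "chrom")))
  }
  need <- c("chrom", "pos", "ref", "alt", "ac")
  if (!all(need %in% colnames(blacklist)))
    stop("blacklist must have columns: ", paste(need, collapse = ", "))
  if (anyNA(blacklist$pos) || anyNA(blacklist$ac))
    stop("malformed blacklist line (missing pos or ac)")
  bl <- blacklist[blacklist$ac >= minAC, , drop = FALSE]
  gr <- mutationRecords(cohort)
  if (!nrow(bl) || !length(gr)) {
    message("filterGermlineBlacklist: removed 0 record(s)")
    return(cohort)
  }
  mc <- S4Vectors::mcols(gr)
  key <- paste(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), mc$ref, mc$alt, sep = ":")
  blkey <- paste(bl$chrom, bl$pos, toupper(bl$ref), toupper(bl$alt), sep = ":")
  keep <- !(key %in% blkey)
  message("filterGermlineBlacklist: removed ", sum(!keep), " record(s)")
  MutationCohort(gr[keep], nSamples = nSamples(cohort),
                 cancerLabel = cancerLabel(cohort))
}
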