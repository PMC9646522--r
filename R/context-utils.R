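# Internal encodings for trinucleotide contexts.
#
# Bases are encoded A=0, C=1, G=2, T=3 (reference strand); anything else is
# NA. A context aXb has id 16*a + 4*X + b in 0..63. The three possible
# alternate alleles of a reference base X are the other bases in A<C<G<T
# order; their rank r in 1..3 gives the category id ctx*3 + r in 1..192.

.BASES <- c("A", "C", "G", "T")

.baseCodeTable <- local({
  tab <- rep(NA_integer_, 256)
  tab[utf8ToInt("A") + 1L] <- 0L
  tab[utf8ToInt("C") + 1L] <- 1L
  tab[utf8ToInt("G") + 1L] <- 2L
  tab[utf8ToInt("T") + 1L] <- 3L
  tab
})

# character string -> integer codes (NA for non-ACGT)
encodeBases <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  .baseCodeTable[utf8ToInt(x) + 1L]
}

# per-position context ids (0..63) for one chromosome sequence; NA at the
# two chromosome edges and wherever the trinucleotide contains a non-ACGT base
contextIds <- function(seq) {
  enc <- if (is.integer(seq)) seq else encodeBases(as.character(seq))
  n <- length(enc)
  ctx <- rep(NA_integer_, n)
  if (n >= 3L) {
    a <- enc[1:(n - 2L)]
    x <- enc[2:(n - 1L)]
    b <- enc[3:n]
    ctx[2:(n - 1L)] <- 16L * a + 4L * x + b
  }
  ctx
}

# rank (1..3) of alt among the three alternates of ref, both encoded 0..3
altRank <- function(ref, alt) {
  r <- alt + 1L - as.integer(alt > ref)
  r[alt == ref] <- NA_integer_
  r
}

# category id in 1..192 from context id (0..63) and encoded ref/alt
categoryId <- function(ctx, ref, alt) {
  ctx * 3L + altRank(ref, alt)
}

# the 192-row scaffold (ordered by context id, then alt rank)
contextScaffold <- function() {
  ctx <- 0:63
  a <- ctx %/% 16L
  x <- (ctx %/% 4L) %% 4L
  b <- ctx %% 4L
  rows <- data.frame(
    a = rep(.BASES[a + 1L], each = 3L),
    X = rep(.BASES[x + 1L], each = 3L),
    b = rep(.BASES[b + 1L], each = 3L),
    stringsAsFactors = FALSE)
  altcode <- unlist(lapply(x, function(xx) setdiff(0:3, xx)))
  rows$alt <- .BASES[altcode + 1L]
  rows
}

# per-chromosome encoded sequences, cached on the DNAStringSet via an attr-free
# environment keyed by object identity is fragile; recompute instead (cheap at
# the scales handled here) unless the caller passes a prebuilt index.
referenceContextIndex <- function(reference) {
  chroms <- names(reference)
  idx <- lapply(chroms, function(ch) contextIds(as.character(reference[[ch]])))
  names(idx) <- chroms
  idx
}
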