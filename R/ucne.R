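#' AlignmentPair: a two-row pairwise alignment with reference coordinates
#'
#' Both rows are strings of equal length over an alphabet plus the gap
#' character `-`. Reference coordinates advance only on non-gap reference
#' columns; `offset` is the 0-based coordinate of the first reference base.
#'
#' @slot ref reference row (gapped string).
#' @slot partner aligned partner row (gapped string).
#' @slot chrom chromosome name of the reference.
#' @slot offset 0-based reference coordinate of the first reference base.
#' @export
setClass("AlignmentPair",
         representation(ref = "character", partner = "character",
                        chrom = "character", offset = "integer"))

setValidity("AlignmentPair", function(object) {
  if (length(object@ref) != 1L || length(object@partner) != 1L)
    return("ref and partner must be single strings")
  if (nchar(object@ref) != nchar(object@partner))
    return("ref and partner must have equal column counts")
  if (!grepl("[^-]", object@ref))
    return("reference row must contain at least one base")
  if (object@offset < 0L) return("offset must be >= 0")
  TRUE
})

#' Construct an AlignmentPair
#' @param ref,partner gapped alignment rows (equal length strings).
#' @param chrom reference chromosome name.
#' @param offset 0-based reference coordinate of the first reference base.
#' @return An [AlignmentPair-class].
#' @export
alignmentPair <- function(ref, partner, chrom = "chr1", offset = 0L) {
  new("AlignmentPair", ref = as.character(ref), partner = as.character(partner),
      chrom = as.character(chrom), offset = as.integer(offset))
}

setMethod("show", "AlignmentPair", function(object) {
  cat("AlignmentPair:", nchar(object@ref), "columns on", object@chrom,
      "starting at", object@offset, "\n")
})

## Internal: per-column match/ref-base vectors. Gap columns (either row)
## count as mismatches; only reference bases consume reference coordinate.
.alnColumns <- function(aln) {
  r <- strsplit(toupper(aln@ref), "", fixed = TRUE)[[1]]
  p <- strsplit(toupper(aln@partner), "", fixed = TRUE)[[1]]
  isRef <- r != "-"
  list(match = (r == p) & isRef & (p != "-"),
       isRef = isRef,
       refCoord = ifelse(isRef, aln@offset + cumsum(isRef) - 1L, NA_integer_))
}

## Internal: greedy maximal selection over qualifying windows, longest first
## and leftmost on ties, enumerated length-descending so candidate windows
## never need to be materialized all at once.
.greedyScan <- function(S, isRef, L, minLen, minIdentity) {
  covered <- logical(L)
  selS <- integer(0); selL <- integer(0)
  for (len in seq.int(L, minLen)) {
    i <- seq_len(L - len + 1L)
    idv <- (S[i + len] - S[i]) / len
    ok <- i[idv >= minIdentity & isRef[i] & isRef[i + len - 1L]]
    if (!length(ok)) next
    covC <- c(0L, cumsum(covered))
    free <- ok[covC[ok + len] - covC[ok] == 0L]
    while (length(free)) {
      s <- free[1L]
      covered[s:(s + len - 1L)] <- TRUE
      selS <- c(selS, s); selL <- c(selL, len)
      free <- free[free >= s + len]
    }
  }
  list(starts = selS, lens = selL)
}

#' Scan a pairwise alignment for ultraconserved segments
#'
#' Finds maximal reference intervals whose alignment columns reach the
#' identity threshold: a window qualifies when it spans at least `minLen`
#' columns, starts and ends on reference-base columns, its column identity
#' (gaps counted as mismatches) is at least `minIdentity`, and the reference
#' span it maps to is at least `minLen` bp. Among overlapping qualifying
#' windows the longest is reported, ties broken leftmost, so no reported
#' interval can be extended without dropping below the threshold. The
#' defaults encode the defining criteria of ultraconserved non-coding
#' elements: length strictly greater than 200 bp at >= 95% identity.
#'
#' @param aln an [AlignmentPair-class].
#' @param minLen minimum segment length in bp (default 201, i.e. > 200 bp).
#' @param minIdentity minimum fraction of identical columns (default 0.95).
#' @return A `GRanges` on the reference with `identity` and `name` columns.
#' @export
scanUltraconserved <- function(aln, minLen = 201L, minIdentity = 0.95) {
  cols <- .alnColumns(aln)
  L <- length(cols$match)
  if (L < minLen) return(.emptyUcneGr(aln))
  S <- c(0, cumsum(cols$match))
  sel <- .greedyScan(S, cols$isRef, L, as.integer(minLen), minIdentity)
  if (!length(sel$starts)) return(.emptyUcneGr(aln))
  s <- sel$starts
  e <- sel$starts + sel$lens - 1L
  refS0 <- cols$refCoord[s]
  refE0 <- cols$refCoord[e] + 1L
  ident <- (S[e + 1L] - S[s]) / sel$lens
  keep <- (refE0 - refS0) >= minLen
  if (!any(keep)) return(.emptyUcneGr(aln))
  o <- order(refS0[keep])
  gr <- GRanges(aln@chrom, IRanges((refS0[keep] + 1L)[o], refE0[keep][o]))
  mcols(gr)$identity <- ident[keep][o]
  mcols(gr)$name <- sprintf("ucne_%d", seq_along(gr))
  gr
}

.emptyUcneGr <- function(aln) {
  gr <- GRanges()
  seqlevels(gr) <- aln@chrom
  mcols(gr)$identity <- numeric(0)
  mcols(gr)$name <- character(0)
  gr
}

#' Remove records overlapping coding annotation
#'
#' Records overlapping any coding interval by at least one base are dropped;
#' half-open abutment is kept (an element ending exactly where an exon starts
#' is still non-coding).
#'
#' @param records a `GRanges` (e.g. from [scanUltraconserved()]).
#' @param coding a `GRanges` of coding intervals on the same assembly.
#' @return The non-coding subset of `records`.
#' @export
filterNoncoding <- function(records, coding) {
  if (!length(records) || !length(coding)) return(records)
  records[!overlapsAny(records, coding, minoverlap = 1L, ignore.strand = TRUE)]
}
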