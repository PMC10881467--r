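#' Deterministic interval ordering
#'
#' Sorts a `GRanges` by chromosome (seqlevel order), then start, then end,
#' then the `name` metadata column when present. Every writer and report in
#' the package emits intervals in this order so artifacts diff cleanly.
#'
#' @param x a `GRanges`.
#' @return The sorted `GRanges`.
#' @export
sortIntervals <- function(x) {
  nm <- if (!is.null(mcols(x)$name)) as.character(mcols(x)$name) else rep("", length(x))
  o <- order(match(as.character(seqnames(x)), seqlevels(x)), start(x), end(x), nm)
  x[o]
}

#' Overlapping pairs between two interval sets
#'
#' Reports every pair (a-interval, b-interval) sharing at least one base,
#' exactly once. Half-open abutment at the file level (e.g. BED `[10,20)` vs
#' `[20,30)`) is not an overlap.
#'
#' @param a,b `GRanges` on the same assembly.
#' @return A data.frame with columns `aIdx`, `bIdx` (indices into `a` and `b`)
#'   and `overlap` (shared bases), ordered by `aIdx` then `bIdx`.
#' @export
intersectPairs <- function(a, b) {
  hits <- findOverlaps(a, b, minoverlap = 1L, ignore.strand = TRUE)
  qi <- queryHits(hits)
  si <- subjectHits(hits)
  ov <- pmin(end(a)[qi], end(b)[si]) - pmax(start(a)[qi], start(b)[si]) + 1L
  o <- order(qi, si)
  data.frame(aIdx = qi[o], bIdx = si[o], overlap = ov[o])
}

#' Overlapping pairs after symmetric extension of the query set
#'
#' Each interval of `a` is extended by `flank` bp on both sides (clamped to
#' the chromosome bounds) before intersecting with `b`; `flank = 0` reduces to
#' [intersectPairs()]. Used with `flank = 250` to overlap ChIP-seq peaks in
#' the vicinity of an element.
#'
#' @param a,b `GRanges` on the same assembly.
#' @param flank non-negative extension in bp.
#' @return As [intersectPairs()]; `overlap` is measured on the extended
#'   `a`-intervals.
#' @export
windowOverlapPairs <- function(a, b, flank) {
  if (length(flank) != 1L || is.na(flank) || flank < 0)
    stop("flank must be a single non-negative number")
  aExt <- a
  sl <- seqlengths(seqinfo(a))[as.character(seqnames(a))]
  newStart <- pmax(1L, start(a) - as.integer(flank))
  newEnd <- end(a) + as.integer(flank)
  if (!any(is.na(sl))) newEnd <- pmin(newEnd, sl)
  ranges(aExt) <- IRanges(newStart, newEnd)
  intersectPairs(aExt, b)
}

#' Merge intervals closer than a gap
#'
#' Returns intervals pairwise separated by more than `gap` uncovered bases;
#' with `gap = 0` overlapping or abutting intervals are unioned and per-base
#' coverage is preserved.
#'
#' @param a a `GRanges`.
#' @param gap non-negative separation in bp below or at which intervals fuse.
#' @return A sorted, merged `GRanges`.
#' @export
mergeIntervals <- function(a, gap = 0) {
  if (length(gap) != 1L || is.na(gap) || gap < 0)
    stop("gap must be a single non-negative number")
  reduce(sortIntervals(a), min.gapwidth = as.integer(gap) + 1L,
         ignore.strand = TRUE)
}

#' Signed distance from an interval to a point
#'
#' Distances are computed in half-open coordinate space: for an element
#' occupying `[s, e)` (0-based) and a 0-based position `p`, the distance is 0
#' when `p` falls inside the element, `p - s` (negative) when the point lies
#' left of it and `p - e` when it lies right of it. This is the arithmetic
#' used for TSS-to-element distance distributions.
#'
#' @param iv a `GRanges` (recycled against `point`).
#' @param point 0-based genomic position(s) on the same chromosome(s).
#' @param chrom optional chromosome name(s) of the point(s); an error is
#'   raised when it differs from the interval's chromosome.
#' @return Signed distance(s) in bp.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200)) # [100,200)
#' distanceToPoint(gr, 150) # 0
#' distanceToPoint(gr, 90)  # -10
#' distanceToPoint(gr, 260) # 60
#' @export
distanceToPoint <- function(iv, point, chrom = NULL) {
  if (!is.null(chrom) && any(as.character(seqnames(iv)) != chrom))
    stop("interval and point are on different chromosomes")
  s0 <- start(iv) - 1L
  e0 <- end(iv)
  ifelse(point < s0, point - s0, ifelse(point >= e0, point - e0, 0))
}
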