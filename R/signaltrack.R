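#' SignalTrack: a chromosome-wise step function
#'
#' Holds non-overlapping runs of constant signal as a `GRanges` with a numeric
#' `score` metadata column. Positions not covered by a run carry the value 0
#' (accessibility / ChIP signal semantics); extraction can instead treat them
#' as missing (constraint-score semantics, see [scoreValues()]).
#'
#' @slot runs `GRanges` with a numeric `score` column; runs are disjoint
#'   within each chromosome and stored in sorted order.
#' @export
setClass("SignalTrack", representation(runs = "GRanges"))

setValidity("SignalTrack", function(object) {
  r <- object@runs
  if (is.null(mcols(r)$score) || !is.numeric(mcols(r)$score))
    return("runs must carry a numeric 'score' column")
  if (any(is.na(mcols(r)$score)))
    return("run values must not be NA")
  if (!isDisjoint(r))
    return("runs overlap within a chromosome")
  TRUE
})

#' Construct a SignalTrack from signal runs
#'
#' @param runs `GRanges` with a numeric `score` column; must be disjoint per
#'   chromosome and within assembly bounds.
#' @return A [SignalTrack-class] object.
#' @export
signalTrack <- function(runs) {
  runs <- sortIntervals(runs)
  strand(runs) <- "*"
  new("SignalTrack", runs = runs)
}

#' @describeIn SignalTrack-class the underlying runs as a `GRanges`.
#' @param x a `SignalTrack`.
#' @export
trackRuns <- function(x) x@runs

setMethod("show", "SignalTrack", function(object) {
  r <- object@runs
  cat("SignalTrack with", length(r), "runs on",
      length(seqlevels(r)), "chromosome(s)\n")
  if (length(r)) {
    cat("  value range: [", min(mcols(r)$score), ", ",
        max(mcols(r)$score), "]\n", sep = "")
  }
})

#' Query a SignalTrack at single positions
#'
#' @param track a [SignalTrack-class].
#' @param chrom chromosome name(s).
#' @param pos 0-based position(s).
#' @return Numeric values; uncovered positions return 0.
#' @export
trackValueAt <- function(track, chrom, pos) {
  q <- GRanges(chrom, IRanges(pos + 1L, pos + 1L))
  hits <- findOverlaps(q, track@runs)
  out <- numeric(length(q))
  out[queryHits(hits)] <- mcols(track@runs)$score[subjectHits(hits)]
  out
}

#' Extract per-base signal values over regions
#'
#' A region of width w contributes w observations. With
#' `uncovered = "zero"` bases outside every run count as 0; with
#' `uncovered = "missing"` they are dropped and counted, which is the
#' behaviour needed for constraint tracks that do not cover the whole genome.
#'
#' @param track a [SignalTrack-class].
#' @param regions `GRanges` to extract over.
#' @param uncovered `"zero"` or `"missing"`.
#' @return A list with `values` (numeric vector over all regions) and
#'   `nMissing` (bases dropped; 0 under `"zero"`).
#' @export
scoreValues <- function(track, regions, uncovered = c("zero", "missing")) {
  uncovered <- match.arg(uncovered)
  hits <- findOverlaps(regions, track@runs)
  qi <- queryHits(hits)
  si <- subjectHits(hits)
  w <- pmin(end(regions)[qi], end(track@runs)[si]) -
    pmax(start(regions)[qi], start(track@runs)[si]) + 1L
  vals <- rep(mcols(track@runs)$score[si], w)
  covered <- sum(w)
  total <- sum(width(regions))
  nMissing <- total - covered
  if (uncovered == "zero" && nMissing > 0) {
    vals <- c(vals, numeric(nMissing))
    nMissing <- 0L
  }
  list(values = vals, nMissing = nMissing)
}

## Internal: flatten possibly-overlapping scored intervals into a disjoint
## step function taking the maximum value on overlaps.
flattenToTrack <- function(gr, values, assembly = NULL) {
  if (!is.null(assembly)) {
    gr <- GRanges(as.character(seqnames(gr)), ranges(gr), seqinfo = assembly)
  }
  if (!length(gr)) {
    mcols(gr)$score <- numeric(0)
    return(signalTrack(gr))
  }
  if (isDisjoint(gr)) {
    mcols(gr)$score <- as.numeric(values)
    return(signalTrack(gr))
  }
  frag <- disjoin(gr, ignore.strand = TRUE)
  hits <- findOverlaps(frag, gr)
  mx <- tapply(values[subjectHits(hits)], queryHits(hits), max)
  mcols(frag)$score <- as.numeric(mx[as.character(seq_along(frag))])
  signalTrack(frag)
}
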