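#' Threshold-based narrow-peak detection on a signal track
#'
#' Peaks are maximal runs of positions whose signal is at or above `cutoff`,
#' after closing sub-threshold gaps of at most `maxGap` bases and discarding
#' runs shorter than `minLength`. This reproduces plain cutoff calling on
#' pre-normalized tracks (cutoff 0.4 for single-cell accessibility signal,
#' 20 for histone-mark signal); no significance model is involved.
#'
#' @param track a [SignalTrack-class].
#' @param cutoff positive signal threshold.
#' @param minLength minimum peak length in bp (default 200, the narrow-peak
#'   caller default).
#' @param maxGap maximum sub-threshold gap closed, in bp (default 30).
#' @return A `GRanges` of peaks with metadata columns `name`, `maxValue` (run
#'   maximum) and `summit` (1-based position of the leftmost base attaining
#'   the maximum).
#' @export
callPeaks <- function(track, cutoff, minLength = 200, maxGap = 30) {
  if (!(length(cutoff) == 1L && cutoff > 0)) stop("cutoff must be > 0")
  if (minLength < 1) stop("minLength must be >= 1")
  if (maxGap < 0) stop("maxGap must be >= 0")
  runs <- track@runs
  hot <- runs[mcols(runs)$score >= cutoff]
  peaks <- reduce(hot, min.gapwidth = as.integer(maxGap) + 1L,
                  ignore.strand = TRUE)
  peaks <- peaks[width(peaks) >= minLength]
  if (!length(peaks)) {
    mcols(peaks)$name <- character(0)
    mcols(peaks)$maxValue <- numeric(0)
    mcols(peaks)$summit <- integer(0)
    return(peaks)
  }
  hits <- findOverlaps(peaks, hot)
  qi <- queryHits(hits)
  v <- mcols(hot)$score[subjectHits(hits)]
  s <- start(hot)[subjectHits(hits)]
  mx <- vapply(split(v, qi), max, numeric(1))
  summit <- vapply(seq_along(peaks), function(i) {
    sel <- qi == i
    vi <- v[sel]; si <- s[sel]
    min(si[vi == max(vi)])  # leftmost base attaining the run maximum
  }, numeric(1))
  mcols(peaks)$name <- sprintf("peak_%d", seq_along(peaks))
  mcols(peaks)$maxValue <- as.numeric(mx[as.character(seq_along(peaks))])
  mcols(peaks)$summit <- as.integer(summit)
  peaks
}

#' Drop peaks carrying a low-signal category label
#'
#' Removes peaks whose label matches the configured low-signal category
#' (e.g. `Low-DNase` elements of the DNase hypersensitivity annotation);
#' all other peaks pass unchanged.
#'
#' @param peaks a `GRanges`.
#' @param labels character vector of per-peak categories (parallel to
#'   `peaks`).
#' @param low character vector of labels to remove (may be empty, giving the
#'   identity).
#' @param allowed optional full label vocabulary; labels outside it raise an
#'   error naming them.
#' @return The filtered `GRanges`.
#' @export
filterLowSignalRegions <- function(peaks, labels, low = "Low-DNase",
                                   allowed = NULL) {
  if (length(labels) != length(peaks))
    stop("labels must be parallel to peaks")
  if (!is.null(allowed)) {
    unknown <- setdiff(unique(labels), allowed)
    if (length(unknown))
      stop("unknown peak label(s): ", paste(unknown, collapse = ", "))
  }
  peaks[!(labels %in% low)]
}

#' Write peaks in narrowPeak-style BED6+4
#'
#' Columns: chrom, start, end, name, score (run maximum scaled to an integer,
#' capped at 1000), strand, signalValue (run maximum), pValue and qValue (-1,
#' not computed by cutoff calling), and the summit offset from the peak start.
#'
#' @param peaks output of [callPeaks()].
#' @param path output path.
#' @export
writeNarrowPeak <- function(peaks, path) {
  peaks <- sortIntervals(peaks)
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L,
                   end = end(peaks),
                   name = mcols(peaks)$name,
                   score = pmin(1000L, as.integer(round(mcols(peaks)$maxValue * 10))),
                   strand = ".",
                   signalValue = mcols(peaks)$maxValue,
                   pValue = -1, qValue = -1,
                   peak = mcols(peaks)$summit - start(peaks))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
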