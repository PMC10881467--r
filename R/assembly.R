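#' Build a genome assembly descriptor
#'
#' An assembly is the coordinate system every interval in the pipeline is
#' validated against. It is represented as a [GenomeInfoDb::Seqinfo] object
#' with known chromosome lengths.
#'
#' @param chromNames character vector of unique chromosome identifiers.
#' @param chromLengths integer vector of chromosome lengths in bp (> 0).
#' @return A `Seqinfo` object.
#' @examples
#' genomeAssembly(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genomeAssembly <- function(chromNames, chromLengths) {
  chromNames <- as.character(chromNames)
  chromLengths <- as.integer(chromLengths)
  if (length(chromNames) != length(chromLengths))
    stop("chromNames and chromLengths must have equal length")
  if (anyDuplicated(chromNames))
    stop("duplicate chromosome names: ",
         paste(unique(chromNames[duplicated(chromNames)]), collapse = ", "))
  if (any(is.na(chromLengths)) || any(chromLengths <= 0L))
    stop("chromosome lengths must be positive integers")
  Seqinfo(seqnames = chromNames, seqlengths = chromLengths)
}

#' Read a two-column chrom.sizes file
#'
#' @param path path to a TSV with columns chromosome name and length.
#' @return A `Seqinfo` object.
#' @export
readChromSizes <- function(path) {
  df <- read.delim(path, header = FALSE, col.names = c("chrom", "length"),
                   colClasses = c("character", "integer"))
  genomeAssembly(df$chrom, df$length)
}

## Internal: stop if any interval exceeds its chromosome bounds.
checkWithinAssembly <- function(gr, what = "interval") {
  sl <- seqlengths(seqinfo(gr))
  if (any(is.na(sl)))
    stop("assembly has chromosomes with unknown length")
  bad <- which(start(gr) < 1L | end(gr) > sl[as.character(seqnames(gr))])
  if (length(bad))
    stop(what, " out of chromosome bounds: ",
         paste0(seqnames(gr)[bad[1]], ":", start(gr)[bad[1]] - 1L, "-",
                end(gr)[bad[1]]))
  invisible(gr)
}
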