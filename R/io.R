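## Readers and writers for every external format the pipeline touches.
## All files use 0-based half-open coordinates (BED convention) except VCF
## positions (1-based, converted on read); in memory everything is a GRanges
## (1-based closed, the Bioconductor convention). Writers convert back, sort
## deterministically, and emit canonical form so write . read is the identity.

.readTextLines <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines))
  list(lines = lines[keep], lineno = keep)
}

.splitFields <- function(parsed, minFields, what) {
  fields <- strsplit(parsed$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < minFields)
  if (length(bad))
    stop(what, ": malformed line ", parsed$lineno[bad[1]],
         " (expected >= ", minFields, " fields, got ", nf[bad[1]], ")")
  fields
}

.numField <- function(x, parsed, what, field) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    stop(what, ": malformed line ", parsed$lineno[bad[1]],
         " (non-numeric ", field, " '", x[bad[1]], "')")
  v
}

.checkCoords <- function(chrom, start0, end0, assembly, parsed, what) {
  known <- seqnames(assembly)
  unk <- which(!(chrom %in% known))
  if (length(unk))
    stop(what, ": unknown chromosome '", chrom[unk[1]], "' at line ",
         parsed$lineno[unk[1]])
  bad <- which(start0 < 0 | start0 >= end0)
  if (length(bad))
    stop(what, ": invalid coordinates at line ", parsed$lineno[bad[1]],
         " (start ", start0[bad[1]], ", end ", end0[bad[1]],
         "; need 0 <= start < end)")
  sl <- seqlengths(assembly)[chrom]
  oob <- which(end0 > sl)
  if (length(oob))
    stop(what, ": interval exceeds length of ", chrom[oob[1]], " at line ",
         parsed$lineno[oob[1]])
  invisible(NULL)
}

#' Read a BED3/BED6 file
#'
#' Coordinates are validated against the assembly (`0 <= start < end <=`
#' chromosome length); name, score and strand are preserved when present.
#' Input need not be sorted; the returned set is in deterministic order.
#'
#' @param path path to a BED file.
#' @param assembly a `Seqinfo` from [genomeAssembly()].
#' @return A sorted `GRanges` with optional `name` and `score` columns.
#' @export
readBed <- function(path, assembly) {
  parsed <- .readTextLines(path)
  if (!length(parsed$lines))
    return(GRanges(seqinfo = assembly))
  fields <- .splitFields(parsed, 3L, "BED")
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- .numField(vapply(fields, `[`, "", 2L), parsed, "BED", "start")
  end0 <- .numField(vapply(fields, `[`, "", 3L), parsed, "BED", "end")
  .checkCoords(chrom, start0, end0, assembly, parsed, "BED")
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), seqinfo = assembly)
  nf <- lengths(fields)
  if (all(nf >= 4L)) mcols(gr)$name <- vapply(fields, `[`, "", 4L)
  if (all(nf >= 5L))
    mcols(gr)$score <- .numField(vapply(fields, `[`, "", 5L), parsed, "BED", "score")
  if (all(nf >= 6L)) {
    str <- vapply(fields, `[`, "", 6L)
    if (!all(str %in% c("+", "-", ".")))
      stop("BED: invalid strand at line ",
           parsed$lineno[which(!(str %in% c("+", "-", ".")))[1]])
    str[str == "."] <- "*"
    strand(gr) <- str
  }
  sortIntervals(gr)
}

#' Write intervals as BED
#'
#' Output is chromosome-then-start sorted; BED6 when name/score/strand
#' metadata are present, BED3 otherwise.
#'
#' @param x a `GRanges`.
#' @param path output path.
#' @export
writeBed <- function(x, path) {
  x <- sortIntervals(x)
  df <- data.frame(chrom = as.character(seqnames(x)),
                   start = format(start(x) - 1L, scientific = FALSE, trim = TRUE),
                   end = format(end(x), scientific = FALSE, trim = TRUE))
  hasName <- !is.null(mcols(x)$name)
  hasScore <- !is.null(mcols(x)$score)
  hasStrand <- any(as.character(strand(x)) != "*")
  if (hasName || hasScore || hasStrand) {
    df$name <- if (hasName) as.character(mcols(x)$name) else "."
    df$score <- if (hasScore) mcols(x)$score else 0
    str <- as.character(strand(x))
    df$strand <- ifelse(str == "*", ".", str)
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a SignalTrack
#'
#' Steps must be non-overlapping within each chromosome; uncovered positions
#' have value 0. An empty file yields an all-zero track.
#'
#' @param path path to a 4-column bedGraph file.
#' @param assembly a `Seqinfo`.
#' @return A [SignalTrack-class].
#' @export
readBedGraph <- function(path, assembly) {
  parsed <- .readTextLines(path)
  if (!length(parsed$lines)) {
    gr <- GRanges(seqinfo = assembly)
    mcols(gr)$score <- numeric(0)
    return(signalTrack(gr))
  }
  fields <- .splitFields(parsed, 4L, "bedGraph")
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- .numField(vapply(fields, `[`, "", 2L), parsed, "bedGraph", "start")
  end0 <- .numField(vapply(fields, `[`, "", 3L), parsed, "bedGraph", "end")
  value <- .numField(vapply(fields, `[`, "", 4L), parsed, "bedGraph", "value")
  .checkCoords(chrom, start0, end0, assembly, parsed, "bedGraph")
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), seqinfo = assembly)
  mcols(gr)$score <- value
  if (!isDisjoint(gr)) stop("bedGraph: overlapping steps in ", path)
  signalTrack(gr)
}

#' Write a SignalTrack as canonical bedGraph
#'
#' Canonical form: sorted, zero-valued runs omitted (uncovered equals 0), and
#' abutting runs of equal value merged, so that reading the output back gives
#' an equivalent step function.
#'
#' @param track a [SignalTrack-class].
#' @param path output path.
#' @export
writeBedGraph <- function(track, path) {
  r <- track@runs
  r <- r[mcols(r)$score != 0]
  if (length(r)) {
    ch <- as.character(seqnames(r))
    v <- mcols(r)$score
    newGroup <- c(TRUE, !(ch[-1] == ch[-length(r)] &
                            start(r)[-1] == end(r)[-length(r)] + 1L &
                            v[-1] == v[-length(r)]))
    grp <- cumsum(newGroup)
    s <- tapply(start(r), grp, min)
    e <- tapply(end(r), grp, max)
    df <- data.frame(chrom = ch[newGroup],
                     start = format(as.integer(s) - 1L, scientific = FALSE, trim = TRUE),
                     end = format(as.integer(e), scientific = FALSE, trim = TRUE),
                     value = v[newGroup])
  } else {
    df <- data.frame(chrom = character(0), start = character(0),
                     end = character(0), value = numeric(0))
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read variants from VCF or TSV
#'
#' Returns a `GRanges` with one range per variant: width 1 for SNVs, the
#' REF-allele span for indels, and `[pos, END]` for structural variants.
#' Metadata columns: `id`, `ref`, `alt`, `svtype` (`NA` for small variants),
#' `af` (reference-population allele frequency; `NA` = frequency-unknown),
#' `observed` (`FALSE` = absent from the reference database, which is distinct
#' from frequency-unknown), `n_hom` (homozygote count in the reference
#' population), and when provided `n_carriers` and `in_unsolved` (cohort
#' columns).
#'
#' The TSV schema (normative) has columns `chrom, pos, ref, alt, svtype, end,
#' af, observed, n_hom` plus optional cohort columns; `pos`/`end` are 1-based
#' as in VCF. In VCF input, `AF=0` encodes absence from the reference
#' database and a record with no `AF` key is flagged frequency-unknown, never
#' silently 0.
#'
#' @param path path to a `.vcf` or TSV file.
#' @return A `GRanges` of variant records.
#' @export
readVariants <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) .readVariantsVcf(path) else .readVariantsTsv(path)
}

.readVariantsTsv <- function(path) {
  df <- read.delim(path, header = TRUE, colClasses = NA,
                   na.strings = c("NA", "."))
  need <- c("chrom", "pos", "ref", "alt", "af", "observed", "n_hom")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant TSV lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(df$svtype)) df$svtype <- NA_character_
  if (is.null(df$end)) df$end <- NA_integer_
  isSv <- !is.na(df$svtype)
  endPos <- ifelse(isSv, df$end, df$pos + nchar(as.character(df$ref)) - 1L)
  if (any(isSv & is.na(df$end))) stop("SV records need an 'end' column")
  gr <- GRanges(as.character(df$chrom), IRanges(df$pos, endPos))
  mcols(gr)$id <- if (!is.null(df$id)) as.character(df$id) else
    paste0(df$chrom, ":", df$pos, "_", df$ref, ">", df$alt)
  mcols(gr)$ref <- as.character(df$ref)
  mcols(gr)$alt <- as.character(df$alt)
  mcols(gr)$svtype <- as.character(df$svtype)
  mcols(gr)$af <- as.numeric(df$af)
  mcols(gr)$observed <- as.logical(df$observed)
  mcols(gr)$n_hom <- as.integer(df$n_hom)
  if (!is.null(df$n_carriers)) mcols(gr)$n_carriers <- as.integer(df$n_carriers)
  if (!is.null(df$in_unsolved)) mcols(gr)$in_unsolved <- as.logical(df$in_unsolved)
  badAf <- which(!is.na(mcols(gr)$af) & (mcols(gr)$af < 0 | mcols(gr)$af > 1))
  if (length(badAf)) stop("allele frequency outside [0,1] for ", mcols(gr)$id[badAf[1]])
  if (any(mcols(gr)$n_hom < 0, na.rm = TRUE)) stop("negative homozygote count")
  gr
}

.readVariantsVcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  inf <- VariantAnnotation::info(vcf)
  gr <- GRanges(seqnames(rr), ranges(rr))
  n <- length(gr)
  af <- rep(NA_real_, n)
  if ("AF" %in% names(inf)) {
    afl <- inf$AF
    af <- vapply(seq_len(n), function(i) {
      v <- afl[[i]]
      if (length(v) == 0 || all(is.na(v))) NA_real_ else as.numeric(v[1])
    }, numeric(1))
  }
  svtype <- if ("SVTYPE" %in% names(inf)) as.character(inf$SVTYPE) else rep(NA_character_, n)
  if ("END" %in% names(inf)) {
    endv <- suppressWarnings(as.integer(inf$END))
    useEnd <- !is.na(svtype) & !is.na(endv)
    if (any(useEnd)) end(gr)[useEnd] <- endv[useEnd]
  }
  mcols(gr)$id <- rownames(vcf)
  mcols(gr)$ref <- as.character(rr$REF)
  mcols(gr)$alt <- vapply(seq_len(n), function(i) {
    a <- rr$ALT[[i]]
    if (length(a)) as.character(a)[1] else NA_character_
  }, character(1))
  mcols(gr)$svtype <- svtype
  ## AF = 0 encodes "absent from the reference database"; missing AF means
  ## frequency-unknown and is carried as af = NA, observed = NA.
  mcols(gr)$af <- af
  mcols(gr)$observed <- ifelse(is.na(af), NA, af > 0)
  nh <- if ("nhomalt" %in% names(inf)) suppressWarnings(as.integer(inf$nhomalt)) else rep(0L, n)
  nh[is.na(nh)] <- 0L
  mcols(gr)$n_hom <- nh
  gr
}

#' Write variants in the normative TSV schema
#'
#' @param v variant `GRanges` as returned by [readVariants()].
#' @param path output path.
#' @export
writeVariants <- function(v, path) {
  m <- mcols(v)
  df <- data.frame(chrom = as.character(seqnames(v)), pos = start(v),
                   id = m$id, ref = m$ref, alt = m$alt, svtype = m$svtype,
                   end = ifelse(is.na(m$svtype), NA_integer_, end(v)),
                   af = m$af, observed = m$observed, n_hom = m$n_hom)
  if (!is.null(m$n_carriers)) df$n_carriers <- m$n_carriers
  if (!is.null(m$in_unsolved)) df$in_unsolved <- m$in_unsolved
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read gene models (TSV: gene_id, chrom, tss, strand)
#'
#' `tss` is the 0-based coordinate of the transcription start site.
#'
#' @param path path to the TSV.
#' @param assembly a `Seqinfo`.
#' @return A width-1 `GRanges` anchored at each TSS with a `gene_id` column.
#' @export
readGeneModels <- function(path, assembly) {
  df <- read.delim(path, header = TRUE)
  need <- c("gene_id", "chrom", "tss", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene model TSV lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id: ", df$gene_id[duplicated(df$gene_id)][1])
  if (!all(df$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  gr <- GRanges(as.character(df$chrom), IRanges(df$tss + 1L, df$tss + 1L),
                strand = df$strand, seqinfo = assembly)
  checkWithinAssembly(gr, "TSS")
  mcols(gr)$gene_id <- as.character(df$gene_id)
  gr
}

#' Write gene models as TSV
#' @param genes width-1 TSS `GRanges` with `gene_id`.
#' @param path output path.
#' @export
writeGeneModels <- function(genes, path) {
  df <- data.frame(gene_id = mcols(genes)$gene_id,
                   chrom = as.character(seqnames(genes)),
                   tss = start(genes) - 1L,
                   strand = as.character(strand(genes)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix (genes x conditions TSV)
#'
#' @param path TSV with a leading `gene_id` column; remaining columns are
#'   stages or cell clusters.
#' @return A numeric matrix with gene rownames.
#' @export
readExpression <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE)
  if (names(df)[1] != "gene_id") stop("expression TSV must start with a gene_id column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  if (anyDuplicated(colnames(m))) stop("duplicate condition labels")
  if (any(m < 0)) stop("negative expression values")
  m
}

#' Write an expression matrix as TSV
#' @param m numeric matrix with gene rownames.
#' @param path output path.
#' @export
writeExpression <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a disease-gene table (TSV: gene, panel, phenotype)
#' @param path path to the TSV.
#' @return A data.frame with unique gene keys.
#' @export
readDiseaseTable <- function(path) {
  df <- read.delim(path, header = TRUE)
  if (!all(c("gene", "panel", "phenotype") %in% names(df)))
    stop("disease table needs columns gene, panel, phenotype")
  if (anyDuplicated(df$gene)) stop("duplicate gene keys in disease table")
  df
}

#' Read a validated-enhancer label table
#'
#' TSV columns: `chrom, start, end, label, tissues` with 0-based half-open
#' coordinates, `label` in `positive`/`negative` and `tissues` a
#' semicolon-separated list (empty unless positive).
#'
#' @param path path to the TSV.
#' @param assembly a `Seqinfo`.
#' @return A `GRanges` with `label` and a `tissues` CharacterList column.
#' @export
readEnhancerLabels <- function(path, assembly) {
  df <- read.delim(path, header = TRUE, na.strings = c("NA", ""))
  if (!all(c("chrom", "start", "end", "label") %in% names(df)))
    stop("label table needs columns chrom, start, end, label")
  if (!all(df$label %in% c("positive", "negative")))
    stop("labels must be 'positive' or 'negative'")
  gr <- GRanges(as.character(df$chrom), IRanges(df$start + 1L, df$end),
                seqinfo = assembly)
  checkWithinAssembly(gr, "label element")
  tis <- strsplit(ifelse(is.na(df$tissues), "", as.character(df$tissues)), ";",
                  fixed = TRUE)
  if (any(df$label == "negative" & lengths(tis) > 0))
    stop("tissue annotations are only allowed on positive elements")
  mcols(gr)$label <- as.character(df$label)
  mcols(gr)$tissues <- CharacterList(tis)
  gr
}

#' Read peak-to-gene linkage triples (TSV: chrom, start, end, gene, correlation)
#' @param path path to the TSV (0-based half-open peak coordinates).
#' @param assembly a `Seqinfo`.
#' @return A `GRanges` with `gene` and `correlation` columns.
#' @export
readLinkages <- function(path, assembly) {
  df <- read.delim(path, header = TRUE)
  need <- c("chrom", "start", "end", "gene", "correlation")
  if (!all(need %in% names(df)))
    stop("linkage TSV needs columns ", paste(need, collapse = ", "))
  gr <- GRanges(as.character(df$chrom), IRanges(df$start + 1L, df$end),
                seqinfo = assembly)
  checkWithinAssembly(gr, "linkage peak")
  mcols(gr)$gene <- as.character(df$gene)
  mcols(gr)$correlation <- as.numeric(df$correlation)
  gr
}
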