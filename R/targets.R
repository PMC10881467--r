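#' RegulatoryDomains: basal-plus-extension domains for a gene set
#'
#' Each gene owns a strand-aware basal domain (default 5 kb upstream and 1 kb
#' downstream of its TSS) and an extension that reaches, on each side, to the
#' nearer of the closest other gene's basal-domain boundary and a maximum
#' extension (default 1 Mb), clamped to the chromosome ends. Basal domains
#' are never truncated by neighbours; only extensions are.
#'
#' @slot genes width-1 TSS `GRanges` with `gene_id` and strand.
#' @slot basal basal domains, parallel to `genes`.
#' @slot extended extended (or curated) domains, parallel to `genes`.
#' @export
setClass("RegulatoryDomains",
         representation(genes = "GRanges", basal = "GRanges",
                        extended = "GRanges"))

setValidity("RegulatoryDomains", function(object) {
  n <- length(object@genes)
  if (length(object@basal) != n || length(object@extended) != n)
    return("slots must be parallel")
  if (any(start(object@extended) > start(object@basal)) ||
      any(end(object@extended) < end(object@basal)))
    return("basal domain must be contained in the extended domain")
  TRUE
})

setMethod("show", "RegulatoryDomains", function(object) {
  cat("RegulatoryDomains for", length(object@genes), "genes\n")
  if (length(object@genes))
    cat("  median extended width:", median(width(object@extended)), "bp\n")
})

#' @describeIn RegulatoryDomains-class basal domains (`GRanges`).
#' @param x a `RegulatoryDomains`.
#' @export
basalDomains <- function(x) x@basal

#' @describeIn RegulatoryDomains-class extended domains (`GRanges`).
#' @export
extendedDomains <- function(x) x@extended

#' @describeIn RegulatoryDomains-class gene identifiers.
#' @export
geneIds <- function(x) mcols(x@genes)$gene_id

#' Build basal-plus-extension regulatory domains
#'
#' The basal domain spans `[tss - up, tss + down)` on the plus strand,
#' mirrored on the minus strand. The extension on each side stops at the
#' nearest other gene's basal-domain boundary, or after `maxExt` bp,
#' whichever comes first; when a foreign basal domain overlaps this gene's
#' basal boundary on a side, the extension on that side is zero. Curated
#' entries override the computed extension (the mechanism used for
#' experimentally established long-range domains), widened if necessary so
#' the basal domain stays contained.
#'
#' @param genes width-1 TSS `GRanges` with unique `gene_id` and `+`/`-`
#'   strand, carrying a `Seqinfo` with chromosome lengths.
#' @param up,down basal extent upstream/downstream of the TSS in bp.
#' @param maxExt maximum extension beyond the basal domain in bp.
#' @param curated optional data.frame `gene_id, chrom, start, end` (0-based
#'   half-open) of curated domains.
#' @return A [RegulatoryDomains-class].
#' @export
buildDomains <- function(genes, up = 5000, down = 1000, maxExt = 1e6,
                         curated = NULL) {
  if (any(c(up, down, maxExt) <= 0)) stop("up, down and maxExt must be > 0")
  ids <- mcols(genes)$gene_id
  if (is.null(ids)) stop("genes need a gene_id column")
  if (anyDuplicated(ids)) stop("duplicate gene_id: ", ids[duplicated(ids)][1])
  str <- as.character(strand(genes))
  if (!all(str %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  sl <- seqlengths(seqinfo(genes))
  t0 <- start(genes) - 1L          # 0-based TSS
  bs0 <- ifelse(str == "+", t0 - up, t0 - down + 1)
  be0 <- ifelse(str == "+", t0 + down, t0 + up + 1)
  chrom <- as.character(seqnames(genes))
  bs0 <- pmax(0, bs0)
  be0 <- pmin(sl[chrom], be0)
  es0 <- numeric(length(genes)); ee0 <- numeric(length(genes))
  for (i in seq_along(genes)) {
    j <- which(chrom == chrom[i]); j <- j[j != i]
    leftLim <- bs0[i] - maxExt
    if (length(j)) {
      below <- be0[j][be0[j] <= bs0[i]]
      if (length(below)) leftLim <- max(leftLim, max(below))
      if (any(bs0[j] < bs0[i] & be0[j] > bs0[i])) leftLim <- bs0[i]
    }
    rightLim <- be0[i] + maxExt
    if (length(j)) {
      above <- bs0[j][bs0[j] >= be0[i]]
      if (length(above)) rightLim <- min(rightLim, min(above))
      if (any(bs0[j] < be0[i] & be0[j] > be0[i])) rightLim <- be0[i]
    }
    es0[i] <- max(0, leftLim)
    ee0[i] <- min(sl[chrom[i]], rightLim)
  }
  if (!is.null(curated)) {
    hit <- match(curated$gene_id, ids)
    if (any(is.na(hit)))
      stop("curated domain for unknown gene: ",
           curated$gene_id[is.na(hit)][1])
    for (k in seq_along(hit)) {
      i <- hit[k]
      if (as.character(curated$chrom[k]) != chrom[i])
        stop("curated domain on wrong chromosome for ", ids[i])
      es0[i] <- min(curated$start[k], bs0[i])
      ee0[i] <- max(curated$end[k], be0[i])
    }
  }
  basal <- GRanges(chrom, IRanges(bs0 + 1, be0), seqinfo = seqinfo(genes))
  extended <- GRanges(chrom, IRanges(es0 + 1, ee0), seqinfo = seqinfo(genes))
  mcols(basal)$gene_id <- ids
  mcols(extended)$gene_id <- ids
  new("RegulatoryDomains", genes = genes, basal = basal, extended = extended)
}

#' Assign target genes to elements by regulatory-domain overlap
#'
#' An element is associated with every gene whose extended (or curated)
#' regulatory domain it overlaps by at least one base. The signed TSS
#' distance uses half-open boundary arithmetic ([distanceToPoint()]);
#' negative values place the TSS left of the element.
#'
#' @param ucneSet `GRanges` of elements with a `name` column.
#' @param domains a [RegulatoryDomains-class].
#' @return A data.frame of edges: `ucne`, `gene`, `tss_distance`.
#' @export
assignTargets <- function(ucneSet, domains) {
  hits <- intersectPairs(ucneSet, domains@extended)
  if (!nrow(hits))
    return(data.frame(ucne = character(0), gene = character(0),
                      tss_distance = numeric(0)))
  tss0 <- start(domains@genes)[hits$bIdx] - 1L
  d <- distanceToPoint(ucneSet[hits$aIdx], tss0)
  data.frame(ucne = mcols(ucneSet)$name[hits$aIdx],
             gene = geneIds(domains)[hits$bIdx],
             tss_distance = d)
}

#' Histogram of associated genes per element
#' @param edges edge table from [assignTargets()].
#' @param ucneNames all queried element names (so zero-target elements are
#'   counted).
#' @return A table of element counts by number of target genes.
#' @export
genesPerUcne <- function(edges, ucneNames) {
  counts <- table(factor(edges$ucne, levels = ucneNames))
  table(as.integer(counts))
}

#' Bin TSS-element distances
#'
#' Magnitudes are binned 0-5 kb, 5-50 kb, 50-500 kb and >500 kb regardless of
#' orientation; the sign stays available in the raw edge table.
#'
#' @param d signed distances in bp.
#' @return A factor with the four distance bins.
#' @export
tssDistanceBins <- function(d) {
  cut(abs(d), breaks = c(-1, 5e3, 5e4, 5e5, Inf),
      labels = c("0-5kb", "5-50kb", "50-500kb", ">500kb"))
}

#' Restrict edges to retina-expressed target genes
#'
#' A gene counts as expressed when its TPM reaches `tpmMin` in at least one
#' interrogated stage (`TPM < 0.5` defines non-expression, so exactly 0.5 is
#' kept). Genes absent from the matrix are dropped with a warning and counted
#' in the `nMissing` attribute.
#'
#' @param edges edge table from [assignTargets()].
#' @param stageExpr genes x stages TPM matrix.
#' @param tpmMin expression threshold in TPM.
#' @return The restricted edge table with attribute `nMissing`.
#' @export
filterExpressed <- function(edges, stageExpr, tpmMin = 0.5) {
  present <- edges$gene %in% rownames(stageExpr)
  nMissing <- length(unique(edges$gene[!present]))
  if (nMissing)
    warning(nMissing, " target gene(s) absent from the expression matrix")
  keepGene <- rownames(stageExpr)[
    apply(stageExpr, 1, max) >= tpmMin]
  out <- edges[present & edges$gene %in% keepGene, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nMissing") <- nMissing
  out
}

#' TAD co-containment of elements and their target TSSs
#'
#' An edge is TAD-consistent when some TAD overlaps the element by at least
#' one base and contains the gene's TSS (half-open: a TSS at the TAD end
#' coordinate is outside).
#'
#' @param edges edge table.
#' @param tads `GRanges` of TADs.
#' @param ucneSet element `GRanges` with `name`.
#' @param genes TSS `GRanges` with `gene_id`.
#' @return A list: `edges` (with logical `tad_consistent` column),
#'   `fractionGenes` (consistent genes / total genes) and `fractionEdges`.
#' @export
tadConsistency <- function(edges, tads, ucneSet, genes) {
  uIdx <- match(edges$ucne, mcols(ucneSet)$name)
  gIdx <- match(edges$gene, mcols(genes)$gene_id)
  if (any(is.na(uIdx)) || any(is.na(gIdx)))
    stop("edge refers to unknown element or gene")
  uHits <- as(findOverlaps(ucneSet, tads, minoverlap = 1L,
                           ignore.strand = TRUE), "List")
  gHits <- as(findOverlaps(genes, tads, ignore.strand = TRUE), "List")
  cons <- vapply(seq_len(nrow(edges)), function(k) {
    length(intersect(uHits[[uIdx[k]]], gHits[[gIdx[k]]])) > 0
  }, logical(1))
  edges$tad_consistent <- cons
  gTot <- unique(edges$gene)
  gCons <- unique(edges$gene[cons])
  list(edges = edges,
       fractionGenes = if (length(gTot)) length(gCons) / length(gTot) else NA_real_,
       fractionEdges = if (nrow(edges)) mean(cons) else NA_real_)
}

#' Cell-type expression signatures by within-gene percentile
#'
#' For each gene, the threshold is the `pct`-th percentile (linear
#' interpolation) of its own values across clusters; the signature is the set
#' of clusters strictly above it. A constant gene therefore has an empty
#' signature, and an all-zero gene returns empty rather than erroring.
#'
#' @param clusterExpr genes x clusters expression matrix (>= 2 clusters).
#' @param pct percentile threshold (default 80).
#' @return A named `CharacterList`, one entry per gene.
#' @export
assignSignatures <- function(clusterExpr, pct = 80) {
  if (ncol(clusterExpr) < 2) stop("need at least two clusters")
  sig <- lapply(seq_len(nrow(clusterExpr)), function(i) {
    v <- clusterExpr[i, ]
    thr <- quantile(v, pct / 100, type = 7, names = FALSE)
    colnames(clusterExpr)[v > thr]
  })
  names(sig) <- rownames(clusterExpr)
  CharacterList(sig)
}

#' Open-chromatin / expression-signature concordance
#'
#' An active element is concordant when the set of clusters in which it is
#' open intersects the union of its target genes' signature clusters.
#' Cluster labels from the accessibility data are mapped onto the expression
#' vocabulary through `clusterMap` (identity by default); an unmapped label
#' is an error.
#'
#' @param edges edge table (targets per element).
#' @param profiles a [UcneProfiles-class].
#' @param signatures output of [assignSignatures()].
#' @param clusterMap optional named character vector mapping accessibility
#'   cluster labels to expression cluster labels.
#' @return A list: `perUcne` data.frame (`ucne`, `concordant`) over active
#'   elements and `fraction`.
#' @export
concordance <- function(edges, profiles, signatures, clusterMap = NULL) {
  act <- which(isOpen(profiles))
  oc <- openClusters(profiles)
  nmU <- mcols(profiles@ucnes)$name
  conc <- vapply(act, function(i) {
    cl <- oc[[i]]
    if (!is.null(clusterMap) && length(cl)) {
      unmapped <- setdiff(cl, names(clusterMap))
      if (length(unmapped))
        stop("unmapped cluster label: ", unmapped[1])
      cl <- unname(clusterMap[cl])
    }
    tg <- edges$gene[edges$ucne == nmU[i]]
    sigU <- unique(unlist(signatures[intersect(tg, names(signatures))],
                          use.names = FALSE))
    length(intersect(cl, sigU)) > 0
  }, logical(1))
  list(perUcne = data.frame(ucne = nmU[act], concordant = conc),
       fraction = if (length(act)) mean(conc) else NA_real_)
}

#' Compare domain-derived targets with correlation-based linkages
#'
#' Linkage-derived targets of an element are the genes of peaks with
#' correlation strictly above `corrMin` that overlap the element within a
#' symmetric window. Each element is classified against its domain-derived
#' target set as `identical`, `partial`, `disjoint` or `no_linkage`.
#'
#' @param edges domain-derived edge table.
#' @param linkages linkage `GRanges` from [readLinkages()].
#' @param ucneSet element `GRanges` with `name`.
#' @param corrMin correlation threshold (strict, default 0.4).
#' @param flank window half-width in bp (default 250).
#' @return A list: `perUcne` data.frame (`ucne`, `class`, `domain_targets`,
#'   `linkage_targets`) and `agreement` (fraction classified `identical`
#'   among elements with any target by either route).
#' @export
peak2geneCompare <- function(edges, linkages, ucneSet, corrMin = 0.4,
                             flank = 250) {
  qual <- linkages[mcols(linkages)$correlation > corrMin]
  pr <- windowOverlapPairs(ucneSet, qual, flank)
  nmU <- mcols(ucneSet)$name
  linkSets <- split(mcols(qual)$gene[pr$bIdx], nmU[pr$aIdx])
  rows <- lapply(seq_along(ucneSet), function(i) {
    dom <- unique(edges$gene[edges$ucne == nmU[i]])
    lnk <- unique(linkSets[[nmU[i]]])
    if (is.null(lnk)) lnk <- character(0)
    cls <- if (!length(lnk) && !length(dom)) "identical"
      else if (!length(lnk)) "no_linkage"
      else if (setequal(dom, lnk)) "identical"
      else if (length(intersect(dom, lnk))) "partial"
      else "disjoint"
    data.frame(ucne = nmU[i], class = cls,
               domain_targets = paste(sort(dom), collapse = ","),
               linkage_targets = paste(sort(lnk), collapse = ","))
  })
  per <- do.call(rbind, rows)
  withAny <- per[per$domain_targets != "" | per$linkage_targets != "", ]
  list(perUcne = per,
       agreement = if (nrow(withAny)) mean(withAny$class == "identical") else NA_real_)
}

#' Restrict edges to disease-linked genes
#'
#' @param edges edge table.
#' @param diseaseTable data.frame with unique `gene` keys plus `panel` and
#'   `phenotype`.
#' @return Edges whose gene appears in the table, annotated with `panel` and
#'   `phenotype`.
#' @export
diseaseGeneFilter <- function(edges, diseaseTable) {
  if (anyDuplicated(diseaseTable$gene)) stop("disease table keys must be unique")
  hit <- match(edges$gene, diseaseTable$gene)
  out <- edges[!is.na(hit), , drop = FALSE]
  out$panel <- diseaseTable$panel[hit[!is.na(hit)]]
  out$phenotype <- diseaseTable$phenotype[hit[!is.na(hit)]]
  rownames(out) <- NULL
  out
}
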