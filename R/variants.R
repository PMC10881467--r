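.frequencyBinLevels <- c("ultrarare", "very_rare", "rare", "low_frequency",
                         "common")

#' Classify variants into population-frequency bins
#'
#' Bins follow the reference-database convention: `ultrarare` (absent from
#' the reference database), `very_rare` (MAF < 0.1%), `rare`
#' (0.1% <= MAF < 0.5%), `low_frequency` (0.5% <= MAF < 5%) and `common`
#' (MAF >= 5%). MAF is the alternate-allele frequency folded at 0.5.
#' A frequency-unknown record (no frequency and no absence flag) is an error,
#' never defaulted to a bin.
#'
#' @param v variant `GRanges` from [readVariants()] (needs `af` and
#'   `observed` columns).
#' @return A factor with the five bin levels.
#' @export
classifyFrequency <- function(v) {
  af <- mcols(v)$af
  obs <- mcols(v)$observed
  if (is.null(af) || is.null(obs)) stop("variants need 'af' and 'observed' columns")
  unknown <- which(is.na(obs) | (obs & is.na(af)))
  if (length(unknown))
    stop("frequency-unknown variant cannot be binned: ",
         mcols(v)$id[unknown[1]])
  maf <- pmin(af, 1 - af)
  bin <- ifelse(!obs, "ultrarare",
         ifelse(maf < 0.001, "very_rare",
         ifelse(maf < 0.005, "rare",
         ifelse(maf < 0.05, "low_frequency", "common"))))
  factor(bin, levels = .frequencyBinLevels)
}

#' Rare-variant filter
#'
#' Keeps variants that are absent from the reference database or have
#' MAF < 0.5% there, and that have no observed reference-population
#' homozygotes.
#'
#' @param v variant `GRanges`.
#' @return The filtered `GRanges`.
#' @export
rareFilter <- function(v) {
  bin <- classifyFrequency(v)
  keep <- bin %in% c("ultrarare", "very_rare", "rare") & mcols(v)$n_hom == 0L
  v[keep]
}

#' Overlap variants with putatively active elements
#'
#' Any-overlap semantics (>= 1 bp): an SNV at the first base of an element is
#' a hit, and so is a large structural variant whose span covers the element
#' entirely. Hits are annotated with the element's enhancer state and
#' domain-derived target genes.
#'
#' @param v variant `GRanges`.
#' @param profiles a classified [UcneProfiles-class].
#' @param edges edge table restricted to the gene set of interest.
#' @return A data.frame of hits: `variant_id`, `bin`, `is_sv`, `ucne`,
#'   `enhancer_state`, `genes` (comma-joined), plus `in_unsolved` when the
#'   cohort column is present.
#' @export
overlapActiveUcnes <- function(v, profiles, edges) {
  act <- which(isOpen(profiles))
  ug <- profiles@ucnes[act]
  pr <- intersectPairs(v, ug)
  bin <- classifyFrequency(v)
  nmU <- mcols(ug)$name
  st <- as.character(profiles@state)[act]
  genesOf <- function(u) paste(sort(unique(edges$gene[edges$ucne == u])),
                               collapse = ",")
  out <- data.frame(
    variant_id = mcols(v)$id[pr$aIdx],
    bin = as.character(bin)[pr$aIdx],
    is_sv = !is.na(mcols(v)$svtype[pr$aIdx]),
    ucne = nmU[pr$bIdx],
    enhancer_state = st[pr$bIdx],
    genes = vapply(nmU[pr$bIdx], genesOf, ""))
  if (!is.null(mcols(v)$in_unsolved))
    out$in_unsolved <- mcols(v)$in_unsolved[pr$aIdx]
  rownames(out) <- NULL
  out
}

#' Define the prioritized variant search space
#'
#' Keeps hits whose element displays histone-modification evidence (state at
#' least `marked`) and whose target set intersects the disease-gene table,
#' and summarizes the result as counts of distinct variants, elements and
#' disease genes, overall and restricted to unsolved cases when that cohort
#' column is available.
#'
#' @param hits hit table from [overlapActiveUcnes()].
#' @param diseaseGenes character vector of disease-linked gene ids.
#' @return A list: `hits` (the prioritized subset, with a `disease_genes`
#'   column) and `counts`.
#' @export
defineSearchSpace <- function(hits, diseaseGenes) {
  stateOk <- match(hits$enhancer_state, .enhancerStateLevels) >=
    match("marked", .enhancerStateLevels)
  gList <- strsplit(hits$genes, ",", fixed = TRUE)
  dz <- lapply(gList, intersect, diseaseGenes)
  keep <- stateOk & lengths(dz) > 0
  sub <- hits[keep, , drop = FALSE]
  sub$disease_genes <- vapply(dz[keep], paste, "", collapse = ",")
  rownames(sub) <- NULL
  counts <- list(
    n_variants = length(unique(sub$variant_id)),
    n_ucnes = length(unique(sub$ucne)),
    n_genes = length(unique(unlist(dz[keep]))))
  if (!is.null(sub$in_unsolved)) {
    uns <- sub[sub$in_unsolved %in% TRUE, , drop = FALSE]
    counts$n_variants_unsolved <- length(unique(uns$variant_id))
    counts$n_ucnes_unsolved <- length(unique(uns$ucne))
  }
  list(hits = sub, counts = counts)
}
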