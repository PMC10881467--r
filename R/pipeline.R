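#' Pipeline configuration
#'
#' All thresholds default to the analysis' printed values: accessibility
#' peak cutoff 0.4 and histone-mark cutoff 20, ChIP window +/- 250 bp,
#' TPM >= 0.5 expression filter, 80th-percentile expression signatures,
#' peak-to-gene correlation strictly above 0.4, MAF < 0.5% rare filter,
#' 200 random background fragments of 350 bp, and 200 bp constraint flanks.
#' Explicit overrides are recorded and logged by [runPipeline()].
#'
#' @param flank ChIP-seq overlap window half-width (bp).
#' @param tpmMin expression threshold (TPM).
#' @param pct signature percentile.
#' @param corrMin peak-to-gene correlation threshold (strict).
#' @param up,down,maxExt regulatory-domain parameters (bp).
#' @param cutoffAccessibility,cutoffMarks peak-calling cutoffs.
#' @param peakMinLength,peakMaxGap peak-calling shape parameters (bp).
#' @param nFragments,fragmentLength random background fragment count and width.
#' @param constraintFlank constraint flank width (bp).
#' @param devStages,adultStages stage vocabularies for enhancer-state calls.
#' @param dnaseLowLabel,dnaseLabels low-signal filtering vocabulary.
#' @param seed integer seed for background sampling when the bundle does not
#'   provide fragments.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(flank = 250, tpmMin = 0.5, pct = 80,
    corrMin = 0.4, up = 5000, down = 1000, maxExt = 1e6,
    cutoffAccessibility = 0.4, cutoffMarks = 20,
    peakMinLength = 200, peakMaxGap = 30,
    nFragments = 200L, fragmentLength = 350L, constraintFlank = 200,
    devStages = c("FW13/14", "FW15/16", "FW18/20", "FW23/24"),
    adultStages = "adult",
    dnaseLowLabel = "Low-DNase",
    dnaseLabels = c("High-DNase", "Low-DNase"),
    seed = 1L) {
  cfg <- as.list(environment())
  overrides <- names(as.list(match.call()))[-1]
  attr(cfg, "overrides") <- overrides
  class(cfg) <- "PipelineConfig"
  cfg
}

## Polynomial rolling hash over the canonical config text (provenance only).
.hashConfig <- function(cfg) {
  txt <- paste(utils::capture.output(utils::str(unclass(cfg))), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' RunReport: stage-by-stage pipeline summary
#'
#' @slot data named list of stage counts, fractions, statistics and
#'   provenance, as produced by [runPipeline()].
#' @export
setClass("RunReport", representation(data = "list"))

setMethod("show", "RunReport", function(object) {
  d <- object@data
  cat("ucre pipeline report (config ", d$provenance$config_hash, ")\n", sep = "")
  cat("  elements: ", d$annotate$n_ucnes, " total, ", d$annotate$n_open,
      " open (", d$annotate$n_high_confidence, " high-confidence)\n", sep = "")
  cat("  states: ", d$annotate$n_marked, " marked, ",
      d$annotate$n_active_enhancer, " active enhancer, ",
      d$annotate$n_sustained_adult, " sustained at adult stage\n", sep = "")
  cat("  targets: ", d$targets$n_target_genes, " genes (",
      d$targets$n_expressed_genes, " expressed, ",
      d$targets$n_tad_consistent_genes, " TAD-consistent)\n", sep = "")
  cat("  variants: ", d$variants$n_rare, " rare-filtered, search space ",
      d$variants$search_space$n_variants, " variants / ",
      d$variants$search_space$n_ucnes, " elements / ",
      d$variants$search_space$n_genes, " genes\n", sep = "")
  cat("  constraint: KW H = ", format(d$constraint$H, digits = 6),
      ", p = ", format(d$constraint$p, digits = 4), "\n", sep = "")
})

#' @describeIn RunReport-class the report payload as a named list.
#' @param x a `RunReport`.
#' @export
reportData <- function(x) x@data

#' Write a run report as JSON
#' @param report a [RunReport-class].
#' @param path output path.
#' @export
writeRunReport <- function(report, path) {
  jsonlite::write_json(report@data, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

## ---- stage functions ------------------------------------------------------

#' Annotation stage: peak calling, accessibility, marks, state
#' @param bundle a `SimBundle`.
#' @param config a [pipelineConfig()].
#' @return A list with `profiles`, `markCounts`, `vista` and `counts`.
#' @export
stageAnnotate <- function(bundle, config = pipelineConfig()) {
  if (is.null(bundle$scatac) && is.null(bundle$dnase))
    stop("missing upstream artifact: accessibility peak inputs")
  scPeaks <- lapply(bundle$scatac, function(b) {
    trackBundle(callPeaks(b$payload, config$cutoffAccessibility,
                          config$peakMinLength, config$peakMaxGap),
                cluster = b$cluster, stage = b$stage)
  })
  dnPeaks <- lapply(bundle$dnase, function(b) {
    pk <- b$payload
    lab <- mcols(pk)$name
    if (is.null(lab)) lab <- rep(config$dnaseLabels[1], length(pk))
    trackBundle(filterLowSignalRegions(pk, lab, config$dnaseLowLabel,
                                       allowed = config$dnaseLabels),
                stage = b$stage)
  })
  chPeaks <- lapply(bundle$chip, function(b) {
    trackBundle(callPeaks(b$payload, config$cutoffMarks,
                          config$peakMinLength, config$peakMaxGap),
                mark = b$mark, stage = b$stage)
  })
  profiles <- identifyOpenUcnes(bundle$ucnes, dnPeaks, scPeaks)
  profiles <- annotateMarks(profiles, chPeaks, flank = config$flank)
  profiles <- classifyEnhancerState(profiles, config$devStages,
                                    config$adultStages)
  st <- as.integer(enhancerState(profiles))
  counts <- list(
    n_ucnes = length(ucnes(profiles)),
    n_open = sum(isOpen(profiles)),
    n_high_confidence = sum(isHighConfidence(profiles)),
    n_marked = sum(st >= 3L),
    n_marked_activating = sum(vapply(as.list(markNames(profiles)),
                                     function(m) any(m %in% activatingMarks()),
                                     logical(1))),
    n_active_enhancer = sum(st >= 4L),
    n_sustained_adult = sum(st >= 5L),
    active_mark_cooccurrence = activeMarkCooccurrence(profiles))
  vista <- NULL
  if (!is.null(bundle$vista)) {
    act <- ucnes(profiles)[isOpen(profiles)]
    vista <- vistaCorrelate(list(all_ucnes = granges(bundle$ucnes),
                                 active_ucnes = granges(act)),
                            bundle$vista)
  }
  list(profiles = profiles,
       markCounts = markCountTable(profiles,
                                   stages = c(config$devStages,
                                              config$adultStages)),
       vista = vista, counts = counts)
}

#' Target-assignment stage
#' @param bundle a `SimBundle`.
#' @param config a [pipelineConfig()].
#' @param ann output of [stageAnnotate()].
#' @return A list with domains, edge tables, signatures, concordance,
#'   linkage comparison, disease subset and `counts`.
#' @export
stageTargets <- function(bundle, config, ann) {
  if (is.null(bundle$genes) || is.null(bundle$stageExpr))
    stop("missing upstream artifact: gene models or stage expression")
  profiles <- ann$profiles
  active <- ucnes(profiles)[isOpen(profiles)]
  domains <- buildDomains(bundle$genes, config$up, config$down, config$maxExt)
  edges <- assignTargets(active, domains)
  expressedEdges <- suppressWarnings(
    filterExpressed(edges, bundle$stageExpr, config$tpmMin))
  tad <- tadConsistency(expressedEdges, bundle$tads, active, bundle$genes)
  signatures <- assignSignatures(bundle$clusterExpr, config$pct)
  conc <- concordance(expressedEdges, profiles, signatures)
  p2g <- if (!is.null(bundle$linkages))
    peak2geneCompare(expressedEdges, bundle$linkages, active,
                     config$corrMin, config$flank) else NULL
  dzEdges <- if (!is.null(bundle$diseaseTable))
    diseaseGeneFilter(tad$edges, bundle$diseaseTable) else NULL
  dTss <- edges$tss_distance
  counts <- list(
    n_active = length(active),
    n_edges = nrow(edges),
    n_target_genes = length(unique(edges$gene)),
    n_expressed_edges = nrow(expressedEdges),
    n_expressed_genes = length(unique(expressedEdges$gene)),
    n_missing_expression = attr(expressedEdges, "nMissing"),
    n_tad_consistent_genes = length(unique(tad$edges$gene[tad$edges$tad_consistent])),
    tad_consistent_fraction_genes = tad$fractionGenes,
    concordant_fraction = conc$fraction,
    peak2gene_agreement = if (!is.null(p2g)) p2g$agreement else NA,
    n_disease_genes = if (!is.null(dzEdges)) length(unique(dzEdges$gene)) else NA,
    n_disease_ucnes = if (!is.null(dzEdges)) length(unique(dzEdges$ucne)) else NA,
    genes_per_ucne = as.list(genesPerUcne(edges, mcols(active)$name)),
    tss_distance_bins = as.list(table(tssDistanceBins(dTss))))
  list(domains = domains, edges = edges, expressedEdges = tad$edges,
       signatures = signatures, concordance = conc, p2g = p2g,
       dzEdges = dzEdges, counts = counts)
}

#' Variant-prioritization stage
#' @param bundle a `SimBundle`.
#' @param config a [pipelineConfig()].
#' @param ann,tgt outputs of the previous stages.
#' @return A list with the rare set, hit table, search space and `counts`.
#' @export
stageVariants <- function(bundle, config, ann, tgt) {
  if (is.null(bundle$variants))
    stop("missing upstream artifact: variant table")
  bins <- classifyFrequency(bundle$variants)
  rare <- rareFilter(bundle$variants)
  hits <- overlapActiveUcnes(rare, ann$profiles, tgt$expressedEdges)
  dzGenes <- if (!is.null(bundle$diseaseTable)) bundle$diseaseTable$gene else character(0)
  space <- defineSearchSpace(hits, dzGenes)
  dzUcnes <- if (!is.null(tgt$dzEdges)) unique(tgt$dzEdges$ucne) else character(0)
  nUltraDz <- sum(hits$bin == "ultrarare" & hits$ucne %in% dzUcnes)
  counts <- list(
    n_variants = length(bundle$variants),
    bin_counts = as.list(table(bins)),
    n_rare = length(rare),
    n_hits = nrow(hits),
    n_ultrarare_hits = sum(hits$bin == "ultrarare"),
    n_ultrarare_disease_hits = nUltraDz,
    n_sv_hits = sum(hits$is_sv),
    search_space = space$counts)
  list(rare = rare, hits = hits, searchSpace = space, counts = counts)
}

#' Constraint and frequency-spectrum stage
#'
#' Regions of interest are the disease-linked elements (falling back to all
#' active elements when no disease table is available), their flanks, and
#' the random background (taken from the bundle, or sampled with the config
#' seed excluding the element set).
#'
#' @param bundle a `SimBundle`.
#' @param config a [pipelineConfig()].
#' @param ann,tgt outputs of the previous stages.
#' @return A list with `spectrum`, `rankTest`, `suitability` and `counts`.
#' @export
stageConstraint <- function(bundle, config, ann, tgt) {
  if (is.null(bundle$constraint))
    stop("missing upstream artifact: constraint track")
  profiles <- ann$profiles
  active <- ucnes(profiles)[isOpen(profiles)]
  dzNames <- if (!is.null(tgt$dzEdges)) unique(tgt$dzEdges$ucne) else character(0)
  roi <- if (length(dzNames)) active[mcols(active)$name %in% dzNames] else active
  flanks <- buildFlanks(roi, config$constraintFlank)
  background <- bundle$background
  if (is.null(background))
    background <- sampleFragments(bundle$assembly, config$nFragments,
                                  config$fragmentLength,
                                  exclude = granges(bundle$ucnes),
                                  seed = config$seed)
  spectrum <- if (!is.null(bundle$variants))
    afSpectrum(bundle$variants, roi, background) else NULL
  rankTest <- compareConstraint(bundle$constraint, roi, flanks, background)
  suit <- backgroundSuitability(roi, background, bundle$genes)
  ub <- rankTest@pairwise[rankTest@pairwise$group_i == "UCNE" &
                            rankTest@pairwise$group_j == "Random", ]
  counts <- list(
    n_roi_ucnes = length(roi),
    H = rankTest@H, p = rankTest@p,
    medians = as.list(rankTest@medians),
    z_ucne_random = ub$z, p_adj_ucne_random = ub$p_adjusted,
    pairwise = lapply(seq_len(nrow(rankTest@pairwise)), function(i)
      as.list(rankTest@pairwise[i, ])),
    spectrum_roi = if (!is.null(spectrum)) as.list(spectrum$proportions) else NULL,
    spectrum_background = if (!is.null(spectrum))
      as.list(spectrum$backgroundProportions) else NULL,
    common_density_ratio = if (!is.null(spectrum))
      unname(spectrum$densityRatio["common"]) else NULL,
    suitability_p = suit$p)
  list(spectrum = spectrum, rankTest = rankTest, suitability = suit,
       counts = counts)
}

#' Run the full annotation pipeline
#'
#' Executes the four stages in order — accessibility/mark annotation, target
#' assignment, variant prioritization, constraint statistics — and returns a
#' [RunReport-class]. Identical inputs and config give an identical report.
#' With `outdir` set, per-stage TSV artifacts and the JSON report are
#' written.
#'
#' @param bundle a `SimBundle` (from [simulateBundle()],
#'   [workedExampleBundle()] or [loadBundle()]).
#' @param config a [pipelineConfig()].
#' @param outdir optional artifact directory.
#' @return A [RunReport-class].
#' @export
runPipeline <- function(bundle, config = pipelineConfig(), outdir = NULL) {
  ov <- setdiff(attr(config, "overrides"), "seed")
  if (length(ov))
    message("config overrides: ", paste(ov, collapse = ", "))
  ann <- stageAnnotate(bundle, config)
  tgt <- stageTargets(bundle, config, ann)
  vr <- stageVariants(bundle, config, ann, tgt)
  cs <- stageConstraint(bundle, config, ann, tgt)
  report <- new("RunReport", data = list(
    annotate = ann$counts,
    targets = tgt$counts,
    variants = vr$counts,
    constraint = cs$counts,
    vista = if (!is.null(ann$vista)) {
      s <- ann$vista$summary
      lapply(split(s, s$set), function(r)
        list(overlapped = r$overlapped, positive = r$positive,
             proportion = r$proportion, defined = r$defined))
    } else NULL,
    provenance = list(seed = config$seed, config_hash = .hashConfig(config))))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.table(profileTable(ann$profiles),
                file.path(outdir, "profiles.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(as.data.frame(ann$markCounts),
                file.path(outdir, "mark_counts.tsv"), sep = "\t",
                quote = FALSE)
    write.table(tgt$expressedEdges, file.path(outdir, "edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(vr$hits, file.path(outdir, "hits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(vr$searchSpace$hits, file.path(outdir, "search_space.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeRunReport(report, file.path(outdir, "report.json"))
  }
  report
}
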