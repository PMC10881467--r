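#' Simulation configuration for the synthetic input generator
#'
#' The defaults encode the study conditions at desk scale: about one third of
#' elements open in the tissue, a nested fraction carrying histone marks, a
#' small fraction with the active-enhancer mark and a sliver sustaining it at
#' adult stage (0.34 / 0.19 / 0.026 / 0.0076, the observed proportions of the
#' element catalogue), common-variant depletion `ucneCommonDepletion` inside
#' elements, and a constraint-score location shift `constraintShift` (full
#' inside elements, half in their flanks).
#'
#' @param seed integer master seed; fans out to per-component substreams so
#'   components can be regenerated independently.
#' @param nChroms,chromLength genome shape.
#' @param nGenes,nUcnes counts over the whole genome.
#' @param fracOpen,fracMarked,fracActive,fracAdultSustained nested fractions
#'   of elements planted at each evidence tier (each tier a subset of the
#'   previous).
#' @param devStages,adultStage,dnaseStages,clusters,exprStages label
#'   vocabularies.
#' @param tadMeanSize mean TAD width in bp.
#' @param tpmHigh,tpmLow expression levels for planted expressed /
#'   non-expressed genes (TPM).
#' @param variantRates per-bp variant rates per frequency bin.
#' @param ucneCommonDepletion multiplier `d` on the common-variant rate
#'   inside elements (1 = no depletion).
#' @param constraintShift location shift `delta` subtracted from the
#'   standard-normal constraint score inside elements (`delta/2` in flanks).
#' @param backgroundPeakRate accessibility/mark background peaks per Mb per
#'   track (0 = noise-free).
#' @param exprFrac fraction of target genes planted as retina-expressed.
#' @param concFrac fraction of open elements planted concordant with their
#'   targets' expression signatures.
#' @param unsolvedFrac fraction of variant carriers from unsolved cases.
#' @param meanCarriers mean carriers per cohort variant.
#' @param nSv number of large structural variants.
#' @param diseaseFrac fraction of expressed target genes listed as disease
#'   genes.
#' @param nFragments,fragmentLength random background fragment count and width.
#' @param flank constraint flank width in bp.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L, nChroms = 2L, chromLength = 2.5e6,
    nGenes = 60L, nUcnes = 150L,
    fracOpen = 0.34, fracMarked = 0.19, fracActive = 0.026,
    fracAdultSustained = 0.0076,
    devStages = c("FW13/14", "FW15/16", "FW18/20", "FW23/24"),
    adultStage = "adult",
    dnaseStages = c("ED74-85", "ED89", "ED103-125"),
    clusters = c("EarlyRPC", "LateRPC", "GanglionPrecursors",
                 "PhotoreceptorPrecursors", "AmacrineHorizontal", "Rods",
                 "Cones", "BipolarCells", "MullerGlia"),
    exprStages = c("D52", "D67", "D80", "D94", "D107", "D125", "D136"),
    tadMeanSize = 4e5, tpmHigh = 30, tpmLow = 0.1,
    variantRates = c(ultrarare = 0.004, very_rare = 0.003, rare = 0.002,
                     low_frequency = 0.003, common = 0.006),
    ucneCommonDepletion = 0.2, constraintShift = 0.5,
    backgroundPeakRate = 3, exprFrac = 0.85, concFrac = 0.55,
    unsolvedFrac = 0.56, meanCarriers = 1.5, nSv = 4L, diseaseFrac = 0.08,
    nFragments = 200L, fragmentLength = 350L, flank = 200L) {
  cfg <- as.list(environment())
  with(cfg, {
    if (!(fracOpen >= fracMarked && fracMarked >= fracActive &&
          fracActive >= fracAdultSustained))
      stop("fractions must be nested: open >= marked >= active >= sustained")
    if (any(c(fracOpen, fracAdultSustained) < 0) || fracOpen > 1)
      stop("fractions must lie in [0,1]")
    if (any(variantRates < 0) || backgroundPeakRate < 0)
      stop("rates must be >= 0")
    if (ucneCommonDepletion < 0 || ucneCommonDepletion > 1)
      stop("ucneCommonDepletion must be in [0,1]")
    if (constraintShift < 0) stop("constraintShift must be >= 0")
  })
  structure(cfg, class = "SimulationConfig")
}

## Deterministic substream seeding so components can be regenerated alone.
.substream <- function(seed, k) {
  set.seed((as.numeric(seed) * 1009 + k * 9973) %% 2147483629)
}

## Place n points on [margin, len - margin] with guaranteed spacing:
## evenly spaced slots with bounded jitter.
.placeSpaced <- function(len, n, margin, jitter) {
  slots <- seq(margin, len - margin, length.out = n)
  round(slots + runif(n, -jitter, jitter))
}

## Rejection-sample n non-overlapping intervals avoiding `forbidden`
## (matrix with columns start0, end0) with minimum separation `sep`.
.placeAvoiding <- function(len, n, widths, forbidden, sep) {
  placed <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(placed) < n) {
    if (tries > 500L * n) stop("could not place ", n, " intervals")
    s <- floor(runif(1) * (len - widths[nrow(placed) + 1L] - 2 * sep)) + sep
    e <- s + widths[nrow(placed) + 1L]
    okF <- !nrow(forbidden) || all(e + sep <= forbidden[, 1] |
                                     s - sep >= forbidden[, 2])
    okP <- !nrow(placed) || all(e + sep <= placed[, 1] | s - sep >= placed[, 2])
    if (okF && okP) placed <- rbind(placed, c(s, e))
    tries <- tries + 1L
  }
  placed[order(placed[, 1]), , drop = FALSE]
}

## Independent re-derivation of the basal-plus-extension rule used to plant
## truth edges (kept local to the generator).
.truthDomainSpan <- function(t0, str, chromOf, sl, up, down, maxExt) {
  bs <- ifelse(str == "+", t0 - up, t0 - down + 1)
  be <- ifelse(str == "+", t0 + down, t0 + up + 1)
  bs <- pmax(0, bs); be <- pmin(sl[chromOf], be)
  n <- length(t0)
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    j <- setdiff(which(chromOf == chromOf[i]), i)
    lo <- bs[i] - maxExt
    hi <- be[i] + maxExt
    if (length(j)) {
      below <- be[j][be[j] <= bs[i]]
      if (length(below)) lo <- max(lo, max(below))
      if (any(bs[j] < bs[i] & be[j] > bs[i])) lo <- bs[i]
      above <- bs[j][bs[j] >= be[i]]
      if (length(above)) hi <- min(hi, min(above))
      if (any(bs[j] < be[i] & be[j] > be[i])) hi <- be[i]
    }
    out[i, ] <- c(max(0, lo), min(sl[chromOf[i]], hi))
  }
  out
}

#' Generate a synthetic input bundle with a planted truth table
#'
#' Emulates the statistical structure of the real inputs: elements enriched
#' for accessibility, stage- and cluster-structured peaks, expressed target
#' genes sharing TADs with their elements, common-variant depletion inside
#' elements, and lowered constraint scores in elements and their flanks. All
#' planting decisions are recorded in the returned `truth` component.
#'
#' Because every component draws from its own seeded substream, a subset of
#' components can be regenerated alone (`components`) and is identical to the
#' corresponding part of the full bundle.
#'
#' @param config a [simulationConfig()].
#' @param components `"full"`, or a subset of `c("regions", "variants",
#'   "constraint")` to generate only the genome layout, the variant table, or
#'   the background/constraint material.
#' @return A list of class `SimBundle` with components `assembly`, `ucnes`,
#'   `genes`, `dnase`, `scatac`, `chip` (lists of [trackBundle()]s), `tads`,
#'   `stageExpr`, `clusterExpr`, `linkages`, `variants`, `background`,
#'   `constraint`, `diseaseTable`, `truth` and `config` (partial bundles omit
#'   what they did not generate).
#' @export
simulateBundle <- function(config = simulationConfig(), components = "full") {
  stopifnot(inherits(config, "SimulationConfig"))
  full <- identical(components, "full")
  wantVariants <- full || "variants" %in% components
  wantConstraint <- full || "constraint" %in% components
  cfg <- config
  assembly <- genomeAssembly(paste0("chr", seq_len(cfg$nChroms)),
                             rep(cfg$chromLength, cfg$nChroms))
  sl <- seqlengths(assembly)

  ## --- genes -------------------------------------------------------------
  .substream(cfg$seed, 1)
  perChrom <- diff(round(seq(0, cfg$nGenes, length.out = cfg$nChroms + 1)))
  gChrom <- rep(names(sl), perChrom)
  gTss <- unlist(lapply(seq_len(cfg$nChroms), function(c) {
    .placeSpaced(sl[c], perChrom[c], margin = 60000, jitter = 6000)
  }), use.names = FALSE)
  gStrand <- sample(c("+", "-"), cfg$nGenes, replace = TRUE)
  genes <- GRanges(gChrom, IRanges(gTss + 1, gTss + 1), strand = gStrand,
                   seqinfo = assembly)
  mcols(genes)$gene_id <- sprintf("GENE%03d", seq_len(cfg$nGenes))

  ## --- elements ----------------------------------------------------------
  .substream(cfg$seed, 2)
  perChromU <- diff(round(seq(0, cfg$nUcnes, length.out = cfg$nChroms + 1)))
  uList <- lapply(seq_len(cfg$nChroms), function(c) {
    sel <- gChrom == names(sl)[c]
    forb <- cbind(gTss[sel] - 6200, gTss[sel] + 6200)
    w <- sample(250:600, perChromU[c], replace = TRUE)
    pos <- .placeAvoiding(sl[c], perChromU[c], w, forb, sep = 800)
    GRanges(names(sl)[c], IRanges(pos[, 1] + 1, pos[, 2]), seqinfo = assembly)
  })
  ucnes <- sortIntervals(do.call(c, uList))
  mcols(ucnes)$name <- sprintf("ucne_%03d", seq_along(ucnes))
  uNames <- mcols(ucnes)$name

  dnase <- list(); scatac <- list(); chip <- list()
  stageExpr <- NULL; clusterExpr <- NULL; linkages <- NULL; tads <- NULL
  diseaseTable <- NULL; truth <- NULL; variants <- NULL; vista <- NULL
  flanks <- NULL; background <- NULL; constraint <- NULL

  if (full) {

  ## --- truth edges (independent basal-plus-extension re-derivation) ------
  dom <- .truthDomainSpan(gTss, gStrand, gChrom, sl, 5000, 1000, 1e6)
  edgeRows <- list()
  for (i in seq_along(ucnes)) {
    us <- start(ucnes)[i] - 1; ue <- end(ucnes)[i]
    j <- which(gChrom == as.character(seqnames(ucnes))[i] &
                 dom[, 1] < ue & dom[, 2] > us)
    if (length(j))
      edgeRows[[length(edgeRows) + 1L]] <-
        data.frame(ucne = uNames[i], gene = mcols(genes)$gene_id[j])
  }
  truthEdges <- if (length(edgeRows)) do.call(rbind, edgeRows) else
    data.frame(ucne = character(0), gene = character(0))

  ## --- expression and signatures -----------------------------------------
  .substream(cfg$seed, 3)
  gid <- mcols(genes)$gene_id
  isTarget <- gid %in% truthEdges$gene
  expressed <- ifelse(isTarget, runif(cfg$nGenes) < cfg$exprFrac,
                      runif(cfg$nGenes) < 0.7)
  stageExpr <- matrix(0, cfg$nGenes, length(cfg$exprStages),
                      dimnames = list(gid, cfg$exprStages))
  for (i in seq_len(cfg$nGenes)) {
    if (expressed[i]) {
      hi <- sample(length(cfg$exprStages), sample(1:3, 1))
      stageExpr[i, ] <- cfg$tpmLow
      stageExpr[i, hi] <- cfg$tpmHigh * runif(length(hi), 0.5, 1.5)
    } else {
      stageExpr[i, ] <- runif(length(cfg$exprStages), 0, 0.4)
    }
  }
  nCl <- length(cfg$clusters)
  clusterExpr <- matrix(0, cfg$nGenes, nCl, dimnames = list(gid, cfg$clusters))
  sigList <- vector("list", cfg$nGenes)
  for (i in seq_len(cfg$nGenes)) {
    k <- sample(1:2, 1)
    sig <- sample(cfg$clusters, k)
    clusterExpr[i, sig] <- 10
    sigList[[i]] <- sort(sig)
  }
  names(sigList) <- gid

  ## --- planted element states --------------------------------------------
  .substream(cfg$seed, 4)
  nOpen <- round(cfg$fracOpen * cfg$nUcnes)
  nMarked <- round(cfg$fracMarked * cfg$nUcnes)
  nActive <- round(cfg$fracActive * cfg$nUcnes)
  nSustained <- max(1L, round(cfg$fracAdultSustained * cfg$nUcnes))
  openIdx <- sort(sample(seq_len(cfg$nUcnes), nOpen))
  markedIdx <- sort(sample(openIdx, nMarked))
  activeIdx <- sort(sample(markedIdx, nActive))
  sustainedIdx <- sort(sample(activeIdx, nSustained))

  clusterStage <- setNames(rep(c("ED53", "ED59", "ED74", "ED78", "ED113",
                                 "ED132"), length.out = nCl), cfg$clusters)
  exprByGene <- setNames(expressed, gid)
  scCluster <- vector("list", cfg$nUcnes)   # clusters with open chromatin
  dnStages <- vector("list", cfg$nUcnes)
  truthConc <- rep(NA, cfg$nUcnes)
  truthHC <- rep(FALSE, cfg$nUcnes)
  for (i in openIdx) {
    tg <- truthEdges$gene[truthEdges$ucne == uNames[i]]
    tgExpr <- tg[exprByGene[tg]]
    sigUnion <- unique(unlist(sigList[tgExpr], use.names = FALSE))
    hasSc <- runif(1) < 0.9
    hasDn <- runif(1) < 0.5
    if (!hasSc && !hasDn) hasSc <- TRUE
    if (hasSc) {
      wantConc <- runif(1) < cfg$concFrac && length(sigUnion)
      pool <- if (wantConc) sigUnion else setdiff(cfg$clusters, sigUnion)
      if (!length(pool)) pool <- sigUnion
      scCluster[[i]] <- sample(pool, 1)
    } else scCluster[[i]] <- character(0)
    dnStages[[i]] <- if (hasDn) sample(cfg$dnaseStages, sample(1:2, 1)) else character(0)
    truthConc[i] <- length(intersect(scCluster[[i]], sigUnion)) > 0
    truthHC[i] <- hasSc && hasDn
  }

  ## --- planted marks ------------------------------------------------------
  .substream(cfg$seed, 5)
  otherMarks <- setdiff(ucneMarkVocabulary(), "H3K27ac")
  markTags <- vector("list", cfg$nUcnes)
  for (i in seq_len(cfg$nUcnes)) markTags[[i]] <- character(0)
  for (i in markedIdx) {
    mk <- sample(otherMarks, sample(1:3, 1))
    for (m in mk) {
      st <- sample(cfg$devStages, sample(1:2, 1))
      markTags[[i]] <- union(markTags[[i]], paste0(m, "::", st))
    }
  }
  for (i in activeIdx) {
    st <- sample(cfg$devStages, sample(1:2, 1))
    markTags[[i]] <- union(markTags[[i]], paste0("H3K27ac::", st))
    if (runif(1) < 0.95 &&
        !any(grepl("^H3K4me[12]::", markTags[[i]]))) {
      m <- sample(c("H3K4me1", "H3K4me2"), 1)
      markTags[[i]] <- union(markTags[[i]],
                             paste0(m, "::", sample(cfg$devStages, 1)))
    }
  }
  for (i in sustainedIdx)
    markTags[[i]] <- union(markTags[[i]], paste0("H3K27ac::", cfg$adultStage))

  truthState <- rep("none", cfg$nUcnes)
  truthState[openIdx] <- "open_only"
  truthState[markedIdx] <- "marked"
  truthState[activeIdx] <- "active_enhancer"
  truthState[sustainedIdx] <- "sustained_adult"

  ## --- accessibility and mark tracks -------------------------------------
  .substream(cfg$seed, 6)
  genomeMb <- sum(sl) / 1e6
  avoid <- cbind(start(ucnes) - 1 - 600, end(ucnes) + 600)
  avoidByChrom <- split(seq_along(ucnes), as.character(seqnames(ucnes)))
  sampleBgPeaks <- function(nPk, w) {
    if (nPk == 0) return(GRanges(seqinfo = assembly))
    chs <- character(0); sts <- numeric(0)
    guard <- 0L
    while (length(sts) < nPk && guard < 60L) {
      k <- 2L * (nPk - length(sts))
      ch <- sample(names(sl), k, replace = TRUE, prob = sl / sum(sl))
      s <- floor(runif(k) * (sl[ch] - w - 1200)) + 600
      ok <- vapply(seq_len(k), function(i) {
        rows <- avoidByChrom[[ch[i]]]
        is.null(rows) || all(s[i] + w <= avoid[rows, 1] |
                               s[i] >= avoid[rows, 2])
      }, logical(1))
      chs <- c(chs, ch[ok]); sts <- c(sts, s[ok])
      guard <- guard + 1L
    }
    if (!length(sts)) return(GRanges(seqinfo = assembly))
    if (length(sts) > nPk) { chs <- chs[seq_len(nPk)]; sts <- sts[seq_len(nPk)] }
    GRanges(chs, IRanges(sts + 1, sts + w), seqinfo = assembly)
  }

  scatac <- list()
  for (cl in cfg$clusters) {
    members <- which(vapply(scCluster, function(x) cl %in% x, logical(1)))
    pk <- if (length(members))
      GRanges(seqnames(ucnes)[members],
              IRanges(pmax(1, start(ucnes)[members] - 50),
                      pmin(sl[as.character(seqnames(ucnes)[members])],
                           end(ucnes)[members] + 50)),
              seqinfo = assembly) else GRanges(seqinfo = assembly)
    bg <- sampleBgPeaks(rpois(1, cfg$backgroundPeakRate * genomeMb), 300)
    all <- c(pk, bg)
    vals <- c(rep(1.0, length(pk)), runif(length(bg), 0.5, 2))
    scatac[[cl]] <- trackBundle(flattenToTrack(all, vals, assembly),
                                cluster = cl, stage = clusterStage[cl])
  }

  dnase <- list()
  for (stg in cfg$dnaseStages) {
    members <- which(vapply(dnStages, function(x) stg %in% x, logical(1)))
    pk <- if (length(members))
      GRanges(seqnames(ucnes)[members],
              IRanges(pmax(1, start(ucnes)[members] - 40),
                      pmin(sl[as.character(seqnames(ucnes)[members])],
                           end(ucnes)[members] + 40)),
              seqinfo = assembly) else GRanges(seqinfo = assembly)
    lab <- rep("High-DNase", length(pk))
    bg <- sampleBgPeaks(rpois(1, cfg$backgroundPeakRate * genomeMb), 300)
    labBg <- sample(c("High-DNase", "Low-DNase"), length(bg), replace = TRUE,
                    prob = c(0.7, 0.3))
    if (cfg$backgroundPeakRate > 0) {
      ## a few low-signal elements sitting right on closed elements, so the
      ## low-signal filter is load-bearing
      closed <- setdiff(seq_len(cfg$nUcnes), openIdx)
      lowOn <- head(closed, 2)
      if (length(lowOn)) {
        bg <- c(bg, granges(ucnes[lowOn]))
        labBg <- c(labBg, rep("Low-DNase", length(lowOn)))
      }
    }
    peaks <- c(pk, bg)
    mcols(peaks)$name <- c(lab, labBg)
    dnase[[stg]] <- trackBundle(peaks, stage = stg)
  }

  chip <- list()
  allTags <- unique(unlist(markTags, use.names = FALSE))
  allStages <- c(cfg$devStages, cfg$adultStage)
  for (m in ucneMarkVocabulary()) for (stg in allStages) {
    tag <- paste0(m, "::", stg)
    members <- which(vapply(markTags, function(x) tag %in% x, logical(1)))
    if (!length(members) && !(tag %in% allTags) && cfg$backgroundPeakRate == 0)
      next
    pk <- if (length(members))
      GRanges(seqnames(ucnes)[members],
              IRanges(pmax(1, start(ucnes)[members] - 100),
                      pmin(sl[as.character(seqnames(ucnes)[members])],
                           end(ucnes)[members] + 100)),
              seqinfo = assembly) else GRanges(seqinfo = assembly)
    bg <- sampleBgPeaks(rpois(1, cfg$backgroundPeakRate * genomeMb / 4), 300)
    if (!length(pk) && !length(bg)) next
    all <- c(pk, bg)
    vals <- c(runif(length(pk), 24, 45), runif(length(bg), 21, 40))
    chip[[tag]] <- trackBundle(flattenToTrack(all, vals, assembly),
                               mark = m, stage = stg)
  }

  ## --- TADs ---------------------------------------------------------------
  .substream(cfg$seed, 7)
  tadList <- lapply(names(sl), function(ch) {
    bounds <- 0
    while (tail(bounds, 1) < sl[ch]) {
      sz <- max(5e4, min(1e6, round(rexp(1, 1 / cfg$tadMeanSize))))
      bounds <- c(bounds, tail(bounds, 1) + sz)
    }
    bounds[length(bounds)] <- sl[ch]
    GRanges(ch, IRanges(head(bounds, -1) + 1, bounds[-1]), seqinfo = assembly)
  })
  tads <- do.call(c, tadList)
  mcols(tads)$name <- sprintf("tad_%d", seq_along(tads))

  uTad <- as(findOverlaps(ucnes, tads, minoverlap = 1L), "List")
  gTad <- as(findOverlaps(genes, tads), "List")
  gidIdx <- setNames(seq_along(gid), gid)
  uIdxByName <- setNames(seq_along(uNames), uNames)
  truthEdges$tad_shared <- vapply(seq_len(nrow(truthEdges)), function(k) {
    length(intersect(uTad[[uIdxByName[truthEdges$ucne[k]]]],
                     gTad[[gidIdx[truthEdges$gene[k]]]])) > 0
  }, logical(1))
  truthEdges$expressed <- exprByGene[truthEdges$gene]

  ## --- disease table ------------------------------------------------------
  .substream(cfg$seed, 8)
  exprTargets <- unique(truthEdges$gene[truthEdges$expressed])
  nDz <- max(3L, round(cfg$diseaseFrac * length(exprTargets)))
  dzGenes <- sort(sample(exprTargets, min(nDz, length(exprTargets))))
  extra <- head(setdiff(gid, unique(truthEdges$gene)), 2)
  diseaseTable <- data.frame(
    gene = c(dzGenes, extra),
    panel = rep(c("Eye", "DD"), length.out = length(dzGenes) + length(extra)),
    phenotype = rep(c("retinal dystrophy", "ocular malformation",
                      "developmental disorder"),
                    length.out = length(dzGenes) + length(extra)))

  ## --- peak-to-gene linkages ---------------------------------------------
  .substream(cfg$seed, 9)
  linkRows <- list()
  for (i in openIdx) {
    if (runif(1) > 0.5) next
    tg <- truthEdges$gene[truthEdges$ucne == uNames[i]]
    gLink <- if (length(tg) && runif(1) < 0.6) sample(tg, 1) else sample(gid, 1)
    corr <- if (runif(1) < 0.8) runif(1, 0.45, 0.9) else runif(1, 0.1, 0.4)
    linkRows[[length(linkRows) + 1L]] <- data.frame(
      chrom = as.character(seqnames(ucnes))[i],
      start = start(ucnes)[i] - 1, end = end(ucnes)[i],
      gene = gLink, correlation = corr)
  }
  linkages <- if (length(linkRows)) {
    df <- do.call(rbind, linkRows)
    gr <- GRanges(df$chrom, IRanges(df$start + 1, df$end), seqinfo = assembly)
    mcols(gr)$gene <- df$gene
    mcols(gr)$correlation <- df$correlation
    gr
  } else {
    gr <- GRanges(seqinfo = assembly)
    mcols(gr)$gene <- character(0)
    mcols(gr)$correlation <- numeric(0)
    gr
  }

  ## --- validated-enhancer label table -------------------------------------
  .substream(cfg$seed, 13)
  tisVocab <- c("eye", "forebrain", "hindbrain", "midbrain", "neural tube",
                "limb", "tail")
  vsIdx <- sort(sample(openIdx, max(1L, round(0.3 * length(openIdx)))))
  vsU <- GRanges(seqnames(ucnes)[vsIdx],
                 IRanges(pmax(1, start(ucnes)[vsIdx] - 200),
                         pmin(sl[as.character(seqnames(ucnes)[vsIdx])],
                              end(ucnes)[vsIdx] + 200)),
                 seqinfo = assembly)
  posU <- runif(length(vsU)) < 0.68
  nBgV <- 20L
  bgCh <- sample(names(sl), nBgV, replace = TRUE)
  bgS <- floor(runif(nBgV) * (sl[bgCh] - 1500)) + 1
  vsB <- GRanges(bgCh, IRanges(bgS, bgS + 999), seqinfo = assembly)
  posB <- runif(nBgV) < 0.5
  vista <- c(vsU, vsB)
  lab <- ifelse(c(posU, posB), "positive", "negative")
  tis <- lapply(lab, function(l) {
    if (l == "positive") sort(sample(tisVocab, sample(1:3, 1))) else character(0)
  })
  mcols(vista)$label <- lab
  mcols(vista)$tissues <- CharacterList(tis)

  truth <- list(
    perUcne = data.frame(
      ucne = uNames, state = truthState,
      open = truthState != "none",
      high_confidence = truthHC,
      clusters = vapply(scCluster, function(x) paste(sort(x), collapse = ","), ""),
      dnase_stages = vapply(dnStages, function(x) paste(sort(x), collapse = ","), ""),
      marks = vapply(markTags, function(x) paste(sort(x), collapse = ","), ""),
      concordant = truthConc),
    edges = truthEdges,
    signatures = sigList,
    expressed = exprByGene,
    diseaseGenes = dzGenes)

  }  # end full

  if (wantVariants) {

  if (!full) {
    ## replay the first draw of the state substream to recover the planted
    ## open subset (needed for SV placement) without the rest of the bundle
    .substream(cfg$seed, 4)
    openIdx <- sort(sample(seq_len(cfg$nUcnes),
                           round(cfg$fracOpen * cfg$nUcnes)))
  }

  ## --- variants -----------------------------------------------------------
  .substream(cfg$seed, 10)
  bins <- names(cfg$variantRates)
  vRows <- list()
  nt <- c("A", "C", "G", "T")
  for (ch in names(sl)) {
    for (b in bins) {
      nv <- rpois(1, cfg$variantRates[[b]] * sl[ch])
      if (!nv) next
      pos0 <- floor(runif(nv) * sl[ch])
      vRows[[length(vRows) + 1L]] <- data.frame(chrom = ch, pos0 = pos0, bin = b)
    }
  }
  vdf <- do.call(rbind, vRows)
  vgr0 <- GRanges(vdf$chrom, IRanges(vdf$pos0 + 1, vdf$pos0 + 1),
                  seqinfo = assembly)
  inU <- overlapsAny(vgr0, ucnes, ignore.strand = TRUE)
  drop <- vdf$bin == "common" & inU &
    runif(nrow(vdf)) >= cfg$ucneCommonDepletion
  vdf <- vdf[!drop, , drop = FALSE]
  n <- nrow(vdf)
  vdf$af <- 0
  vdf$observed <- vdf$bin != "ultrarare"
  vdf$af[vdf$bin == "very_rare"] <- runif(sum(vdf$bin == "very_rare"), 1e-5, 9.99e-4)
  vdf$af[vdf$bin == "rare"] <- runif(sum(vdf$bin == "rare"), 1e-3, 4.99e-3)
  vdf$af[vdf$bin == "low_frequency"] <- runif(sum(vdf$bin == "low_frequency"), 5e-3, 4.99e-2)
  vdf$af[vdf$bin == "common"] <- runif(sum(vdf$bin == "common"), 0.05, 0.5)
  vdf$n_hom <- 0L
  vdf$n_hom[vdf$bin == "rare"] <- rbinom(sum(vdf$bin == "rare"), 1, 0.25)
  vdf$n_hom[vdf$bin == "low_frequency"] <- rpois(sum(vdf$bin == "low_frequency"), 1)
  vdf$n_hom[vdf$bin == "common"] <- rpois(sum(vdf$bin == "common"), 5) + 1L
  ref <- sample(nt, n, replace = TRUE)
  alt <- nt[(match(ref, nt) - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L]
  variants <- GRanges(vdf$chrom, IRanges(vdf$pos0 + 1, vdf$pos0 + 1),
                      seqinfo = assembly)
  mcols(variants)$id <- sprintf("var_%05d", seq_len(n))
  mcols(variants)$ref <- ref
  mcols(variants)$alt <- alt
  mcols(variants)$svtype <- NA_character_
  mcols(variants)$af <- vdf$af
  mcols(variants)$observed <- vdf$observed
  mcols(variants)$n_hom <- vdf$n_hom

  if (cfg$nSv > 0) {
    svOn <- sample(openIdx, min(ceiling(cfg$nSv / 2), length(openIdx)))
    svRows <- list()
    for (i in svOn) {
      w <- round(runif(1, 2e4, 1e5))
      ch <- as.character(seqnames(ucnes))[i]
      s <- max(1, start(ucnes)[i] - round(w / 2))
      svRows[[length(svRows) + 1L]] <- c(ch, s, min(sl[ch], s + w))
    }
    for (k in seq_len(cfg$nSv - length(svOn))) {
      ch <- sample(names(sl), 1)
      w <- round(runif(1, 2e4, 1e5))
      s <- floor(runif(1) * (sl[ch] - w)) + 1
      svRows[[length(svRows) + 1L]] <- c(ch, s, s + w)
    }
    svGr <- GRanges(vapply(svRows, `[`, "", 1),
                    IRanges(as.numeric(vapply(svRows, `[`, "", 2)),
                            as.numeric(vapply(svRows, `[`, "", 3))),
                    seqinfo = assembly)
    mcols(svGr)$id <- sprintf("sv_%02d", seq_along(svGr))
    mcols(svGr)$ref <- "N"
    mcols(svGr)$alt <- "<SV>"
    mcols(svGr)$svtype <- sample(c("DUP", "DEL"), length(svGr), replace = TRUE)
    mcols(svGr)$af <- 0
    mcols(svGr)$observed <- FALSE
    mcols(svGr)$n_hom <- 0L
    variants <- c(variants, svGr)
  }
  nAll <- length(variants)
  mcols(variants)$n_carriers <- 1L + rpois(nAll, cfg$meanCarriers - 1)
  mcols(variants)$in_unsolved <- runif(nAll) < cfg$unsolvedFrac

  }  # end variants

  if (wantConstraint || wantVariants) {

  ## --- background fragments and constraint track --------------------------
  flanks <- buildFlanks(ucnes, cfg$flank)
  background <- sampleFragments(assembly, cfg$nFragments, cfg$fragmentLength,
                                exclude = c(granges(ucnes), flanks),
                                seed = (cfg$seed * 1009 + 11 * 9973) %% 2147483629)
  .substream(cfg$seed, 12)
  uBody <- reduce(granges(ucnes), ignore.strand = TRUE)
  bgBody <- setdiff(reduce(granges(background), ignore.strand = TRUE),
                    c(uBody, flanks), ignore.strand = TRUE)
  regs <- c(uBody, flanks, bgBody)
  shift <- c(rep(-cfg$constraintShift, length(uBody)),
             rep(-cfg$constraintShift / 2, length(flanks)),
             rep(0, length(bgBody)))
  w <- width(regs)
  starts <- sequence(w) + rep(start(regs) - 1L, w)
  chromPB <- rep(as.character(seqnames(regs)), w)
  vals <- rnorm(sum(w)) + rep(shift, w)
  cgr <- GRanges(chromPB, IRanges(starts, starts), seqinfo = assembly)
  mcols(cgr)$score <- vals
  constraint <- signalTrack(cgr)

  }  # end constraint

  structure(list(assembly = assembly, ucnes = ucnes, genes = genes,
                 dnase = dnase, scatac = scatac, chip = chip, tads = tads,
                 stageExpr = stageExpr, clusterExpr = clusterExpr,
                 linkages = linkages, variants = variants, vista = vista,
                 background = background, constraint = constraint,
                 diseaseTable = diseaseTable, truth = truth, config = cfg),
            class = "SimBundle")
}
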