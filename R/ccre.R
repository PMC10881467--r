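#' Default histone-mark vocabulary
#'
#' The ten ChIP-seq tracks assessed around accessible elements. The first
#' five (plus PolII binding) are associated with active or poised regulatory
#' chromatin; H3K27me3 and H3K9me3 mark repressed chromatin.
#'
#' @return Character vector of mark labels.
#' @export
ucneMarkVocabulary <- function() {
  c("H3K27ac", "H3K27me3", "H3K36me3", "H3K4me1", "H3K4me2", "H3K4me3",
    "H3K9/14Ac", "H3K9me3", "PolII", "CTCF")
}

#' Marks counted as activating for the activating-only feature tally
#' @return Character vector of mark labels.
#' @export
activatingMarks <- function() {
  c("H3K27ac", "H3K4me1", "H3K4me2", "H3K4me3", "H3K9/14Ac", "PolII")
}

.enhancerStateLevels <- c("none", "open_only", "marked", "active_enhancer",
                          "sustained_adult")

#' Bundle a peak set or signal track with its biological labels
#'
#' @param payload a `GRanges` of peaks or a [SignalTrack-class].
#' @param stage developmental stage label (e.g. `"FW13/14"`).
#' @param cluster cell-cluster label (single-cell accessibility bundles).
#' @param mark histone-mark label (ChIP-seq bundles).
#' @param label free-text label.
#' @return A list of class `TrackBundle`.
#' @export
trackBundle <- function(payload, stage = NA_character_, cluster = NA_character_,
                        mark = NA_character_, label = NA_character_) {
  if (!(is(payload, "GRanges") || is(payload, "SignalTrack")))
    stop("payload must be a GRanges or SignalTrack")
  structure(list(payload = payload, stage = stage, cluster = cluster,
                 mark = mark, label = label), class = "TrackBundle")
}

#' UcneProfiles: per-element regulatory evidence
#'
#' One row per queried ultraconserved element, recording which accessibility
#' sources (DNase stages; single-cell clusters with their stage) and which
#' histone marks (per stage, window evidence) support it, plus the derived
#' enhancer state.
#'
#' @slot ucnes the elements as a `GRanges` with a `name` column.
#' @slot dnaseStages per-element DNase stages with an overlap.
#' @slot scatacHits per-element `"cluster::stage"` accessibility evidence.
#' @slot marks per-element `"mark::stage"` window evidence.
#' @slot state per-element enhancer state, ordered
#'   `none < open_only < marked < active_enhancer < sustained_adult`.
#' @export
setClass("UcneProfiles",
         representation(ucnes = "GRanges", dnaseStages = "CharacterList",
                        scatacHits = "CharacterList", marks = "CharacterList",
                        state = "factor"))

setValidity("UcneProfiles", function(object) {
  n <- length(object@ucnes)
  if (is.null(mcols(object@ucnes)$name)) return("ucnes need a 'name' column")
  if (length(object@dnaseStages) != n || length(object@scatacHits) != n ||
      length(object@marks) != n || length(object@state) != n)
    return("profile slots must be parallel to ucnes")
  if (!identical(levels(object@state), .enhancerStateLevels))
    return("state must use the enhancer-state levels")
  TRUE
})

setMethod("show", "UcneProfiles", function(object) {
  cat("UcneProfiles for", length(object@ucnes), "elements\n")
  print(table(object@state))
})

#' @describeIn UcneProfiles-class the elements as a `GRanges`.
#' @param x a `UcneProfiles`.
#' @export
ucnes <- function(x) x@ucnes

#' @describeIn UcneProfiles-class logical: element overlaps at least one
#'   accessibility peak (either source).
#' @export
isOpen <- function(x) lengths(x@dnaseStages) + lengths(x@scatacHits) > 0

#' @describeIn UcneProfiles-class logical: element supported by both DNase
#'   and single-cell accessibility.
#' @export
isHighConfidence <- function(x) {
  lengths(x@dnaseStages) > 0 & lengths(x@scatacHits) > 0
}

#' @describeIn UcneProfiles-class per-element enhancer state (ordered factor).
#' @export
enhancerState <- function(x) x@state

#' @describeIn UcneProfiles-class per-element cell clusters with open
#'   chromatin (a `CharacterList`).
#' @export
openClusters <- function(x) {
  CharacterList(lapply(x@scatacHits, function(h) {
    unique(sub("::.*$", "", h))
  }))
}

#' @describeIn UcneProfiles-class per-element histone marks present at any
#'   stage (a `CharacterList`).
#' @export
markNames <- function(x) {
  CharacterList(lapply(x@marks, function(h) unique(sub("::.*$", "", h))))
}

#' Identify putatively active elements from accessibility evidence
#'
#' An element counts as putatively active when it overlaps (>= 1 bp) at
#' least one DNase peak or one single-cell accessibility peak at any
#' stage/cluster; evidence from either source alone suffices, and the
#' high-confidence subset supported by both sources is recorded separately
#' (see [isHighConfidence()]).
#'
#' @param ucneSet `GRanges` of elements with a `name` column.
#' @param dnase list of [trackBundle()]s with `stage` set and peak `GRanges`
#'   payloads.
#' @param scatac list of [trackBundle()]s with `cluster` (and `stage`) set.
#' @return A [UcneProfiles-class]; elements with no overlap keep state
#'   `none` and are excluded from the active list.
#' @export
identifyOpenUcnes <- function(ucneSet, dnase = list(), scatac = list()) {
  n <- length(ucneSet)
  dn <- vector("list", n); sc <- vector("list", n)
  for (i in seq_len(n)) { dn[[i]] <- character(0); sc[[i]] <- character(0) }
  for (b in dnase) {
    hit <- unique(intersectPairs(ucneSet, b$payload)$aIdx)
    for (i in hit) dn[[i]] <- union(dn[[i]], b$stage)
  }
  for (b in scatac) {
    hit <- unique(intersectPairs(ucneSet, b$payload)$aIdx)
    tag <- paste0(b$cluster, "::", b$stage)
    for (i in hit) sc[[i]] <- union(sc[[i]], tag)
  }
  open <- lengths(dn) + lengths(sc) > 0
  state <- factor(ifelse(open, "open_only", "none"),
                  levels = .enhancerStateLevels)
  new("UcneProfiles", ucnes = ucneSet, dnaseStages = CharacterList(dn),
      scatacHits = CharacterList(sc),
      marks = CharacterList(rep(list(character(0)), n)), state = state)
}

#' Annotate histone-mark context around elements
#'
#' Overlaps each ChIP-seq peak bundle with the elements extended by a
#' symmetric window (default +/- 250 bp), recording `"mark::stage"` evidence.
#' Reported coordinates always remain the original element coordinates.
#'
#' @param profiles a [UcneProfiles-class].
#' @param chip list of [trackBundle()]s with `mark` and `stage` set.
#' @param flank window half-width in bp.
#' @param vocabulary permitted mark labels; an unknown mark raises an error.
#' @return The updated [UcneProfiles-class].
#' @export
annotateMarks <- function(profiles, chip, flank = 250,
                          vocabulary = ucneMarkVocabulary()) {
  mk <- as.list(profiles@marks)
  for (b in chip) {
    if (!(b$mark %in% vocabulary))
      stop("unknown histone mark label: ", b$mark)
    hit <- unique(windowOverlapPairs(profiles@ucnes, b$payload, flank)$aIdx)
    tag <- paste0(b$mark, "::", b$stage)
    for (i in hit) mk[[i]] <- union(mk[[i]], tag)
  }
  profiles@marks <- CharacterList(mk)
  validObject(profiles)
  profiles
}

#' Derive the enhancer state of each element
#'
#' States are ordered `none < open_only < marked < active_enhancer <
#' sustained_adult`: any assessed mark at any stage makes an element
#' `marked`; the active-enhancer mark H3K27ac at a developmental stage makes
#' it `active_enhancer`; H3K27ac additionally present at an adult stage makes
#' it `sustained_adult`; an accessible element with no marks is `open_only`.
#'
#' @param profiles a [UcneProfiles-class] after [annotateMarks()].
#' @param devStages developmental stage labels.
#' @param adultStages adult stage labels.
#' @param activeMark the active-enhancer mark (default `"H3K27ac"`).
#' @return The [UcneProfiles-class] with its `state` slot filled.
#' @export
classifyEnhancerState <- function(profiles, devStages, adultStages,
                                  activeMark = "H3K27ac") {
  open <- isOpen(profiles)
  st <- vapply(seq_along(profiles@ucnes), function(i) {
    mk <- profiles@marks[[i]]
    if (!length(mk)) return(if (open[i]) "open_only" else "none")
    mark <- sub("::.*$", "", mk)
    stage <- sub("^.*::", "", mk)
    activeDev <- any(mark == activeMark & stage %in% devStages)
    activeAdult <- any(mark == activeMark & stage %in% adultStages)
    if (activeDev && activeAdult) "sustained_adult"
    else if (activeDev) "active_enhancer"
    else "marked"
  }, character(1))
  profiles@state <- factor(st, levels = .enhancerStateLevels)
  profiles
}

#' Per-mark-per-stage count table
#'
#' One row per mark, one column per stage counting elements with window
#' evidence for that mark at that stage, plus a `Unique` column counting
#' elements with the mark at one or more stages (so `Unique` is at most the
#' row sum and at least the row maximum).
#'
#' @param profiles a [UcneProfiles-class].
#' @param marks,stages row and column vocabularies.
#' @return An integer matrix.
#' @export
markCountTable <- function(profiles, marks = ucneMarkVocabulary(),
                           stages = NULL) {
  tags <- unlist(profiles@marks, use.names = FALSE)
  elem <- rep(seq_along(profiles@marks), lengths(profiles@marks))
  mark <- sub("::.*$", "", tags)
  stage <- sub("^.*::", "", tags)
  if (is.null(stages)) stages <- sort(unique(stage))
  out <- matrix(0L, nrow = length(marks), ncol = length(stages) + 1L,
                dimnames = list(marks, c(stages, "Unique")))
  for (m in marks) {
    for (s in stages)
      out[m, s] <- length(unique(elem[mark == m & stage == s]))
    out[m, "Unique"] <- length(unique(elem[mark == m]))
  }
  out
}

#' Fraction of active-enhancer elements also carrying priming marks
#'
#' Among elements at state `active_enhancer` or above, the fraction that also
#' display H3K4me1 or H3K4me2 at any stage.
#'
#' @param profiles a classified [UcneProfiles-class].
#' @return A fraction in `[0,1]`, or `NA` when no element is active.
#' @export
activeMarkCooccurrence <- function(profiles) {
  act <- which(as.integer(profiles@state) >=
                 match("active_enhancer", .enhancerStateLevels))
  if (!length(act)) return(NA_real_)
  has <- vapply(act, function(i) {
    any(sub("::.*$", "", profiles@marks[[i]]) %in% c("H3K4me1", "H3K4me2"))
  }, logical(1))
  mean(has)
}

#' Flat per-element profile table
#' @param profiles a [UcneProfiles-class].
#' @return A data.frame, one row per element, ready for TSV export.
#' @export
profileTable <- function(profiles) {
  u <- profiles@ucnes
  data.frame(ucne = mcols(u)$name,
             chrom = as.character(seqnames(u)),
             start = start(u) - 1L, end = end(u),
             open = isOpen(profiles),
             high_confidence = isHighConfidence(profiles),
             dnase_stages = vapply(profiles@dnaseStages, paste, "", collapse = ","),
             scatac = vapply(profiles@scatacHits, paste, "", collapse = ","),
             marks = vapply(profiles@marks, paste, "", collapse = ","),
             state = as.character(profiles@state))
}

#' Correlate element sets with validated-enhancer labels
#'
#' For each input set, counts the label-table elements overlapping at least
#' one set member, the positives among them, and (over positives) the
#' per-tissue breakdown, both over elements (an element counts once per
#' annotated tissue) and over element-tissue mentions.
#'
#' @param sets named list of `GRanges`.
#' @param labels a label `GRanges` from [readEnhancerLabels()].
#' @return A list with `summary` (data.frame: set, overlapped, positive,
#'   proportion, defined) and `tissues` (per set, a list with element-level
#'   and mention-level proportion tables).
#' @export
vistaCorrelate <- function(sets, labels) {
  stopifnot(!is.null(names(sets)))
  rows <- list(); tissues <- list()
  for (nm in names(sets)) {
    ovl <- overlapsAny(labels, sets[[nm]], minoverlap = 1L, ignore.strand = TRUE)
    hit <- labels[ovl]
    nPos <- sum(mcols(hit)$label == "positive")
    defined <- length(hit) > 0
    rows[[nm]] <- data.frame(set = nm, overlapped = length(hit),
                             positive = nPos,
                             proportion = if (defined) nPos / length(hit) else 0,
                             defined = defined)
    pos <- hit[mcols(hit)$label == "positive"]
    mentions <- unlist(mcols(pos)$tissues, use.names = FALSE)
    elemTab <- if (length(pos)) table(mentions) / length(pos) else table(character(0))
    mentTab <- if (length(mentions)) table(mentions) / length(mentions) else table(character(0))
    tissues[[nm]] <- list(perElement = elemTab, perMention = mentTab)
  }
  list(summary = do.call(rbind, rows), tissues = tissues)
}
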