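#' Sample fixed-length random genomic fragments
#'
#' Draws `n` fragments of exactly `width` bp uniformly over the allowed
#' start positions of the assembly, rejecting any draw overlapping the
#' exclusion set. Fragments may overlap each other, as in genome-wide uniform
#' background sampling. Deterministic given the RNG state (set `seed`, or
#' seed the session).
#'
#' @param assembly a `Seqinfo`.
#' @param n number of fragments (default 200).
#' @param width fragment length in bp (default 350).
#' @param exclude optional `GRanges` the fragments must not overlap
#'   (assembly gaps, the element set itself, ...).
#' @param seed optional integer seed applied before sampling.
#' @param maxTries rejection-sampling budget.
#' @return A `GRanges` of `n` fragments with a `name` column.
#' @export
sampleFragments <- function(assembly, n = 200, width = 350, exclude = NULL,
                            seed = NULL, maxTries = 200 * n) {
  if (!is.null(seed)) set.seed(seed)
  sl <- seqlengths(assembly)
  if (any(sl < width)) sl <- sl[sl >= width]
  if (!length(sl)) stop("no chromosome can host a fragment of width ", width)
  slots <- sl - width + 1
  placed <- GRanges(seqinfo = assembly)
  tries <- 0L
  while (length(placed) < n && tries < maxTries) {
    k <- min(n, max(10L, n - length(placed)))
    ch <- sample(names(slots), k, replace = TRUE, prob = slots / sum(slots))
    st <- floor(runif(k) * slots[ch]) + 1
    cand <- GRanges(ch, IRanges(st, st + width - 1), seqinfo = assembly)
    if (!is.null(exclude) && length(exclude))
      cand <- cand[!overlapsAny(cand, exclude, ignore.strand = TRUE)]
    need <- n - length(placed)
    if (length(cand) > need) cand <- cand[seq_len(need)]
    placed <- c(placed, cand)
    tries <- tries + k
  }
  if (length(placed) < n)
    stop("could not place ", n, " fragments (achieved ", length(placed),
         " after ", tries, " draws)")
  mcols(placed)$name <- sprintf("frag_%d", seq_len(n))
  placed
}

#' Allele-frequency spectrum over regions
#'
#' Bins the variants overlapping `regions` and reports counts and
#' proportions; with a `background` region set it additionally reports, per
#' bin, the per-bp variant-density ratio (regions / background), the
#' normalization under which a planted depletion factor on a bin is recovered
#' directly. Proportion spectra for both sets are also returned (the overlay
#' view).
#'
#' @param v variant `GRanges`.
#' @param regions `GRanges` of the region class of interest.
#' @param background optional `GRanges` of background regions.
#' @return A list with `counts`, `proportions`, and when `background` is
#'   given `backgroundCounts`, `backgroundProportions`, `densityRatio` and
#'   `ratioDefined` (FALSE for bins with zero background variants).
#' @export
afSpectrum <- function(v, regions, background = NULL) {
  bin <- classifyFrequency(v)
  inReg <- overlapsAny(v, regions, minoverlap = 1L, ignore.strand = TRUE)
  counts <- table(bin[inReg])
  nReg <- sum(counts)
  out <- list(counts = counts,
              proportions = if (nReg) counts / nReg else counts * NA_real_)
  if (!is.null(background)) {
    inBg <- overlapsAny(v, background, minoverlap = 1L, ignore.strand = TRUE)
    bCounts <- table(bin[inBg])
    nBg <- sum(bCounts)
    out$backgroundCounts <- bCounts
    out$backgroundProportions <- if (nBg) bCounts / nBg else bCounts * NA_real_
    bpReg <- sum(width(reduce(regions, ignore.strand = TRUE)))
    bpBg <- sum(width(reduce(background, ignore.strand = TRUE)))
    dens <- as.numeric(counts) / bpReg
    densBg <- as.numeric(bCounts) / bpBg
    ratio <- ifelse(bCounts > 0, dens / densBg, NA_real_)
    names(ratio) <- names(counts)
    out$densityRatio <- ratio
    out$ratioDefined <- bCounts > 0
  }
  out
}

#' Flanking regions around elements
#'
#' Two flanks of `flank` bp per element (clamped at chromosome ends, so a
#' flank may be truncated or absent), with any base belonging to an element
#' body excluded — flank bases never overlap any element, also for clustered
#' elements.
#'
#' @param ucneSet element `GRanges`.
#' @param flank flank width in bp (> 0, default 200).
#' @return A merged `GRanges` of flank intervals.
#' @export
buildFlanks <- function(ucneSet, flank = 200) {
  if (flank <= 0) stop("flank must be > 0")
  sl <- seqlengths(seqinfo(ucneSet))[as.character(seqnames(ucneSet))]
  ch <- as.character(seqnames(ucneSet))
  ls <- pmax(1, start(ucneSet) - flank); le <- start(ucneSet) - 1
  rs <- end(ucneSet) + 1; re <- pmin(end(ucneSet) + flank, sl)
  keepL <- le >= ls
  keepR <- re >= rs
  fl <- GRanges(c(ch[keepL], ch[keepR]),
                IRanges(c(ls[keepL], rs[keepR]), c(le[keepL], re[keepR])),
                seqinfo = seqinfo(ucneSet))
  fl <- reduce(fl, ignore.strand = TRUE)
  sortIntervals(setdiff(fl, granges(ucneSet), ignore.strand = TRUE))
}

#' Kruskal-Wallis rank-sum test
#'
#' H is computed on mid-ranks with the tie correction
#' `H / (1 - sum(t^3 - t) / (N^3 - N))`; the p-value comes from the
#' chi-square distribution with k-1 degrees of freedom. All-identical values
#' give H = 0, p = 1.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return A list with `H`, `df`, `p`, `n` (group sizes) and `meanRanks`.
#' @export
kruskalWallis <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(lengths(groups) == 0)) stop("groups must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  if (N < 3) stop("need at least three observations in total")
  r <- rank(x)
  Rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(n * Rbar^2) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) {
    H <- 0
  } else {
    H <- H / C
  }
  H <- max(0, H)  # guard tiny negative rounding
  df <- length(groups) - 1L
  p <- if (H == 0) 1 else pchisq(H, df, lower.tail = FALSE)
  list(H = H, df = df, p = p, n = n, meanRanks = as.numeric(Rbar))
}

#' Dunn post-hoc pairwise comparisons
#'
#' For groups i, j the statistic is
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) *
#' (1/n_i + 1/n_j))` with two-sided normal p-values; Bonferroni adjustment
#' multiplies by the number of pairs and caps at 1.
#'
#' @param groups list of >= 2 non-empty numeric vectors (named if you want
#'   named pairs).
#' @param correction `"bonferroni"` (the only correction offered) or
#'   `"none"`.
#' @return A data.frame with `group_i`, `group_j`, `z`, `p`, `p_adjusted`.
#' @export
dunnPosthoc <- function(groups, correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  if (length(groups) < 2) stop("need at least two groups")
  if (any(lengths(groups) == 0)) stop("groups must be non-empty")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  Rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  ties <- table(x)
  sigma2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(length(groups), 2)
  nPairs <- ncol(pairs)
  rows <- lapply(seq_len(nPairs), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(sigma2 * (1 / n[i] + 1 / n[j]))
    z <- if (se > 0) (Rbar[i] - Rbar[j]) / se else 0
    p <- 2 * pnorm(-abs(z))
    data.frame(group_i = nm[i], group_j = nm[j], z = as.numeric(z), p = p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (correction == "bonferroni")
    pmin(1, out$p * nPairs) else out$p
  out
}

#' RankTestResult: omnibus and pairwise rank comparison of score groups
#'
#' @slot H Kruskal-Wallis statistic (tie-corrected).
#' @slot p omnibus p-value.
#' @slot pairwise Dunn pairwise table (`z`, `p`, `p_adjusted`).
#' @slot medians per-group medians.
#' @slot n per-group sample sizes.
#' @slot nMissing bases without a score, dropped per group.
#' @export
setClass("RankTestResult",
         representation(H = "numeric", p = "numeric", pairwise = "data.frame",
                        medians = "numeric", n = "integer",
                        nMissing = "integer"))

setValidity("RankTestResult", function(object) {
  if (object@H < 0) return("H must be >= 0")
  if (object@p < 0 || object@p > 1) return("p must be in [0,1]")
  if (any(object@pairwise$p_adjusted < object@pairwise$p - 1e-12))
    return("adjusted p below raw p")
  TRUE
})

setMethod("show", "RankTestResult", function(object) {
  cat("Kruskal-Wallis H =", format(object@H, digits = 6),
      ", p =", format(object@p, digits = 4), "\n")
  cat("group medians:\n")
  print(object@medians)
  cat("pairwise (Dunn, Bonferroni):\n")
  print(object@pairwise, row.names = FALSE)
})

#' Compare constraint scores across element, flank and background regions
#'
#' Draws the constraint samples for each region class — per-base by default
#' (a region contributes its length in observations, matching a
#' nucleotide-resolution score), or per-region means for sensitivity analysis
#' — then runs the Kruskal-Wallis omnibus test and Dunn post-hoc pairwise
#' comparisons with Bonferroni correction. Lower scores mean greater
#' intolerance to variation, so a negative element-minus-background shift is
#' the depletion signature.
#'
#' @param track a [SignalTrack-class] of constraint scores (uncovered bases
#'   are treated as missing and dropped with a count).
#' @param ucneSet,flanks,background `GRanges` of the three region classes.
#' @param unit `"base"` or `"region"`.
#' @return A [RankTestResult-class] with groups named `UCNE`, `Flanking`,
#'   `Random`.
#' @export
compareConstraint <- function(track, ucneSet, flanks, background,
                              unit = c("base", "region")) {
  unit <- match.arg(unit)
  regionSets <- list(UCNE = ucneSet, Flanking = flanks, Random = background)
  groups <- list(); nMiss <- integer(3)
  for (k in seq_along(regionSets)) {
    sv <- scoreValues(track, regionSets[[k]], uncovered = "missing")
    vals <- sv$values
    if (unit == "region") {
      per <- lapply(seq_along(regionSets[[k]]), function(i) {
        scoreValues(track, regionSets[[k]][i], uncovered = "missing")$values
      })
      vals <- vapply(per[lengths(per) > 0], mean, numeric(1))
    }
    if (!length(vals)) stop("empty score group: ", names(regionSets)[k])
    groups[[names(regionSets)[k]]] <- vals
    nMiss[k] <- sv$nMissing
  }
  kw <- kruskalWallis(groups)
  dn <- dunnPosthoc(groups, "bonferroni")
  new("RankTestResult", H = kw$H, p = kw$p, pairwise = dn,
      medians = vapply(groups, median, numeric(1)),
      n = lengths(groups), nMissing = nMiss)
}

#' Check a random background for TSS-distance bias
#'
#' Computes the TSS-distance distribution (nearest-TSS magnitude, binned as
#' in [tssDistanceBins()]) for the element set and for the background, and a
#' two-sample rank test (Kruskal-Wallis with k = 2, a Wilcoxon-type
#' comparison) on the unbinned distances. A non-significant result supports
#' the background's suitability.
#'
#' @param ucneSet,background `GRanges`.
#' @param genes TSS `GRanges` with `gene_id`.
#' @return A list: `bins` (2 x 4 count matrix), `H`, `p`.
#' @export
backgroundSuitability <- function(ucneSet, background, genes) {
  distTo <- function(set) {
    nea <- nearest(set, genes, ignore.strand = TRUE)
    abs(distanceToPoint(set, start(genes)[nea] - 1L))
  }
  dU <- distTo(ucneSet)
  dB <- distTo(background)
  bins <- rbind(UCNE = table(tssDistanceBins(dU)),
                Random = table(tssDistanceBins(dB)))
  kw <- kruskalWallis(list(UCNE = dU, Random = dB))
  list(bins = bins, H = kw$H, p = kw$p)
}
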