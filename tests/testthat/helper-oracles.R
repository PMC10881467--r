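# Brute-force oracles and small fixture builders. Every oracle is written
# from the definition (per-base scans, all-pairs loops, definitional
# formulas) and never calls the implementation it checks.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

toyAssembly <- function(lens = c(chr1 = 10000L, chr2 = 8000L)) {
  genomeAssembly(names(lens), lens)
}

# Random interval set on an assembly (1-based closed internally).
randomIntervals <- function(n, assembly, maxWidth = 500) {
  sl <- seqlengths(assembly)
  ch <- sample(names(sl), n, replace = TRUE)
  w <- sample.int(maxWidth, n, replace = TRUE)
  s <- vapply(seq_len(n), function(i) sample.int(sl[ch[i]] - w[i] + 1L, 1L),
              integer(1))
  gr <- GRanges(ch, IRanges(s, s + w - 1L), seqinfo = assembly)
  mcols(gr)$name <- sprintf("iv%03d", seq_len(n))
  gr
}

# All-pairs overlap oracle: evaluates the overlap predicate on every (i, j)
# pair (outer loop over a, vector arithmetic over all of b).
bfIntersectPairs <- function(a, b) {
  chA <- as.character(seqnames(a)); chB <- as.character(seqnames(b))
  sA <- start(a); eA <- end(a); sB <- start(b); eB <- end(b)
  rows <- vector("list", length(a))
  for (i in seq_along(a)) {
    ov <- pmin(eA[i], eB) - pmax(sA[i], sB) + 1L
    j <- which(chB == chA[i] & ov >= 1L)
    if (length(j)) rows[[i]] <- cbind(i, j, ov[j])
  }
  m <- do.call(rbind, rows)
  if (is.null(m))
    return(data.frame(aIdx = integer(0), bIdx = integer(0),
                      overlap = integer(0)))
  df <- data.frame(aIdx = m[, 1], bIdx = m[, 2], overlap = m[, 3])
  df[order(df$aIdx, df$bIdx), , drop = FALSE]
}

# Per-base coverage oracle over one chromosome.
bfCoverage <- function(gr, chrom, len) {
  cov <- logical(len)
  sel <- as.character(seqnames(gr)) == chrom
  for (i in which(sel)) cov[start(gr)[i]:end(gr)[i]] <- TRUE
  cov
}

# Per-base threshold-scan peak oracle on a single-chromosome track.
bfCallPeaks <- function(track, chromLen, cutoff, minLength, maxGap) {
  val <- numeric(chromLen)
  r <- trackRuns(track)
  for (i in seq_along(r)) val[start(r)[i]:end(r)[i]] <- mcols(r)$score[i]
  hot <- val >= cutoff
  # close sub-threshold gaps <= maxGap
  runs <- rle(hot)
  pos <- cumsum(c(1, runs$lengths))
  for (k in seq_along(runs$lengths)) {
    if (!runs$values[k] && runs$lengths[k] <= maxGap &&
        k > 1 && k < length(runs$lengths)) {
      hot[pos[k]:(pos[k + 1] - 1)] <- TRUE
    }
  }
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= minLength
  out <- data.frame(start = starts[keep], end = ends[keep])
  out$maxValue <- vapply(seq_len(nrow(out)), function(i)
    max(val[out$start[i]:out$end[i]]), numeric(1))
  out$summit <- vapply(seq_len(nrow(out)), function(i) {
    v <- val[out$start[i]:out$end[i]]
    out$start[i] + which.max(v) - 1L
  }, numeric(1))
  out
}

# Random step-function track on one chromosome.
randomTrack <- function(assembly, chrom = "chr1", nRuns = 40,
                        values = c(0, 0.1, 0.3, 0.5, 1, 5, 10, 25, 30)) {
  len <- seqlengths(assembly)[chrom]
  cuts <- sort(sample.int(len - 1L, nRuns - 1L))
  s <- c(1L, cuts + 1L)
  e <- c(cuts, len)
  v <- sample(values, nRuns, replace = TRUE)
  gr <- GRanges(chrom, IRanges(s, e), seqinfo = assembly)
  mcols(gr)$score <- v
  signalTrack(gr[v != 0])
}

# All-windows identity oracle for the ultraconservation scan: per-start loop
# plus an independently coded longest-first selection.
bfScanUltraconserved <- function(ref, partner, offset = 0L, minLen = 201L,
                                 minIdent = 0.95) {
  r <- strsplit(toupper(ref), "")[[1]]
  p <- strsplit(toupper(partner), "")[[1]]
  isRef <- r != "-"
  m <- as.integer((r == p) & isRef & (p != "-"))
  refC <- ifelse(isRef, offset + cumsum(isRef) - 1L, NA_integer_)
  L <- length(m)
  wins <- list()
  for (s in seq_len(L)) {
    if (!isRef[s]) next
    if (L - s + 1L < minLen) next
    lens <- seq.int(minLen, L - s + 1L)
    csum <- cumsum(m[s:L])
    idv <- csum[lens] / lens
    okLens <- lens[idv >= minIdent & isRef[s + lens - 1L]]
    for (len in okLens) wins[[length(wins) + 1L]] <- c(s, len)
  }
  if (!length(wins)) return(data.frame(start0 = integer(0), end0 = integer(0)))
  wm <- do.call(rbind, wins)
  wm <- wm[order(-wm[, 2], wm[, 1]), , drop = FALSE]
  taken <- logical(L)
  sel <- list()
  for (k in seq_len(nrow(wm))) {
    s <- wm[k, 1]; e <- s + wm[k, 2] - 1L
    if (any(taken[s:e])) next
    taken[s:e] <- TRUE
    sel[[length(sel) + 1L]] <- c(s, e)
  }
  out <- do.call(rbind, sel)
  df <- data.frame(start0 = refC[out[, 1]], end0 = refC[out[, 2]] + 1L)
  df <- df[df$end0 - df$start0 >= minLen, , drop = FALSE]
  df[order(df$start0), , drop = FALSE]
}

# Random alignment with planted perfect blocks; background identity ~ 0.25.
randomAlignment <- function(len, blocks = list()) {
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, len, replace = TRUE)
  par <- sample(nt, len, replace = TRUE)
  for (b in blocks) par[b[1]:b[2]] <- ref[b[1]:b[2]]
  list(ref = paste(ref, collapse = ""), partner = paste(par, collapse = ""))
}

# Per-base regulatory-domain membership oracle: a base belongs to gene g's
# domain iff it lies within maxExt of g's basal domain and not beyond the
# nearest flanking foreign basal boundary (basal bases always belong).
# Vectorized over bases; the per-base predicate is evaluated for every base.
bfDomainMember <- function(base0, g, genesDf, up, down, maxExt, chromLen) {
  bs <- ifelse(genesDf$strand == "+", genesDf$tss - up, genesDf$tss - down + 1)
  be <- ifelse(genesDf$strand == "+", genesDf$tss + down, genesDf$tss + up + 1)
  bs <- pmax(0, bs); be <- pmin(chromLen, be)
  inBasal <- base0 >= bs[g] & base0 < be[g]
  okLeft <- base0 >= bs[g] - maxExt
  okRight <- base0 < be[g] + maxExt & base0 < chromLen
  for (j in seq_len(nrow(genesDf))) {
    if (j == g) next
    # left side: a foreign basal boundary strictly between base and basal,
    # or a foreign basal overlapping g's left basal edge
    okLeft <- okLeft & !(be[j] > base0 & be[j] <= bs[g])
    if (bs[j] < bs[g] && be[j] > bs[g]) okLeft <- FALSE
    # right side, mirrored
    okRight <- okRight & !(bs[j] >= be[g] & bs[j] <= base0)
    if (bs[j] < be[g] && be[j] > be[g]) okRight <- FALSE
  }
  inBasal | (base0 < bs[g] & okLeft) | (base0 >= be[g] & okRight)
}

# Definitional Kruskal-Wallis oracle: brute-force mid-ranks (comparison
# counting) plugged into the variance-form statistic.
bfKruskalWallis <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- vapply(seq_len(N), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
  Rbar <- mean(r)
  num <- (N - 1) * sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - Rbar)^2))
  den <- sum((r - Rbar)^2)
  if (den == 0) return(0)
  num / den
}

expect_same_pairs <- function(got, want) {
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$aIdx, want$aIdx)
  expect_equal(got$bIdx, want$bIdx)
  expect_equal(as.integer(got$overlap), as.integer(want$overlap))
}
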