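test_that("Kruskal-Wallis H matches the hand-computed tie-free value", {
  kw <- kruskalWallis(list(1:3, 4:6, 7:9))
  expect_equal(kw$H, 7.2)  # mean ranks 2, 5, 8 on N = 9
  expect_equal(kw$df, 2L)
  expect_equal(kw$p, pchisq(7.2, 2, lower.tail = FALSE))
  kwSame <- kruskalWallis(list(rep(2, 5), rep(2, 4)))
  expect_equal(kwSame$H, 0)
  expect_equal(kwSame$p, 1)
})

test_that("H equals the definitional brute-force rank statistic for N <= 10", {
  set.seed(701)
  for (rep in 1:80) {
    N <- sample(3:10, 1)
    k <- sample(2:min(3, N - 1), 1)
    sizes <- as.integer(table(sample(k, N, replace = TRUE)))
    sizes <- sizes[sizes > 0]
    if (length(sizes) < 2) next
    vals <- sample(1:5, sum(sizes), replace = TRUE)  # plenty of ties
    groups <- split(vals, rep(seq_along(sizes), sizes))
    expect_equal(kruskalWallis(groups)$H, bfKruskalWallis(groups),
                 tolerance = 1e-12)
    # cross-check against the reference implementation
    x <- unlist(groups); g <- factor(rep(seq_along(groups), lengths(groups)))
    if (all(lengths(groups) > 0) && length(unique(vals)) > 1) {
      ref <- stats::kruskal.test(x, g)
      expect_equal(kruskalWallis(groups)$H, unname(ref$statistic),
                   tolerance = 1e-12)
      expect_equal(kruskalWallis(groups)$p, unname(ref$p.value),
                   tolerance = 1e-12)
    }
  }
})

test_that("the omnibus test holds its nominal size under the null", {
  set.seed(702)
  nSim <- 2000
  rej <- logical(nSim)
  for (i in seq_len(nSim)) {
    g <- list(rnorm(30), rnorm(30), rnorm(30))
    rej[i] <- kruskalWallis(g)$p < 0.05
  }
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("Dunn z equals the direct formula on tie-free toys", {
  groups <- list(a = c(1, 4, 7), b = c(2, 5, 8), c = c(3, 6, 9))
  dn <- dunnPosthoc(groups)
  x <- unlist(groups); r <- rank(x)
  Rbar <- tapply(r, rep(1:3, each = 3), mean)
  N <- 9
  sigma2 <- N * (N + 1) / 12  # no ties
  zWant <- (Rbar[1] - Rbar[2]) / sqrt(sigma2 * (1 / 3 + 1 / 3))
  expect_equal(dn$z[dn$group_i == "a" & dn$group_j == "b"], unname(zWant))
  expect_equal(dn$p_adjusted, pmin(1, dn$p * 3))
  expect_true(all(dn$p_adjusted >= dn$p))
  expect_true(all(dn$p_adjusted <= 1))

  same <- dunnPosthoc(list(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_equal(same$z, 0)
  expect_equal(same$p_adjusted, 1)
})

test_that("a large planted location shift is detected by the post hoc", {
  set.seed(703)
  g <- list(rnorm(40), rnorm(40), rnorm(40) - 2)
  dn <- dunnPosthoc(g)
  expect_lt(min(dn$p_adjusted), 0.001)
})

test_that("fragment sampling is seeded, exact-width and exclusion-aware", {
  asm <- toyAssembly()
  f1 <- sampleFragments(asm, n = 50, width = 350, seed = 42)
  f2 <- sampleFragments(asm, n = 50, width = 350, seed = 42)
  f3 <- sampleFragments(asm, n = 50, width = 350, seed = 43)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  expect_false(identical(as.data.frame(f1), as.data.frame(f3)))
  expect_true(all(width(f1) == 350))

  tiny <- genomeAssembly("c", 350L)
  forced <- sampleFragments(tiny, n = 1, width = 350, seed = 1)
  expect_equal(c(start(forced), end(forced)), c(1L, 350L))

  whole <- GRanges("c", IRanges(1, 350))
  expect_error(sampleFragments(tiny, n = 1, width = 350, exclude = whole,
                               seed = 1, maxTries = 50), "could not place")

  excl <- GRanges("chr1", IRanges(1, 9000), seqinfo = asm)
  fr <- sampleFragments(asm, n = 30, width = 100, exclude = excl, seed = 7)
  expect_equal(nrow(bfIntersectPairs(fr, excl)), 0L)
})

test_that("flanks hug the element, clamp at ends and avoid all bodies", {
  asm <- toyAssembly()
  u <- GRanges("chr1", IRanges(1001, 1400), seqinfo = asm)  # [1000,1400)
  fl <- buildFlanks(u, 200)
  expect_equal(start(fl) - 1, c(800, 1400))
  expect_equal(end(fl), c(1000, 1600))

  uStart <- GRanges("chr1", IRanges(1, 300), seqinfo = asm)
  flS <- buildFlanks(uStart, 200)
  expect_equal(length(flS), 1L)  # left flank absent at the chromosome start
  expect_equal(c(start(flS), end(flS)), c(301L, 500L))

  set.seed(704)
  uC <- randomIntervals(30, asm, maxWidth = 300)
  flC <- buildFlanks(uC, 200)
  # per-base: flank bases never fall in any element body
  for (ch in GenomeInfoDb::seqnames(asm)) {
    len <- seqlengths(asm)[ch]
    expect_false(any(bfCoverage(flC, ch, len) & bfCoverage(uC, ch, len)))
  }
  expect_error(buildFlanks(u, 0), "flank must be")
})

test_that("spectrum proportions sum to one and flag empty backgrounds", {
  asm <- toyAssembly()
  u <- GRanges("chr1", IRanges(1001, 2000), seqinfo = asm)
  v <- GRanges("chr1", IRanges(seq(1101, 1600, by = 50), width = 1), seqinfo = asm)
  n <- length(v)
  mcols(v)$id <- sprintf("v%d", 1:n)
  mcols(v)$svtype <- NA; mcols(v)$n_hom <- 0L
  mcols(v)$af <- 0; mcols(v)$observed <- FALSE
  sp <- afSpectrum(v, u)
  expect_equal(sum(sp$proportions), 1)
  expect_equal(unname(sp$proportions["ultrarare"]), 1)

  bgEmpty <- GRanges("chr2", IRanges(1, 1000), seqinfo = asm)
  sp2 <- afSpectrum(v, u, background = bgEmpty)
  expect_false(any(sp2$ratioDefined))
  expect_true(all(is.na(sp2$densityRatio)))
})

test_that("group extraction and rank comparison work per base", {
  asm <- toyAssembly()
  mk <- function(s, e, v) {
    g <- GRanges("chr1", IRanges(s, e), seqinfo = asm)
    mcols(g)$score <- v
    g
  }
  track <- signalTrack(c(mk(1001, 1100, -1), mk(2001, 2100, -0.5),
                         mk(3001, 3100, 0.4)))
  u <- GRanges("chr1", IRanges(1001, 1100), seqinfo = asm)
  fl <- GRanges("chr1", IRanges(2001, 2100), seqinfo = asm)
  bg <- GRanges("chr1", IRanges(3001, 3100), seqinfo = asm)
  res <- compareConstraint(track, u, fl, bg)
  expect_equal(unname(res@n), c(100L, 100L, 100L))  # sizes = base counts
  expect_equal(unname(res@medians), c(-1, -0.5, 0.4))
  ub <- res@pairwise[res@pairwise$group_i == "UCNE" &
                       res@pairwise$group_j == "Random", ]
  expect_lt(ub$z, 0)  # elements score lower than background
  expect_lt(ub$p_adjusted, 0.05)
  # missing-score bases are dropped, not imputed
  uWide <- GRanges("chr1", IRanges(1001, 1200), seqinfo = asm)
  res2 <- compareConstraint(track, uWide, fl, bg)
  expect_equal(unname(res2@n[1]), 100L)
  expect_equal(res2@nMissing[1], 100L)
  expect_error(compareConstraint(track,
    GRanges("chr1", IRanges(9001, 9100), seqinfo = asm), fl, bg),
    "empty score group")
})

test_that("identical backgrounds give p = 1 in the suitability check", {
  asm <- toyAssembly()
  g <- GRanges("chr1", IRanges(5001, 5001), strand = "+", seqinfo = asm)
  mcols(g)$gene_id <- "g1"
  u <- GRanges("chr1", IRanges(c(1001, 7001), c(1300, 7300)), seqinfo = asm)
  res <- backgroundSuitability(u, u, g)
  expect_equal(res$p, 1)
  expect_equal(unname(rowSums(res$bins)), c(2, 2))  # bin totals = set sizes

  set.seed(705)
  far <- GRanges("chr1", IRanges(seq(9000, 9900, by = 100), width = 10),
                 seqinfo = asm)
  near <- GRanges("chr1", IRanges(seq(4800, 5200, by = 40), width = 10),
                  seqinfo = asm)
  res2 <- backgroundSuitability(near, far, g)
  expect_lt(res2$p, 0.01)  # a biased background is detected
})
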