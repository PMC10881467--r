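mkGenes <- function(asm, tss0, strand, ids = NULL) {
  gr <- GRanges(rep("chr1", length(tss0)), IRanges(tss0 + 1, tss0 + 1),
                strand = strand, seqinfo = asm)
  mcols(gr)$gene_id <- if (is.null(ids)) sprintf("g%d", seq_along(gr)) else ids
  gr
}

test_that("basal and extended domains follow the stated geometry", {
  asm <- genomeAssembly("chr1", 10e6)
  g <- mkGenes(asm, 2e6, "+")
  d <- buildDomains(g)
  expect_equal(c(start(basalDomains(d)) - 1, end(basalDomains(d))),
               c(1995000, 2001000))
  expect_equal(c(start(extendedDomains(d)) - 1, end(extendedDomains(d))),
               c(995000, 3001000))  # full 1 Mb both sides, no neighbours

  gNear <- mkGenes(asm, 3000, "+")
  dNear <- buildDomains(gNear)
  expect_equal(start(extendedDomains(dNear)) - 1, 0)  # clamped at chrom start

  gm <- mkGenes(asm, 2e6, "-")
  dm <- buildDomains(gm)
  expect_equal(c(start(basalDomains(dm)) - 1, end(basalDomains(dm))),
               c(2e6 - 999, 2e6 + 5001))  # mirrored on the minus strand

  expect_error(buildDomains(mkGenes(asm, c(1e6, 2e6), "+", c("a", "a"))),
               "duplicate gene_id")
})

test_that("extensions stop at the neighbouring basal boundary", {
  asm <- genomeAssembly("chr1", 10e6)
  g <- mkGenes(asm, c(2e6, 2.1e6), "+")
  d <- buildDomains(g)
  # gene 1 extends right exactly to gene 2's basal start, and vice versa
  expect_equal(end(extendedDomains(d))[1], 2.1e6 - 5e3)
  expect_equal(start(extendedDomains(d))[2] - 1, 2e6 + 1e3)
  # basal domains are never truncated
  expect_true(all(start(extendedDomains(d)) <= start(basalDomains(d))))
  expect_true(all(end(extendedDomains(d)) >= end(basalDomains(d))))
})

test_that("domain membership matches the per-base oracle on random layouts", {
  set.seed(501)
  # full per-base check at reduced scale, then spot checks at full scale
  asm <- genomeAssembly("chr1", 100000L)
  for (rep in 1:12) {
    n <- sample(2:6, 1)
    df <- data.frame(tss = sort(sample.int(99000, n)),
                     strand = sample(c("+", "-"), n, replace = TRUE))
    g <- mkGenes(asm, df$tss, df$strand)
    d <- buildDomains(g, up = 50, down = 10, maxExt = 10000)
    ext <- extendedDomains(d)
    bases0 <- sort(sample.int(100000L, 4000L)) - 1L
    for (i in seq_len(n)) {
      got <- bases0 >= start(ext)[i] - 1 & bases0 < end(ext)[i]
      want <- bfDomainMember(bases0, g = i, genesDf = df,
                             up = 50, down = 10, maxExt = 10000,
                             chromLen = 100000L)
      expect_equal(got, want)
    }
  }
})

test_that("domain boundaries match the oracle at full scale parameters", {
  set.seed(502)
  asm <- genomeAssembly("chr1", 10e6)
  for (rep in 1:6) {
    n <- sample(3:12, 1)
    df <- data.frame(tss = sort(sample.int(9.9e6, n)),
                     strand = sample(c("+", "-"), n, replace = TRUE))
    g <- mkGenes(asm, df$tss, df$strand)
    d <- buildDomains(g, up = 5000, down = 1000, maxExt = 1e6)
    ext <- extendedDomains(d)
    # check every boundary base and its two neighbours against the oracle
    for (i in seq_len(n)) {
      probe0 <- unique(pmax(0, pmin(10e6 - 1,
        c(start(ext)[i] - 2, start(ext)[i] - 1, start(ext)[i],
          end(ext)[i] - 1, end(ext)[i], end(ext)[i] + 1))))
      got <- probe0 >= start(ext)[i] - 1 & probe0 < end(ext)[i]
      want <- bfDomainMember(probe0, g = i, genesDf = df,
                             up = 5000, down = 1000, maxExt = 1e6,
                             chromLen = 10e6)
      expect_equal(got, want)
    }
  }
})

test_that("overlapping basal domains zero out the extension on that side", {
  asm <- genomeAssembly("chr1", 10e6)
  g <- mkGenes(asm, c(2e6, 2e6 + 2000), "+")  # basal domains overlap
  d <- buildDomains(g)
  ext <- extendedDomains(d)
  bas <- basalDomains(d)
  expect_equal(end(ext)[1], end(bas)[1])      # gene 1: no right extension
  expect_equal(start(ext)[2], start(bas)[2])  # gene 2: no left extension
})

test_that("curated domains override the computed extension", {
  asm <- genomeAssembly("chr1", 10e6)
  g <- mkGenes(asm, 2e6, "+")
  cur <- data.frame(gene_id = "g1", chrom = "chr1", start = 1e6, end = 4e6)
  d <- buildDomains(g, curated = cur)
  expect_equal(c(start(extendedDomains(d)) - 1, end(extendedDomains(d))),
               c(1e6, 4e6))
  expect_error(buildDomains(g, curated = data.frame(
    gene_id = "nope", chrom = "chr1", start = 1, end = 2)), "unknown gene")
})

test_that("target edges, histograms and distance bins behave", {
  asm <- genomeAssembly("chr1", 10e6)
  g <- mkGenes(asm, c(2e6, 2.1e6), "+")
  d <- buildDomains(g)
  u <- GRanges("chr1", IRanges(c(1.5e6, 2.05e6, 9.5e6) + 1,
                               c(1.5e6 + 300, 2.05e6 + 300, 9.5e6 + 300)),
               seqinfo = asm)
  mcols(u)$name <- c("u1", "u2", "u3")
  e <- assignTargets(u, d)
  expect_equal(e$gene[e$ucne == "u1"], "g1")
  expect_setequal(e$gene[e$ucne == "u2"], c("g1", "g2"))  # overlap zone
  expect_equal(sum(e$ucne == "u3"), 0L)
  hist <- genesPerUcne(e, mcols(u)$name)
  expect_equal(as.integer(hist[c("0", "1", "2")]), c(1L, 1L, 1L))
  expect_equal(as.character(tssDistanceBins(c(100, 20000, 200000, 7e5))),
               c("0-5kb", "5-50kb", "50-500kb", ">500kb"))
  # with one gene and no cap, every element lands on it
  g1 <- mkGenes(asm, 5e6, "+")
  dAll <- buildDomains(g1, maxExt = 1e9)
  eAll <- assignTargets(u, dAll)
  expect_equal(sort(unique(eAll$ucne)), c("u1", "u2", "u3"))

  # edge set equals brute-force overlap of elements with extended domains
  set.seed(503)
  uR <- GRanges("chr1", IRanges(sample.int(9e6, 40), width = 400), seqinfo = asm)
  mcols(uR)$name <- sprintf("r%d", 1:40)
  eR <- assignTargets(uR, d)
  bf <- bfIntersectPairs(uR, extendedDomains(d))
  expect_equal(nrow(eR), nrow(bf))
  expect_equal(eR$ucne, mcols(uR)$name[bf$aIdx])
  expect_equal(eR$gene, geneIds(d)[bf$bIdx])
})

test_that("expression filtering keeps TPM exactly at the threshold", {
  e <- data.frame(ucne = c("u1", "u1", "u2", "u3"),
                  gene = c("gA", "gB", "gC", "gZ"),
                  tss_distance = c(0, 1, 2, 3))
  m <- matrix(c(0.6, 0, 0,
                0.49, 0.2, 0.1,
                0.5, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2", "s3")))
  expect_warning(out <- filterExpressed(e, m), "absent from the expression")
  expect_setequal(out$gene, c("gA", "gC"))  # 0.49 dropped, 0.5 kept
  expect_equal(attr(out, "nMissing"), 1L)
  # idempotent
  out2 <- filterExpressed(out, m)
  expect_equal(out2$gene, out$gene)
})

test_that("TAD consistency uses co-containment with half-open ends", {
  asm <- genomeAssembly("chr1", 10e6)
  tads <- GRanges("chr1", IRanges(c(1, 50001), c(50000, 100000)), seqinfo = asm)
  u <- GRanges("chr1", IRanges(10001, 10300), seqinfo = asm)
  mcols(u)$name <- "u1"
  gIn <- mkGenes(asm, 20000, "+", "gin")        # same TAD
  gEdge <- mkGenes(asm, 50000, "+", "gedge")    # TSS at TAD end (exclusive)
  e <- data.frame(ucne = c("u1", "u1"), gene = c("gin", "gedge"),
                  tss_distance = c(0, 0))
  res <- tadConsistency(e, tads, u, c(gIn, gEdge))
  expect_equal(res$edges$tad_consistent, c(TRUE, FALSE))
  expect_equal(res$fractionGenes, 0.5)

  # random layouts equal the brute-force triple loop
  set.seed(504)
  for (rep in 1:5) {
    uR <- GRanges("chr1", IRanges(sample.int(9e6, 15), width = 300), seqinfo = asm)
    mcols(uR)$name <- sprintf("u%d", 1:15)
    gR <- mkGenes(asm, sort(sample.int(9e6, 10)), "+")
    tR <- GRanges("chr1", IRanges(seq(1, 9e6, by = 7e5),
                                  seq(1, 9e6, by = 7e5) + 699999), seqinfo = asm)
    eR <- assignTargets(uR, buildDomains(gR))
    if (!nrow(eR)) next
    res <- tadConsistency(eR, tR, uR, gR)
    for (k in seq_len(nrow(eR))) {
      ui <- match(eR$ucne[k], mcols(uR)$name)
      gi <- match(eR$gene[k], mcols(gR)$gene_id)
      want <- FALSE
      for (t in seq_along(tR)) {
        ovU <- min(end(uR)[ui], end(tR)[t]) - max(start(uR)[ui], start(tR)[t]) >= 0
        inG <- start(gR)[gi] >= start(tR)[t] && start(gR)[gi] <= end(tR)[t]
        if (ovU && inG) want <- TRUE
      }
      expect_equal(res$edges$tad_consistent[k], want)
    }
  }
})

test_that("signatures are the clusters strictly above the gene percentile", {
  m <- rbind(g1 = c(rep(0, 9), 5),
             g2 = rep(3, 10),
             g3 = rep(0, 10))
  colnames(m) <- paste0("c", 1:10)
  sig <- assignSignatures(m, 80)
  expect_equal(unname(as.list(sig)$g1), "c10")
  expect_equal(lengths(sig)[["g2"]], 0L)  # constant gene: nothing above
  expect_equal(lengths(sig)[["g3"]], 0L)  # all-zero gene: empty, no error

  set.seed(505)
  mR <- matrix(rpois(50 * 12, 4), 50, 12,
               dimnames = list(sprintf("g%02d", 1:50), sprintf("c%02d", 1:12)))
  sigR <- assignSignatures(mR, 80)
  for (i in sample(50, 10)) {
    thr <- as.numeric(quantile(mR[i, ], 0.8, type = 7))
    expect_setequal(sigR[[i]], colnames(mR)[mR[i, ] > thr])
  }
  expect_error(assignSignatures(m[, 1, drop = FALSE]), "two clusters")
})

test_that("concordance intersects open clusters with target signatures", {
  asm <- toyAssembly()
  u <- GRanges("chr1", IRanges(c(1001, 3001), c(1300, 3300)), seqinfo = asm)
  mcols(u)$name <- c("u1", "u2")
  prof <- identifyOpenUcnes(u, scatac = list(
    trackBundle(GRanges("chr1", IRanges(1001, 1100), seqinfo = asm),
                cluster = "GanglionPrecursors", stage = "s"),
    trackBundle(GRanges("chr1", IRanges(3001, 3100), seqinfo = asm),
                cluster = "Cones", stage = "s")))
  e <- data.frame(ucne = c("u1", "u2"), gene = c("gA", "gB"),
                  tss_distance = c(0, 0))
  sig <- CharacterList(gA = c("GanglionPrecursors", "Rods"), gB = "Rods")
  res <- concordance(e, prof, sig)
  expect_equal(res$perUcne$concordant, c(TRUE, FALSE))
  expect_equal(res$fraction, 0.5)
  expect_error(
    concordance(e, prof, sig, clusterMap = c(Rods = "Rods")),
    "unmapped cluster")
  resMapped <- concordance(e, prof, sig,
    clusterMap = c(GanglionPrecursors = "Rods", Cones = "Muller"))
  expect_equal(resMapped$perUcne$concordant, c(TRUE, FALSE))
})

test_that("linkage comparison applies the strict correlation threshold", {
  asm <- toyAssembly()
  u <- GRanges("chr1", IRanges(c(1001, 3001), c(1300, 3300)), seqinfo = asm)
  mcols(u)$name <- c("u1", "u2")
  lnk <- GRanges("chr1", IRanges(c(1001, 3001), c(1300, 3300)), seqinfo = asm)
  mcols(lnk)$gene <- c("gA", "gB")
  mcols(lnk)$correlation <- c(0.4, 0.41)  # 0.4 exactly is excluded
  e <- data.frame(ucne = c("u1", "u2"), gene = c("gA", "gB"),
                  tss_distance = c(0, 0))
  res <- peak2geneCompare(e, lnk, u)
  expect_equal(res$perUcne$class[res$perUcne$ucne == "u1"], "no_linkage")
  expect_equal(res$perUcne$class[res$perUcne$ucne == "u2"], "identical")
  expect_equal(res$agreement, 0.5)
})

test_that("disease filtering is a keyed intersection", {
  e <- data.frame(ucne = c("u1", "u2", "u3"), gene = c("gA", "gB", "gC"),
                  tss_distance = 0)
  dz <- data.frame(gene = "gB", panel = "Eye", phenotype = "x")
  out <- diseaseGeneFilter(e, dz)
  expect_equal(out$gene, "gB")
  expect_equal(out$panel, "Eye")
  expect_equal(nrow(diseaseGeneFilter(e, dz[0, ])), 0L)
})

test_that("edges and downstream flags match the planted truth without noise", {
  cfg <- simulationConfig(seed = 11, backgroundPeakRate = 0)
  b <- simulateBundle(cfg)
  pcfg <- pipelineConfig()
  ann <- stageAnnotate(b, pcfg)
  tgt <- stageTargets(b, pcfg, ann)
  tr <- b$truth
  activeNames <- mcols(ucnes(ann$profiles))$name[isOpen(ann$profiles)]
  wantEdges <- tr$edges[tr$edges$ucne %in% activeNames, ]
  expect_equal(nrow(tgt$edges), nrow(wantEdges))
  expect_equal(paste(tgt$edges$ucne, tgt$edges$gene),
               paste(wantEdges$ucne, wantEdges$gene))
  wantExpr <- wantEdges[wantEdges$expressed, ]
  expect_equal(paste(tgt$expressedEdges$ucne, tgt$expressedEdges$gene),
               paste(wantExpr$ucne, wantExpr$gene))
  expect_equal(tgt$expressedEdges$tad_consistent, wantExpr$tad_shared)
  # planted signatures recovered from the cluster matrix
  for (g in sample(names(tr$signatures), 20))
    expect_setequal(tgt$signatures[[g]], tr$signatures[[g]])
  # concordance flags equal planting for open elements
  conc <- tgt$concordance$perUcne
  wantConc <- tr$perUcne[match(conc$ucne, tr$perUcne$ucne), "concordant"]
  expect_equal(conc$concordant, wantConc)
  # filter chain is monotone
  expect_gte(nrow(tgt$edges), nrow(tgt$expressedEdges))
  expect_gte(nrow(tgt$expressedEdges), sum(tgt$expressedEdges$tad_consistent))
})
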