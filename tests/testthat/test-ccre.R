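mkUcnes <- function(asm, starts0, width = 300) {
  gr <- GRanges("chr1", IRanges(starts0 + 1, starts0 + width), seqinfo = asm)
  mcols(gr)$name <- sprintf("u%d", seq_along(gr))
  gr
}

test_that("openness needs a single source; both sources mark high confidence", {
  asm <- toyAssembly()
  u <- mkUcnes(asm, c(1000, 3000, 5000))
  scPk <- GRanges("chr1", IRanges(1101, 1200), seqinfo = asm)   # over u1
  dnPk <- GRanges("chr1", IRanges(c(1101, 3101), c(1300, 3200)), seqinfo = asm)
  prof <- identifyOpenUcnes(u,
    dnase = list(trackBundle(dnPk, stage = "ED89")),
    scatac = list(trackBundle(scPk, cluster = "Rods", stage = "ED113")))
  expect_equal(isOpen(prof), c(TRUE, TRUE, FALSE))
  expect_equal(isHighConfidence(prof), c(TRUE, FALSE, FALSE))
  expect_equal(as.character(enhancerState(prof)),
               c("open_only", "open_only", "none"))
  expect_equal(unname(as.list(openClusters(prof))[[1]]), "Rods")
  # the active list always contains the high-confidence subset
  expect_true(all(which(isHighConfidence(prof)) %in% which(isOpen(prof))))
})

test_that("mark evidence uses the +/-250 bp window and mark vocabulary", {
  asm <- toyAssembly()
  u <- mkUcnes(asm, 1000)  # [1000,1300)
  near <- GRanges("chr1", IRanges(1501, 1600), seqinfo = asm)  # 200 bp away
  far <- GRanges("chr1", IRanges(1601, 1700), seqinfo = asm)   # 300 bp away
  prof <- identifyOpenUcnes(u, scatac = list(
    trackBundle(GRanges("chr1", IRanges(1001, 1100), seqinfo = asm),
                cluster = "Rods", stage = "s")))
  p1 <- annotateMarks(prof, list(trackBundle(near, mark = "H3K27ac",
                                             stage = "FW13/14")))
  expect_equal(unname(as.list(markNames(p1))[[1]]), "H3K27ac")
  p2 <- annotateMarks(prof, list(trackBundle(far, mark = "H3K27ac",
                                             stage = "FW13/14")))
  expect_equal(lengths(markNames(p2)), 0L)
  expect_error(
    annotateMarks(prof, list(trackBundle(near, mark = "H3K9ac", stage = "s"))),
    "unknown histone mark")
})

test_that("enhancer states are ordered and adult persistence is separate", {
  asm <- toyAssembly()
  u <- mkUcnes(asm, c(1000, 3000, 5000, 7000))
  open <- lapply(c(1000, 3000, 5000, 7000), function(s)
    GRanges("chr1", IRanges(s + 1, s + 50), seqinfo = asm))
  prof <- identifyOpenUcnes(u, scatac = list(
    trackBundle(do.call(c, open), cluster = "Rods", stage = "s")))
  chip <- list(
    trackBundle(GRanges("chr1", IRanges(3001, 3100), seqinfo = asm),
                mark = "H3K4me1", stage = "FW13/14"),
    trackBundle(GRanges("chr1", IRanges(5001, 5100), seqinfo = asm),
                mark = "H3K27ac", stage = "FW15/16"),
    trackBundle(GRanges("chr1", IRanges(7001, 7100), seqinfo = asm),
                mark = "H3K27ac", stage = "FW15/16"),
    trackBundle(GRanges("chr1", IRanges(7001, 7100), seqinfo = asm),
                mark = "H3K27ac", stage = "adult"))
  prof <- annotateMarks(prof, chip)
  prof <- classifyEnhancerState(prof,
    devStages = c("FW13/14", "FW15/16"), adultStages = "adult")
  st <- as.character(enhancerState(prof))
  expect_equal(st, c("open_only", "marked", "active_enhancer",
                     "sustained_adult"))
  # ladder: marked superset of active superset of sustained
  expect_true(sum(st %in% c("marked", "active_enhancer", "sustained_adult")) >=
                sum(st %in% c("active_enhancer", "sustained_adult")))
})

test_that("mark count table satisfies the unique-column bounds", {
  set.seed(401)
  asm <- toyAssembly()
  u <- mkUcnes(asm, seq(500, 8000, by = 1500), width = 200)
  prof <- identifyOpenUcnes(u, scatac = list(
    trackBundle(granges(u), cluster = "Rods", stage = "s")))
  chip <- list()
  stages <- c("FW13/14", "FW15/16")
  for (m in c("H3K27ac", "H3K4me1")) for (s in stages) {
    sel <- sample(length(u), 3)
    chip[[paste(m, s)]] <- trackBundle(granges(u)[sel], mark = m, stage = s)
  }
  prof <- annotateMarks(prof, chip)
  tab <- markCountTable(prof, stages = stages)
  for (m in rownames(tab)) {
    expect_lte(tab[m, "Unique"], sum(tab[m, stages]))
    expect_gte(tab[m, "Unique"], max(tab[m, stages]))
  }
})

test_that("enlarging a peak set never shrinks the active list", {
  set.seed(402)
  asm <- toyAssembly()
  u <- mkUcnes(asm, seq(500, 9000, by = 900), width = 200)
  pk1 <- randomIntervals(5, asm)
  pk2 <- c(granges(pk1), granges(randomIntervals(5, asm)))
  p1 <- identifyOpenUcnes(u, scatac = list(trackBundle(pk1, cluster = "c", stage = "s")))
  p2 <- identifyOpenUcnes(u, scatac = list(trackBundle(pk2, cluster = "c", stage = "s")))
  expect_true(all(isOpen(p2)[isOpen(p1)]))
})

test_that("validated-enhancer correlation counts overlaps and tissues", {
  asm <- toyAssembly()
  u <- mkUcnes(asm, c(1000, 3000))
  lab <- GRanges("chr1", IRanges(c(1101, 3101, 6001, 8001),
                                 c(1200, 3200, 6100, 8100)), seqinfo = asm)
  mcols(lab)$label <- c("positive", "negative", "positive", "negative")
  mcols(lab)$tissues <- CharacterList(list(c("eye", "forebrain"),
                                           character(0), "limb", character(0)))
  res <- vistaCorrelate(list(test = u), lab)
  expect_equal(res$summary$overlapped, 2L)
  expect_equal(res$summary$positive, 1L)
  expect_equal(res$summary$proportion, 0.5)
  expect_true(res$summary$defined)
  expect_equal(as.numeric(res$tissues$test$perElement[c("eye", "forebrain")]),
               c(1, 1))
  expect_equal(as.numeric(res$tissues$test$perMention[c("eye", "forebrain")]),
               c(0.5, 0.5))

  far <- mkUcnes(asm, 9000, width = 50)
  res2 <- vistaCorrelate(list(test = far), lab)
  expect_equal(res2$summary$overlapped, 0L)
  expect_false(res2$summary$defined)  # 0/0 case flagged, not NaN
  expect_equal(res2$summary$proportion, 0)
})

test_that("planted synthetic activity is recovered exactly without noise", {
  cfg <- simulationConfig(seed = 5, backgroundPeakRate = 0)
  b <- simulateBundle(cfg)
  ann <- stageAnnotate(b, pipelineConfig())
  prof <- ann$profiles
  tr <- b$truth$perUcne
  expect_equal(unname(isOpen(prof)), tr$open)
  expect_equal(unname(isHighConfidence(prof)), tr$high_confidence)
  expect_equal(as.character(enhancerState(prof)), tr$state)
  got <- vapply(as.list(openClusters(prof)),
                function(x) paste(sort(x), collapse = ","), "")
  expect_equal(unname(got), tr$clusters)
})
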