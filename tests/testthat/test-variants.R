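mkVariants <- function(af, observed, n_hom = 0L, pos = NULL, asm = NULL) {
  n <- length(af)
  if (is.null(pos)) pos <- seq(100, by = 10, length.out = n)
  gr <- if (is.null(asm)) GRanges("chr1", IRanges(pos, pos)) else
    GRanges("chr1", IRanges(pos, pos), seqinfo = asm)
  mcols(gr)$id <- sprintf("v%d", seq_len(n))
  mcols(gr)$ref <- "A"; mcols(gr)$alt <- "C"
  mcols(gr)$svtype <- NA_character_
  mcols(gr)$af <- af
  mcols(gr)$observed <- observed
  mcols(gr)$n_hom <- rep_len(as.integer(n_hom), n)
  gr
}

test_that("frequency bins match the printed boundaries exactly", {
  v <- mkVariants(af = c(0, 5e-4, 1e-3, 3e-3, 5e-3, 0.02, 0.05, 0.3),
                  observed = c(FALSE, rep(TRUE, 7)))
  expect_equal(as.character(classifyFrequency(v)),
               c("ultrarare", "very_rare", "rare", "rare", "low_frequency",
                 "low_frequency", "common", "common"))
})

test_that("every representable frequency gets exactly one bin", {
  af <- (0:10000) / 10000
  v <- mkVariants(af = af, observed = rep(TRUE, length(af)),
                  pos = seq_len(length(af)))
  bin <- classifyFrequency(v)
  expect_false(any(is.na(bin)))
  # fold at 0.5: MAF semantics
  maf <- pmin(af, 1 - af)
  want <- ifelse(maf < 0.001, "very_rare",
          ifelse(maf < 0.005, "rare",
          ifelse(maf < 0.05, "low_frequency", "common")))
  expect_equal(as.character(bin), want)
  # the absent flag is its own bin, never inferred from af
  vAbs <- mkVariants(af = 0, observed = FALSE)
  expect_equal(as.character(classifyFrequency(vAbs)), "ultrarare")
})

test_that("frequency-unknown is an error, never silently binned", {
  v <- mkVariants(af = c(NA, 0.1), observed = c(NA, TRUE))
  expect_error(classifyFrequency(v), "frequency-unknown")
  v2 <- mkVariants(af = c(NA, 0.1), observed = c(TRUE, TRUE))
  expect_error(classifyFrequency(v2), "frequency-unknown")
})

test_that("the rare filter keeps MAF < 0.5% or absent, with no homozygotes", {
  v <- mkVariants(af = c(0.004, 0.004, 0, 0.02, 0.001),
                  observed = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                  n_hom = c(0L, 1L, 0L, 0L, 0L))
  kept <- rareFilter(v)
  expect_equal(mcols(kept)$id, c("v1", "v3", "v5"))

  set.seed(601)
  af <- runif(300, 0, 0.6)
  obs <- runif(300) > 0.1
  af[!obs] <- 0
  nh <- rpois(300, 0.5)
  vR <- mkVariants(af = af, observed = obs, n_hom = nh, pos = seq_len(300))
  kept <- rareFilter(vR)
  wantKeep <- (!obs | pmin(af, 1 - af) < 0.005) & nh == 0
  expect_equal(mcols(kept)$id, mcols(vR)$id[wantKeep])
})

test_that("variant-element overlap includes SV spans and SNV boundary bases", {
  asm <- toyAssembly()
  u <- GRanges("chr1", IRanges(c(1001, 5001), c(1300, 5400)), seqinfo = asm)
  mcols(u)$name <- c("u1", "u2")
  prof <- identifyOpenUcnes(u, scatac = list(
    trackBundle(granges(u), cluster = "c", stage = "s")))
  v <- mkVariants(af = c(0, 0, 0), observed = FALSE,
                  pos = c(1001, 1301, 2000), asm = asm)  # first base / abutting / away
  sv <- GRanges("chr1", IRanges(4001, 9000), seqinfo = asm)  # spans u2 fully
  mcols(sv)$id <- "sv1"; mcols(sv)$ref <- "N"; mcols(sv)$alt <- "<DUP>"
  mcols(sv)$svtype <- "DUP"; mcols(sv)$af <- 0
  mcols(sv)$observed <- FALSE; mcols(sv)$n_hom <- 0L
  e <- data.frame(ucne = c("u1", "u2"), gene = c("gA", "gB"), tss_distance = 0)
  hits <- overlapActiveUcnes(c(v, sv), prof, e)
  expect_setequal(paste(hits$variant_id, hits$ucne),
                  c("v1 u1", "sv1 u2"))
  expect_true(hits$is_sv[hits$variant_id == "sv1"])
  expect_equal(hits$genes[hits$ucne == "u2"], "gB")
})

test_that("the search space needs histone marks plus a disease-gene link", {
  hits <- data.frame(
    variant_id = c("v1", "v2", "v3", "v4"),
    bin = "ultrarare", is_sv = FALSE,
    ucne = c("u1", "u2", "u3", "u2"),
    enhancer_state = c("open_only", "marked", "sustained_adult", "marked"),
    genes = c("gA,gB", "gA", "gC", "gA,gC"),
    in_unsolved = c(TRUE, TRUE, FALSE, FALSE))
  res <- defineSearchSpace(hits, diseaseGenes = c("gA"))
  expect_setequal(res$hits$variant_id, c("v2", "v4"))  # u1 open_only excluded
  expect_equal(res$counts$n_variants, 2L)
  expect_equal(res$counts$n_ucnes, 1L)
  expect_equal(res$counts$n_genes, 1L)
  expect_equal(res$counts$n_variants_unsolved, 1L)
  # no disease link -> empty space
  expect_equal(defineSearchSpace(hits, "gZ")$counts$n_variants, 0L)
})

test_that("planted search-space counts are recovered without noise", {
  cfg <- simulationConfig(seed = 19, backgroundPeakRate = 0)
  b <- simulateBundle(cfg)
  pcfg <- pipelineConfig()
  ann <- stageAnnotate(b, pcfg)
  tgt <- stageTargets(b, pcfg, ann)
  vr <- stageVariants(b, pcfg, ann, tgt)
  # independent recount from the truth table and raw variant table
  tr <- b$truth
  bin <- classifyFrequency(b$variants)
  keep <- bin %in% c("ultrarare", "very_rare", "rare") &
    mcols(b$variants)$n_hom == 0L
  rare <- b$variants[keep]
  stOf <- setNames(tr$perUcne$state, tr$perUcne$ucne)
  exprEdges <- tr$edges[tr$edges$expressed, ]
  dz <- tr$diseaseGenes
  qual <- character(0); qualU <- character(0); qualG <- character(0)
  for (i in seq_along(b$ucnes)) {
    nm <- mcols(b$ucnes)$name[i]
    if (!(stOf[nm] %in% c("marked", "active_enhancer", "sustained_adult"))) next
    tg <- intersect(exprEdges$gene[exprEdges$ucne == nm], dz)
    if (!length(tg)) next
    ov <- mcols(rare)$id[overlapsAny(rare, b$ucnes[i], ignore.strand = TRUE)]
    if (length(ov)) {
      qual <- union(qual, ov); qualU <- union(qualU, nm)
      qualG <- union(qualG, tg)
    }
  }
  expect_equal(vr$counts$search_space$n_variants, length(qual))
  expect_equal(vr$counts$search_space$n_ucnes, length(qualU))
  expect_equal(vr$counts$search_space$n_genes, length(qualG))
  # chain: search space within hits within the rare set
  expect_lte(vr$counts$search_space$n_variants, vr$counts$n_hits)
  expect_lte(vr$counts$n_hits, length(rare) + sum(duplicated(vr$hits$variant_id)))
})
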