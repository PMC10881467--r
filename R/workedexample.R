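#' A miniature, fully hand-checkable input bundle
#'
#' One 100 kb chromosome, three genes and five elements, with every value
#' chosen so each pipeline stage can be verified by hand: one element is open
#' by DNase only, one sustains the active-enhancer mark into adult stage, one
#' is covered by a duplication, one sits under a low-signal DNase peak and
#' stays closed, and one gene is expressed at exactly the TPM threshold.
#' The bundle is fixed (no random numbers), so repeated pipeline runs give
#' byte-identical reports.
#'
#' @return A `SimBundle` list (see [simulateBundle()]); no truth table is
#'   attached — the expected outputs ship as fixtures.
#' @export
workedExampleBundle <- function() {
  assembly <- genomeAssembly("chrZ", 100000L)
  gr <- function(s0, e0, ...) GRanges("chrZ", IRanges(s0 + 1L, e0),
                                      seqinfo = assembly, ...)
  genes <- c(gr(20000, 20001, strand = "+"), gr(60000, 60001, strand = "-"),
             gr(90000, 90001, strand = "+"))
  end(genes) <- start(genes)  # width-1 TSS anchors
  mcols(genes)$gene_id <- c("GENE1", "GENE2", "GENE3")

  ucnes <- c(gr(10000, 10350), gr(30000, 30400), gr(50000, 50300),
             gr(70000, 70250), gr(95000, 95400))
  mcols(ucnes)$name <- paste0("U", 1:5)

  mkTrack <- function(s0, e0, v) {
    g <- gr(s0, e0)
    mcols(g)$score <- v
    signalTrack(g)
  }
  scatac <- list(
    trackBundle(mkTrack(29950, 30450, 1.0),
                cluster = "GanglionPrecursors", stage = "ED59"),
    trackBundle(mkTrack(69950, 70300, 1.0), cluster = "Rods", stage = "ED113"),
    trackBundle(mkTrack(94950, 95450, 1.0), cluster = "Cones", stage = "ED113"))

  dnPk <- c(gr(9950, 10400), gr(69950, 70350), gr(49900, 50400))
  mcols(dnPk)$name <- c("High-DNase", "High-DNase", "Low-DNase")
  dnase <- list(trackBundle(dnPk, stage = "ED74-85"))

  chip <- list(
    trackBundle(mkTrack(30450, 30700, 30), mark = "H3K27ac", stage = "FW13/14"),
    trackBundle(mkTrack(29900, 30200, 25), mark = "H3K27ac", stage = "adult"),
    trackBundle(mkTrack(69900, 70400, 30), mark = "H3K4me1", stage = "FW15/16"),
    trackBundle(mkTrack(30000, 30300, 22), mark = "H3K4me1", stage = "FW13/14"))

  tads <- c(gr(0, 55000), gr(55000, 100000))
  mcols(tads)$name <- c("tad_1", "tad_2")

  stageExpr <- matrix(c(0.2, 12, 0.3,
                        0.4, 0.4, 0.49,
                        0.5, 0.2, 0.1),
                      nrow = 3, byrow = TRUE,
                      dimnames = list(c("GENE1", "GENE2", "GENE3"),
                                      c("D52", "D80", "D136")))
  clusters <- c("EarlyRPC", "GanglionPrecursors", "Rods", "Cones",
                "MullerGlia")
  clusterExpr <- matrix(0, 3, 5,
                        dimnames = list(c("GENE1", "GENE2", "GENE3"), clusters))
  clusterExpr["GENE1", "GanglionPrecursors"] <- 10
  clusterExpr["GENE2", "EarlyRPC"] <- 10
  clusterExpr["GENE3", "Rods"] <- 10

  linkages <- c(gr(30000, 30400), gr(70000, 70250), gr(95000, 95400))
  mcols(linkages)$gene <- c("GENE1", "GENE2", "GENE3")
  mcols(linkages)$correlation <- c(0.6, 0.7, 0.4)

  vdf <- data.frame(
    chrom = "chrZ",
    pos = c(30101, 70101, 70201, 95101, 10101, 45001, 30201, 69001),
    id = c(paste0("v", 1:7), "sv1"),
    ref = c(rep("A", 7), "N"),
    alt = c(rep("T", 7), "<DUP>"),
    svtype = c(rep(NA, 7), "DUP"),
    end = c(rep(NA, 7), 72000),
    af = c(0, 0, 0.002, 0, 0.004, 5e-4, 0.2, 0),
    observed = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
    n_hom = c(0L, 0L, 0L, 0L, 1L, 0L, 10L, 0L),
    n_carriers = c(1L, 2L, 1L, 1L, 1L, 3L, 5L, 4L),
    in_unsolved = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  variants <- GRanges(vdf$chrom,
                      IRanges(vdf$pos, ifelse(is.na(vdf$end), vdf$pos, vdf$end)),
                      seqinfo = assembly)
  for (col in c("id", "ref", "alt", "svtype", "af", "observed", "n_hom",
                "n_carriers", "in_unsolved"))
    mcols(variants)[[col]] <- vdf[[col]]

  diseaseTable <- data.frame(gene = "GENE3", panel = "Eye",
                             phenotype = "rod dystrophy")

  background <- c(gr(40000, 40350), gr(80000, 80350))
  mcols(background)$name <- c("frag_1", "frag_2")

  flanks <- buildFlanks(ucnes, 200)
  cRuns <- c(granges(ucnes), flanks, granges(background))
  mcols(cRuns)$score <- c(rep(-1, length(ucnes)), rep(-0.5, length(flanks)),
                          rep(0.3, length(background)))
  constraint <- signalTrack(cRuns)

  vista <- c(gr(29900, 30500), gr(49900, 50500), gr(5000, 6000))
  mcols(vista)$label <- c("positive", "negative", "positive")
  mcols(vista)$tissues <- CharacterList(list(c("eye", "forebrain"),
                                             character(0), "eye"))

  structure(list(assembly = assembly, ucnes = ucnes, genes = genes,
                 dnase = dnase, scatac = scatac, chip = chip, tads = tads,
                 stageExpr = stageExpr, clusterExpr = clusterExpr,
                 linkages = linkages, variants = variants, vista = vista,
                 background = background, constraint = constraint,
                 diseaseTable = diseaseTable, truth = NULL,
                 config = NULL),
            class = "SimBundle")
}
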