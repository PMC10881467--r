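## Persisting and re-reading an input bundle as the plain-text formats the
## pipeline accepts, with a JSON manifest tying files to their labels.

.safeName <- function(x) gsub("[^A-Za-z0-9._-]", "-", x)

#' Write a bundle to a directory of plain-text pipeline inputs
#'
#' Emits chrom.sizes, BED, bedGraph and TSV files for every component plus a
#' `manifest.json` recording file roles and labels, so [loadBundle()] can
#' reconstruct the inputs. The in-memory truth table is not part of the file
#' bundle (it is generator metadata, not a pipeline input).
#'
#' @param bundle a `SimBundle` from [simulateBundle()] or
#'   [workedExampleBundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- list(files = list())
  sl <- seqlengths(bundle$assembly)
  write.table(data.frame(names(sl), as.integer(sl)),
              file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  man$files$assembly <- "chrom.sizes"
  writeBed(bundle$ucnes, file.path(dir, "ucnes.bed"))
  man$files$ucnes <- "ucnes.bed"
  writeGeneModels(bundle$genes, file.path(dir, "genes.tsv"))
  man$files$genes <- "genes.tsv"
  if (!is.null(bundle$tads)) {
    writeBed(bundle$tads, file.path(dir, "tads.bed"))
    man$files$tads <- "tads.bed"
  }
  if (!is.null(bundle$stageExpr)) {
    writeExpression(bundle$stageExpr, file.path(dir, "expr_stage.tsv"))
    man$files$stageExpr <- "expr_stage.tsv"
  }
  if (!is.null(bundle$clusterExpr)) {
    writeExpression(bundle$clusterExpr, file.path(dir, "expr_cluster.tsv"))
    man$files$clusterExpr <- "expr_cluster.tsv"
  }
  if (!is.null(bundle$linkages)) {
    df <- data.frame(chrom = as.character(seqnames(bundle$linkages)),
                     start = start(bundle$linkages) - 1L,
                     end = end(bundle$linkages),
                     gene = mcols(bundle$linkages)$gene,
                     correlation = mcols(bundle$linkages)$correlation)
    write.table(df, file.path(dir, "linkages.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    man$files$linkages <- "linkages.tsv"
  }
  if (!is.null(bundle$variants)) {
    writeVariants(bundle$variants, file.path(dir, "variants.tsv"))
    man$files$variants <- "variants.tsv"
  }
  if (!is.null(bundle$diseaseTable)) {
    write.table(bundle$diseaseTable, file.path(dir, "disease_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    man$files$diseaseTable <- "disease_genes.tsv"
  }
  if (!is.null(bundle$vista)) {
    df <- data.frame(chrom = as.character(seqnames(bundle$vista)),
                     start = start(bundle$vista) - 1L,
                     end = end(bundle$vista),
                     label = mcols(bundle$vista)$label,
                     tissues = vapply(mcols(bundle$vista)$tissues,
                                      paste, "", collapse = ";"))
    write.table(df, file.path(dir, "vista_labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    man$files$vista <- "vista_labels.tsv"
  }
  if (!is.null(bundle$background)) {
    writeBed(bundle$background, file.path(dir, "background.bed"))
    man$files$background <- "background.bed"
  }
  if (!is.null(bundle$constraint)) {
    writeBedGraph(bundle$constraint, file.path(dir, "constraint.bedgraph"))
    man$files$constraint <- "constraint.bedgraph"
  }
  man$dnase <- lapply(bundle$dnase, function(b) {
    f <- paste0("dnase_", .safeName(b$stage), ".bed")
    writeBed(b$payload, file.path(dir, f))
    list(file = f, stage = b$stage)
  })
  man$scatac <- lapply(bundle$scatac, function(b) {
    f <- paste0("scatac_", .safeName(b$cluster), ".bedgraph")
    writeBedGraph(b$payload, file.path(dir, f))
    list(file = f, cluster = b$cluster, stage = b$stage)
  })
  man$chip <- lapply(bundle$chip, function(b) {
    f <- paste0("chip_", .safeName(b$mark), "_", .safeName(b$stage), ".bedgraph")
    writeBedGraph(b$payload, file.path(dir, f))
    list(file = f, mark = b$mark, stage = b$stage)
  })
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Load a bundle written by [writeBundle()]
#'
#' Everything goes back through the strict format readers, so a loaded
#' bundle has been fully re-validated.
#'
#' @param dir directory containing `manifest.json`.
#' @return A list of class `SimBundle` (without a truth table).
#' @export
loadBundle <- function(dir) {
  manPath <- file.path(dir, "manifest.json")
  if (!file.exists(manPath))
    stop("missing upstream artifact: ", manPath,
         " (run the simulate step or writeBundle first)")
  man <- jsonlite::read_json(manPath)
  p <- function(f) file.path(dir, f)
  need <- function(slot) {
    f <- man$files[[slot]]
    if (is.null(f)) stop("bundle is missing required input: ", slot)
    p(f)
  }
  assembly <- readChromSizes(need("assembly"))
  bundle <- list(assembly = assembly,
                 ucnes = readBed(need("ucnes"), assembly),
                 genes = readGeneModels(need("genes"), assembly))
  if (!is.null(man$files$tads))
    bundle$tads <- readBed(p(man$files$tads), assembly)
  if (!is.null(man$files$stageExpr))
    bundle$stageExpr <- readExpression(p(man$files$stageExpr))
  if (!is.null(man$files$clusterExpr))
    bundle$clusterExpr <- readExpression(p(man$files$clusterExpr))
  if (!is.null(man$files$linkages))
    bundle$linkages <- readLinkages(p(man$files$linkages), assembly)
  if (!is.null(man$files$variants))
    bundle$variants <- readVariants(p(man$files$variants))
  if (!is.null(man$files$diseaseTable))
    bundle$diseaseTable <- readDiseaseTable(p(man$files$diseaseTable))
  if (!is.null(man$files$vista))
    bundle$vista <- readEnhancerLabels(p(man$files$vista), assembly)
  if (!is.null(man$files$background))
    bundle$background <- readBed(p(man$files$background), assembly)
  if (!is.null(man$files$constraint))
    bundle$constraint <- readBedGraph(p(man$files$constraint), assembly)
  bundle$dnase <- lapply(man$dnase, function(e) {
    trackBundle(readBed(p(e$file), assembly), stage = e$stage)
  })
  bundle$scatac <- lapply(man$scatac, function(e) {
    trackBundle(readBedGraph(p(e$file), assembly),
                cluster = e$cluster, stage = e$stage)
  })
  bundle$chip <- lapply(man$chip, function(e) {
    trackBundle(readBedGraph(p(e$file), assembly),
                mark = e$mark, stage = e$stage)
  })
  structure(bundle, class = "SimBundle")
}
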