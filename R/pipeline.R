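# Orchestration: file readers/writers for the standard formats and a
# deterministic multi-stage pipeline driven by a single config (R list or
# YAML file). All randomness flows from one global seed via fixed per-stage
# offsets.

#' Read gene models from a GFF3 file
#'
#' Thin wrapper around [rtracklayer::import()] that fails with an actionable
#' message naming the file, and validates that usable CDS-like ranges with a
#' gene identifier are present.
#'
#' @param path GFF3 file.
#' @return a [GenomicRanges::GRanges] with a `gene_id` metadata column.
#' @export
readGeneModels <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("failed to parse gene models from '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  if (!length(gr))
    stop("no gene models found in '", path, "'", call. = FALSE)
  if (is.null(gr$gene_id)) {
    if (!is.null(gr$ID)) gr$gene_id <- gr$ID
    else stop("gene models in '", path,
              "' carry neither gene_id nor ID attributes", call. = FALSE)
  }
  gr
}

#' Write gene models to GFF3
#' @param genes a [GenomicRanges::GRanges] with `gene_id`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeGeneModels <- function(genes, path) {
  genes$ID <- genes$gene_id
  if (is.null(genes$phase)) genes$phase <- 0L
  rtracklayer::export(genes, path, format = "gff3")
  invisible(path)
}

#' Read / write a tab-separated table
#'
#' TSV conventions used throughout the package: header line, tab separator,
#' no quoting, no row names.
#'
#' @param path file path.
#' @return `readTsv`: a data.frame.
#' @export
readTsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' @param x a data.frame.
#' @rdname readTsv
#' @return `writeTsv`: the path, invisibly.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default demonstration configuration for the pipeline
#'
#' A small but complete run: a 300-gene genome (4 planted promoters, a few
#' organellar genes), two 20,000-read libraries with planted fold changes,
#' six proteins with planted ratios, 24 gene trees, 20 cells per condition
#' and a miniature contig set.
#'
#' @param seed global seed; per-stage seeds are derived by fixed offsets.
#' @return a nested configuration list accepted by [runPipeline()].
#' @export
demoConfig <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    seed = seed,
    synth = list(
      n_genes = 300L, planted = c("g1", "g2", "g3", "g4"),
      motif = "ACACGTGC", motif_offset = 200L,
      n_chloroplast = 4L, n_mitochondrial = 4L,
      # named blocks are lists (not named vectors) so a YAML round trip
      # preserves the names
      library_sizes = list(fe_minus = 20000, fe_plus = 20000),
      fold_changes = list(g1 = 8, g2 = 6, g3 = 4, g4 = 4, g5 = 0.2, g6 = 0.25),
      proteins = list(
        FLDA1 = c("LITGAELK", "VAILGAAR", "GGSDWDNK"),
        ISIP1A = c("TLSEDFAK", "NPQGGFTR", "AELSVDGK"),
        PETE = c("GSDLAFDK", "VLSTPGEK", "TFEVALSN"),
        COX2B = c("EAPLSGYK", "DLTFDSYM", "IVTSADGR"),
        FBA4 = c("GILAADES", "TPSALAIK", "ENLKAASS"),
        RPL3 = c("SGVVGYVE", "TLAEKVDK", "MADLIAGG")
      ),
      true_ratios = list(FLDA1 = 4, ISIP1A = 6, PETE = 0.4, COX2B = 1.7,
                         FBA4 = 3, RPL3 = 0.8),
      n_trees = 24L, n_lgt = 20L,
      cells = list(fe_plus = list(5.9, 5.5), fe_minus = list(4.7, 7.0)),
      contig_lengths = c(12000, 15000, 20000, 8000, 5000, 3500, 2000, 1500,
                         1000, 800),
      read_coverage = 8.7
    ),
    ddge = list(alpha = 0.05, method = "parametric_bootstrap", n_boot = 499),
    protquant = list(distinctiveness = 2, fdr = 0.01, ppm = 5,
                     biomass_ratio = 0.5),
    promoscan = list(upstream_len = 500L, window = c(150L, 250L)),
    lgt = list(rooting = "midpoint", n_conserved = 10109L),
    physio = list(convention = "arithmetic_center")
  )
}

.stageSeed <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

#' Run the full synthetic-data pipeline
#'
#' Generates every synthetic input, runs all analysis stages in dependency
#' order, writes per-stage TSV/FASTA/GFF3/newick outputs plus truth ledgers
#' to `outDir`, and returns (and writes) a summary. Re-running with an
#' identical config is bit-identical for all outputs.
#'
#' @param config a configuration list as from [demoConfig()], or the path to
#'   a YAML file holding one.
#' @param outDir output directory (created if missing).
#' @return invisibly, a list with the stage results and the summary.
#' @examples
#' \donttest{
#' out <- runPipeline(demoConfig(seed = 7), file.path(tempdir(), "demo"))
#' out$summary$n_significant_genes
#' }
#' @export
runPipeline <- function(config = demoConfig(), outDir = "ironomics_run") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must provide a global seed")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  sy <- config$synth
  if (is.null(sy)) stop("config must provide a synth block")

  # --- synth -----------------------------------------------------------
  nG <- as.integer(sy$n_genes)
  ids <- paste0("g", seq_len(nG))
  comp <- rep("nuclear", nG)
  if (!is.null(sy$n_chloroplast) && sy$n_chloroplast > 0)
    comp[seq(nG - sy$n_chloroplast - sy$n_mitochondrial + 1L,
             nG - sy$n_mitochondrial)] <- "chloroplast"
  if (!is.null(sy$n_mitochondrial) && sy$n_mitochondrial > 0)
    comp[seq(nG - sy$n_mitochondrial + 1L, nG)] <- "mitochondrial"
  names(comp) <- ids
  genomeSpec <- SynthGenomeSpec(
    nGenes = nG, motif = sy$motif, motifOffset = sy$motif_offset,
    plantedGeneIds = sy$planted, compartments = comp,
    seed = .stageSeed(seed, 11L)
  )
  genome <- simulateGenome(genomeSpec)
  Biostrings::writeXStringSet(genome$genome, file.path(outDir, "genome.fasta"))
  writeGeneModels(genome$genes, file.path(outDir, "genes.gff3"))
  writeTsv(genome$truth, file.path(outDir, "truth_genome.tsv"))

  libSizes <- unlist(sy$library_sizes)
  weights <- stats::setNames(rep(1, nG), ids)
  countSpec <- SynthCountSpec(
    baselineWeights = weights, librarySizes = libSizes,
    foldChanges = unlist(sy$fold_changes), seed = .stageSeed(seed, 23L)
  )
  counts <- suppressMessages(simulateCounts(countSpec))
  counts$counts$compartment <- comp[counts$counts$gene_id]
  writeTsv(counts$counts, file.path(outDir, "counts.tsv"))
  writeTsv(counts$truth, file.path(outDir, "truth_counts.tsv"))

  psmSpec <- SynthPsmSpec(
    proteins = sy$proteins, trueRatios = unlist(sy$true_ratios),
    seed = .stageSeed(seed, 37L)
  )
  psms <- simulatePsms(psmSpec)
  writeTsv(psms$psms, file.path(outDir, "psms.tsv"))
  writeTsv(psms$truth, file.path(outDir, "truth_psms.tsv"))

  treeSim <- simulateLgtTrees(n = as.integer(sy$n_trees),
                              nLgt = as.integer(sy$n_lgt),
                              seed = .stageSeed(seed, 41L))
  ape::write.tree(treeSim$trees, file.path(outDir, "gene_trees.nwk"))
  writeTsv(treeSim$truth, file.path(outDir, "truth_trees.tsv"))
  writeTsv(treeSim$lineages, file.path(outDir, "lineages.tsv"))

  cellTables <- list()
  for (cond in names(sy$cells)) {
    dims <- unlist(sy$cells[[cond]])
    cellSpec <- SynthCellSpec(nCells = 20L, unitDiameter = dims[1],
                              unitLength = dims[2],
                              seed = .stageSeed(seed, 53L + match(cond, names(sy$cells))))
    cellTables[[cond]] <- simulateCells(cellSpec)$cells
    cellTables[[cond]]$condition <- cond
  }
  cells <- do.call(rbind, cellTables)
  writeTsv(cells, file.path(outDir, "cells.tsv"))

  # --- analysis stages -------------------------------------------------
  dd <- config$ddge
  de <- if (!is.null(dd)) {
    runDE(counts$counts, libSizes, alpha = dd$alpha, method = dd$method,
          nBoot = dd$n_boot, seed = .stageSeed(seed, 67L))
  } else {
    message("ddge block missing; stage skipped")
    NULL
  }
  if (!is.null(de)) writeTsv(as.data.frame(de), file.path(outDir, "de_results.tsv"))
  compartmentSummary <- do.call(rbind, lapply(
    c("nuclear", "chloroplast", "mitochondrial"),
    function(cc) suppressWarnings(aggregateCompartment(counts$counts, cc))
  ))
  writeTsv(compartmentSummary, file.path(outDir, "compartment_reads.tsv"))

  pq <- config$protquant
  prot <- if (!is.null(pq)) {
    suppressMessages(protquantPipeline(
      psms$psms, distinctiveness = pq$distinctiveness, fdrTarget = pq$fdr,
      maxPpm = pq$ppm, biomassScale = pq$biomass_ratio
    ))
  } else {
    message("protquant block missing; stage skipped")
    NULL
  }
  if (!is.null(prot))
    writeTsv(prot$ratios, file.path(outDir, "protein_ratios.tsv"))

  pr <- config$promoscan
  promoters <- extractPromoters(genome$genome, genome$genes,
                                upstreamLen = pr$upstream_len)
  hits <- scanMotif(promoters, sy$motif, window = pr$window)
  writeTsv(hits, file.path(outDir, "motif_hits.tsv"))

  lg <- config$lgt
  verdicts <- classifyTrees(treeSim$trees, treeSim$queries, treeSim$lineages,
                            rooting = lg$rooting)
  writeTsv(verdicts, file.path(outDir, "lgt_verdicts.tsv"))
  lgtSummary <- summarizeLgt(verdicts, lg$n_conserved)

  geometry <- lapply(split(cells[, c("diameter", "length")], cells$condition),
                     unitCellFromPopulation,
                     convention = config$physio$convention)
  geomTable <- do.call(rbind, lapply(names(geometry), function(cond) {
    g <- geometry[[cond]]
    data.frame(condition = cond, n_cells = g$nCells,
               mean_volume = g$meanVolume, unit_volume = g$unitVolume,
               surface_raw_mean = g$surfaceRawMean,
               unit_surface_from_volume = g$unitSurfaceFromVolume,
               stringsAsFactors = FALSE)
  }))
  writeTsv(geomTable, file.path(outDir, "cell_geometry.tsv"))

  asm <- assemblyStats(sy$contig_lengths,
                       coverages = rep(sy$read_coverage,
                                       length(sy$contig_lengths)),
                       totalReadBases = sum(sy$contig_lengths) *
                         sy$read_coverage)
  writeTsv(data.frame(asm), file.path(outDir, "assembly_stats.tsv"))

  summary <- list(
    seed = seed,
    n_genes = nG,
    n_significant_genes = if (!is.null(de)) sum(de$significant) else NA,
    n_motif_hits = nrow(hits),
    n_protein_groups = if (!is.null(prot)) nrow(prot$ratios) else NA,
    lgt_confirmed = lgtSummary$confirmed,
    lgt_confirmed_percent = lgtSummary$confirmedPercent,
    n50 = asm$n50
  )
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    genome = genome, counts = counts, de = de, prot = prot,
    promoterHits = hits, verdicts = verdicts, geometry = geometry,
    assembly = asm, summary = summary
  ))
}
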