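# Synthetic-data generators. Every generator takes a validated spec object,
# draws from a single seeded stream, and returns the planted truth alongside
# the data so downstream stages can be tested by parameter recovery.

.randSeq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.countOccurrences <- function(motif, s) {
  # overlapping occurrences included
  Biostrings::countPattern(motif, Biostrings::DNAString(s))
}

#' Simulate a genome with gene models and planted promoter motifs
#'
#' Builds one contig per gene: a promoter of `promoterLen` bases followed by
#' the gene body on the coding strand; minus-strand genes are stored as the
#' reverse complement so the GFF3-style coordinates exercise both strands.
#' Promoters of planted genes contain the motif exactly once at the
#' configured upstream offset; all other promoters are motif-free (rejection
#' sampling, counting overlapping occurrences too).
#'
#' @param spec a [SynthGenomeSpec-class] object.
#' @return a list with `genome` (a [Biostrings::DNAStringSet] of contigs),
#'   `genes` (a [GenomicRanges::GRanges] of CDS ranges with `gene_id` and
#'   `compartment` metadata; the translation start is the first base of the
#'   CDS on the coding strand) and `truth` (data.frame with the planted motif
#'   offsets, strands, compartments and the seed).
#' @examples
#' g <- simulateGenome(SynthGenomeSpec(5, plantedGeneIds = "g1", seed = 7))
#' g$truth
#' @export
simulateGenome <- function(spec) {
  stopifnot(is(spec, "SynthGenomeSpec"))
  validObject(spec)
  set.seed(spec@seed)
  P <- spec@promoterLen
  L <- spec@geneLen
  motif <- spec@motif
  ml <- nchar(motif)
  ids <- names(spec@compartments)
  strands <- sample(c("+", "-"), spec@nGenes, replace = TRUE)

  makePromoter <- function(planted) {
    if (!planted) {
      repeat {
        prom <- .randSeq(P)
        if (.countOccurrences(motif, prom) == 0L) return(prom)
      }
    }
    # motif 5' end at offset bases upstream of the translation start:
    # window index promoterLen - offset + 1
    i <- P - spec@motifOffset + 1L
    repeat {
      left <- if (i > 1L) .randSeq(i - 1L) else ""
      right <- if (i + ml - 1L < P) .randSeq(P - i - ml + 1L) else ""
      prom <- paste0(left, motif, right)
      if (.countOccurrences(motif, prom) == 1L) return(prom)
    }
  }

  seqs <- character(spec@nGenes)
  starts <- integer(spec@nGenes)
  ends <- integer(spec@nGenes)
  for (k in seq_len(spec@nGenes)) {
    prom <- makePromoter(ids[k] %in% spec@plantedGeneIds)
    coding <- paste0(prom, .randSeq(L))
    if (strands[k] == "+") {
      seqs[k] <- coding
      starts[k] <- P + 1L
      ends[k] <- P + L
    } else {
      seqs[k] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(coding))
      )
      starts[k] <- 1L
      ends[k] <- L
    }
  }

  contigs <- paste0("ctg_", ids)
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- contigs
  seqinfo <- GenomeInfoDb::Seqinfo(seqnames = contigs,
                                   seqlengths = Biostrings::width(genome))
  genes <- GenomicRanges::GRanges(
    seqnames = factor(contigs, levels = contigs),
    ranges = IRanges::IRanges(start = starts, end = ends),
    strand = strands,
    gene_id = ids,
    compartment = unname(spec@compartments),
    type = "CDS",
    seqinfo = seqinfo
  )
  truth <- data.frame(
    gene_id = ids,
    strand = strands,
    compartment = unname(spec@compartments),
    planted = ids %in% spec@plantedGeneIds,
    motif = ifelse(ids %in% spec@plantedGeneIds, motif, NA_character_),
    motif_offset = ifelse(ids %in% spec@plantedGeneIds,
                          spec@motifOffset, NA_integer_),
    seed = spec@seed,
    stringsAsFactors = FALSE
  )
  list(genome = genome, genes = genes, truth = truth)
}

#' Simulate per-gene read counts for two (or more) cDNA libraries
#'
#' Per library `i`, counts are one multinomial draw of size `N_i` with
#' per-gene probabilities proportional to the baseline weights, multiplied by
#' the planted fold change for the first (iron-limited) library. Column sums
#' equal the library sizes exactly. Genes without a configured fold change
#' get 1 (with a message).
#'
#' @param spec a [SynthCountSpec-class] object.
#' @return a list with `counts` (data.frame: `gene_id`, one count column per
#'   library, named `count_<library>`) and `truth` (the planted fold changes
#'   and baseline weights).
#' @examples
#' spec <- SynthCountSpec(c(g1 = 1, g2 = 1), c(fe_minus = 100, fe_plus = 100),
#'                        foldChanges = c(g2 = 4), seed = 3)
#' simulateCounts(spec)$counts
#' @export
simulateCounts <- function(spec) {
  stopifnot(is(spec, "SynthCountSpec"))
  validObject(spec)
  set.seed(spec@seed)
  w <- spec@baselineWeights
  ids <- names(w)
  fold <- rep(1, length(ids))
  names(fold) <- ids
  if (length(spec@foldChanges)) {
    known <- intersect(names(spec@foldChanges), ids)
    fold[known] <- spec@foldChanges[known]
  }
  missing <- setdiff(ids, names(spec@foldChanges))
  if (length(spec@foldChanges) && length(missing))
    message(length(missing), " gene(s) without fold change; treated as 1.0")

  counts <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  for (j in seq_along(spec@librarySizes)) {
    prob <- if (j == 1L) w * fold else w
    draw <- stats::rmultinom(1, size = spec@librarySizes[j], prob = prob)[, 1]
    counts[[paste0("count_", names(spec@librarySizes)[j])]] <- draw
  }
  truth <- data.frame(
    gene_id = ids, baseline_weight = unname(w), fold_change = unname(fold),
    seed = spec@seed, stringsAsFactors = FALSE
  )
  list(counts = counts, truth = truth)
}

#' Simulate peptide-spectrum match records with planted protein ratios
#'
#' Each protein contributes the configured number of distinct
#' (peptide, band, charge) combinations. The light (14N, iron-limited) over
#' heavy (15N, iron-replete) intensity ratio of each record is lognormal
#' around the planted ratio with the configured CV and median exactly at the
#' planted ratio, so median-based quantification is unbiased. Decoy records
#' are flagged, get `DECOY_` protein ids and E-values drawn from a strictly
#' worse (larger) distribution than targets.
#'
#' @param spec a [SynthPsmSpec-class] object.
#' @return a list with `psms` (data.frame with columns `spectrum_id`,
#'   `peptide`, `protein_ids`, `evalue`, `evalue_second_best`, `ppm_dev`,
#'   `band`, `charge`, `is_decoy`, `intensity_light`, `intensity_heavy`) and
#'   `truth` (planted per-protein ratios).
#' @export
simulatePsms <- function(spec) {
  stopifnot(is(spec, "SynthPsmSpec"))
  validObject(spec)
  set.seed(spec@seed)
  s <- sqrt(log(1 + spec@intensityCv^2))
  rows <- list()
  for (prot in names(spec@proteins)) {
    peps <- spec@proteins[[prot]]
    combos <- expand.grid(peptide = peps, charge = 2:4, band = 1:10,
                          stringsAsFactors = FALSE)
    combos <- combos[sample(nrow(combos)), , drop = FALSE]
    if (nrow(combos) < spec@nPbcPerProtein)
      stop("not enough distinct (peptide, band, charge) combinations for ", prot)
    combos <- combos[seq_len(spec@nPbcPerProtein), , drop = FALSE]
    n <- nrow(combos)
    heavy <- 1e6 * exp(stats::rnorm(n, 0, s))
    ratioNoise <- if (s > 0) exp(stats::rnorm(n, 0, s)) else rep(1, n)
    light <- heavy * spec@trueRatios[prot] * ratioNoise
    rows[[prot]] <- data.frame(
      peptide = combos$peptide,
      protein_ids = prot,
      band = combos$band,
      charge = combos$charge,
      is_decoy = FALSE,
      intensity_light = light,
      intensity_heavy = heavy,
      stringsAsFactors = FALSE
    )
  }
  psms <- do.call(rbind, rows)
  nTarget <- nrow(psms)
  nDecoy <- round(spec@decoyFraction * nTarget / (1 - spec@decoyFraction))
  if (nDecoy > 0) {
    decoys <- data.frame(
      peptide = replicate(nDecoy, paste(
        sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 9, replace = TRUE),
        collapse = "")),
      protein_ids = paste0("DECOY_", seq_len(nDecoy)),
      band = sample(1:10, nDecoy, replace = TRUE),
      charge = sample(2:4, nDecoy, replace = TRUE),
      is_decoy = TRUE,
      intensity_light = NA_real_,
      intensity_heavy = NA_real_,
      stringsAsFactors = FALSE
    )
    psms <- rbind(psms, decoys)
  }
  n <- nrow(psms)
  lo <- ifelse(psms$is_decoy, spec@evalueModel$decoy[1], spec@evalueModel$target[1])
  hi <- ifelse(psms$is_decoy, spec@evalueModel$decoy[2], spec@evalueModel$target[2])
  psms$evalue <- 10^stats::runif(n, lo, hi)
  # second-best candidate at least a factor 2 worse, so the default
  # distinctiveness filter is passed by clean synthetic records
  psms$evalue_second_best <- psms$evalue * 10^stats::runif(n, log10(2), 3)
  psms$ppm_dev <- if (spec@ppmNoiseSd > 0)
    stats::rnorm(n, 0, spec@ppmNoiseSd) else rep(0, n)
  psms$spectrum_id <- sprintf("spec%05d", seq_len(n))
  psms <- psms[, c("spectrum_id", "peptide", "protein_ids", "evalue",
                   "evalue_second_best", "ppm_dev", "band", "charge",
                   "is_decoy", "intensity_light", "intensity_heavy")]
  rownames(psms) <- NULL
  truth <- data.frame(
    protein_id = names(spec@trueRatios),
    true_ratio = unname(spec@trueRatios),
    seed = spec@seed, stringsAsFactors = FALSE
  )
  list(psms = psms, truth = truth)
}

#' Simulate a cylinder-model cell measurement table
#'
#' Diameters stay at the unit diameter (measurement noise only); lengths span
#' the unit length to twice the unit length according to the growth model,
#' reflecting a cell that grows by gradually doubling its height over the
#' cell cycle.
#'
#' @param spec a [SynthCellSpec-class] object.
#' @return a list with `cells` (data.frame: `cell_id`, `diameter`, `length`
#'   in micrometers) and `truth` (the unit dimensions and growth model).
#' @export
simulateCells <- function(spec) {
  stopifnot(is(spec, "SynthCellSpec"))
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@nCells
  s <- if (spec@noiseCv > 0) sqrt(log(1 + spec@noiseCv^2)) else 0
  noise <- function() if (s > 0) exp(stats::rnorm(n, 0, s)) else rep(1, n)
  factorLen <- switch(spec@growthModel,
    uniform_phase = stats::runif(n, 1, 2),
    exponential_age = {
      # age density 2 ln2 2^(-a) on [0,1]; inverse CDF of u = 2(1 - 2^-a)
      u <- stats::runif(n)
      2^(-log2(1 - u / 2))
    }
  )
  cells <- data.frame(
    cell_id = sprintf("cell%03d", seq_len(n)),
    diameter = spec@unitDiameter * noise(),
    length = spec@unitLength * factorLen * noise(),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    unit_diameter = spec@unitDiameter, unit_length = spec@unitLength,
    growth_model = spec@growthModel, noise_cv = spec@noiseCv,
    seed = spec@seed, stringsAsFactors = FALSE
  )
  list(cells = cells, truth = truth)
}

#' Simulate gene trees with controlled sister-clade composition
#'
#' Generates four-to-six-leaf gene trees for a stramenopile query species
#' whose sister clade is, by construction, either free of stramenopiles
#' (planted lateral-transfer topology), a pure stramenopile clade (vertical),
#' or a mix of both (unresolved). Branch lengths place the midpoint root on
#' the internal edge so the planted sister relationship survives rooting.
#'
#' @param n number of trees.
#' @param nLgt number of trees with a planted stramenopile-free sister.
#' @param nVertical number of trees with a planted pure-stramenopile sister;
#'   the remaining `n - nLgt - nVertical` trees get a mixed sister.
#' @param seed integer seed.
#' @return a list with `trees` (an [ape::multiPhylo] object), `queries`
#'   (query leaf label per tree), `truth` (planted verdict per tree) and
#'   `lineages` (a lineage map data.frame with `taxon`, `is_stramenopile`,
#'   `group` usable by [classifyTree()] and [besthitCensus()]).
#' @examples
#' sim <- simulateLgtTrees(n = 10, nLgt = 8, seed = 42)
#' table(sim$truth$planted_verdict)
#' @export
simulateLgtTrees <- function(n, nLgt, nVertical = 0L, seed = 1L) {
  stopifnot(nLgt + nVertical <= n)
  set.seed(as.integer(seed))
  stramPool <- c("Tpseudonana", "Ptricornutum", "Fcylindrus", "Aanophagefferens")
  donorPool <- c("Micromonas", "Ostreococcus", "Bacillus", "Synechococcus",
                 "Rhodobacter", "Chlamydomonas")
  verdicts <- sample(c(rep("lgt_confirmed", nLgt),
                       rep("vertical", nVertical),
                       rep("unresolved", n - nLgt - nVertical)))
  trees <- vector("list", n)
  queries <- character(n)
  for (k in seq_len(n)) {
    query <- sprintf("Toceanica|gene%03d", k)
    strams <- sample(stramPool, 3)
    donors <- sample(donorPool, 2)
    sister <- switch(verdicts[k],
      lgt_confirmed = sprintf("(%s:0.10,%s:0.12):0.05", donors[1], donors[2]),
      vertical = sprintf("(%s:0.10,%s:0.12):0.05", strams[2], strams[3]),
      unresolved = sprintf("(%s:0.10,%s:0.12):0.05", donors[1], strams[2])
    )
    nwk <- sprintf("((%s:0.08,%s:0.09):0.50,(%s:0.10,%s:0.11):0.50);",
                   query, sister, strams[1],
                   if (verdicts[k] == "vertical") donors[1] else strams[3])
    trees[[k]] <- ape::read.tree(text = nwk)
    queries[k] <- query
  }
  class(trees) <- "multiPhylo"
  lineages <- data.frame(
    taxon = c("Toceanica", stramPool, donorPool),
    is_stramenopile = c(TRUE, rep(TRUE, length(stramPool)),
                        rep(FALSE, length(donorPool))),
    group = c("stramenopile", rep("stramenopile", length(stramPool)),
              c("green alga", "green alga", "bacterium", "cyanobacterium",
                "bacterium", "green alga")),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    tree_id = seq_len(n), query = queries, planted_verdict = verdicts,
    seed = as.integer(seed), stringsAsFactors = FALSE
  )
  list(trees = trees, queries = queries, truth = truth, lineages = lineages)
}
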