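#' @import methods
NULL

#' Specification of a synthetic genome with planted promoter motifs
#'
#' Parameter object for [simulateGenome()]. One gene is placed on one contig,
#' with a promoter of `promoterLen` bases immediately 5' of the translation
#' start on the gene's coding strand. Genes listed in `plantedGeneIds` carry
#' `motif` exactly once, with its 5' end `motifOffset` bases upstream of the
#' translation start (offset n means the motif occupies positions
#' -n ... -n+|motif|-1, where -1 is the base adjacent to the start codon);
#' all other promoters are guaranteed motif-free by rejection sampling.
#'
#' @slot nGenes number of genes (one contig each).
#' @slot promoterLen promoter length in bases.
#' @slot geneLen gene body length in bases.
#' @slot motif DNA string over ACGT planted in selected promoters.
#' @slot motifOffset distance in bases from the translation start to the
#'   motif's 5' end.
#' @slot plantedGeneIds gene identifiers that receive the motif.
#' @slot compartments named character vector mapping gene id to one of
#'   `"nuclear"`, `"chloroplast"`, `"mitochondrial"`.
#' @slot seed integer seed; identical seeds give bit-identical output.
#'
#' @seealso [simulateGenome()]
#' @export
setClass("SynthGenomeSpec",
  representation(
    nGenes = "integer", promoterLen = "integer", geneLen = "integer",
    motif = "character", motifOffset = "integer",
    plantedGeneIds = "character", compartments = "character",
    seed = "integer"
  )
)

setValidity("SynthGenomeSpec", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@promoterLen < 1L) msg <- c(msg, "promoterLen must be >= 1")
  if (object@geneLen < 3L) msg <- c(msg, "geneLen must be >= 3")
  if (!grepl("^[ACGT]+$", object@motif))
    msg <- c(msg, "motif must be a non-empty string over ACGT")
  if (object@motifOffset + nchar(object@motif) > object@promoterLen)
    msg <- c(msg, "motif longer than promoter window: motifOffset + nchar(motif) must be <= promoterLen")
  if (nchar(object@motif) > object@motifOffset)
    msg <- c(msg, "motif must fit upstream of the translation start: nchar(motif) <= motifOffset")
  if (length(object@compartments) != object@nGenes)
    msg <- c(msg, "compartments must name every gene")
  if (!all(object@compartments %in% c("nuclear", "chloroplast", "mitochondrial")))
    msg <- c(msg, "compartments must be nuclear, chloroplast or mitochondrial")
  if (!all(object@plantedGeneIds %in% names(object@compartments)))
    msg <- c(msg, "all plantedGeneIds must be existing gene ids")
  if (length(msg)) msg else TRUE
})

#' @param nGenes,promoterLen,geneLen,motif,motifOffset,plantedGeneIds,compartments,seed
#'   see the corresponding slots.
#' @return a validated `SynthGenomeSpec` object.
#' @rdname SynthGenomeSpec-class
#' @examples
#' spec <- SynthGenomeSpec(nGenes = 10, plantedGeneIds = c("g1", "g2"))
#' @export
SynthGenomeSpec <- function(nGenes, promoterLen = 500L, geneLen = 300L,
                            motif = "ACACGTGC", motifOffset = 200L,
                            plantedGeneIds = character(),
                            compartments = NULL, seed = 1L) {
  nGenes <- as.integer(nGenes)
  ids <- paste0("g", seq_len(nGenes))
  if (is.null(compartments)) {
    compartments <- stats::setNames(rep("nuclear", nGenes), ids)
  }
  new("SynthGenomeSpec",
    nGenes = nGenes, promoterLen = as.integer(promoterLen),
    geneLen = as.integer(geneLen), motif = toupper(motif),
    motifOffset = as.integer(motifOffset),
    plantedGeneIds = as.character(plantedGeneIds),
    compartments = compartments, seed = as.integer(seed)
  )
}

#' Specification of synthetic two-library read counts
#'
#' Parameter object for [simulateCounts()]. Counts per library are drawn from
#' a multinomial with the configured total and per-gene probabilities
#' proportional to `baselineWeights`, multiplied by `foldChanges` for the
#' first (iron-limited) library. Column sums therefore equal the library
#' sizes exactly.
#'
#' @slot librarySizes named numeric of total reads per library; the first
#'   library is the Fe(-) (iron-limited) one and receives the fold changes.
#' @slot baselineWeights named positive weights, one per gene.
#' @slot foldChanges named Fe(-)/Fe(+) multipliers; missing genes default to 1.
#' @slot seed integer seed.
#' @export
setClass("SynthCountSpec",
  representation(
    librarySizes = "numeric", baselineWeights = "numeric",
    foldChanges = "numeric", seed = "integer"
  )
)

setValidity("SynthCountSpec", function(object) {
  msg <- character()
  if (length(object@librarySizes) < 2L || any(object@librarySizes <= 0))
    msg <- c(msg, "librarySizes must be >= 2 positive totals")
  if (!length(object@baselineWeights) || any(object@baselineWeights <= 0))
    msg <- c(msg, "baselineWeights must all be > 0")
  if (is.null(names(object@baselineWeights)))
    msg <- c(msg, "baselineWeights must be named by gene id")
  if (any(object@foldChanges < 0))
    msg <- c(msg, "foldChanges must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param librarySizes,baselineWeights,foldChanges,seed see the slots.
#' @return a validated `SynthCountSpec` object.
#' @rdname SynthCountSpec-class
#' @export
SynthCountSpec <- function(baselineWeights,
                           librarySizes = c(fe_minus = 95000, fe_plus = 95000),
                           foldChanges = numeric(), seed = 1L) {
  new("SynthCountSpec",
    librarySizes = librarySizes, baselineWeights = baselineWeights,
    foldChanges = foldChanges, seed = as.integer(seed)
  )
}

#' Specification of synthetic peptide-spectrum match records
#'
#' Parameter object for [simulatePsms()]. Each protein contributes
#' `nPbcPerProtein` distinct (peptide, band, charge) combinations whose
#' light/heavy intensity pair ratio is lognormal around the planted
#' Fe(-)/Fe(+) ratio with coefficient of variation `intensityCv` (the log
#' noise has median 1, so medians are unbiased). Decoy records are flagged
#' and drawn from an E-value distribution stochastically dominated below the
#' target distribution, so FDR thresholding is informative.
#'
#' @slot proteins named list: protein id -> character vector of peptides.
#' @slot trueRatios named planted Fe(-)/Fe(+) ratio per protein.
#' @slot nPbcPerProtein distinct PBC combinations per protein.
#' @slot decoyFraction fraction of all records that are decoys, in `[0, 1)`.
#' @slot evalueModel list with `target` and `decoy` log10 E-value ranges.
#' @slot ppmNoiseSd standard deviation of precursor mass deviation, ppm.
#' @slot intensityCv coefficient of variation of the pair ratio.
#' @slot seed integer seed.
#' @export
setClass("SynthPsmSpec",
  representation(
    proteins = "list", trueRatios = "numeric", nPbcPerProtein = "integer",
    decoyFraction = "numeric", evalueModel = "list",
    ppmNoiseSd = "numeric", intensityCv = "numeric", seed = "integer"
  )
)

setValidity("SynthPsmSpec", function(object) {
  msg <- character()
  if (!length(object@proteins) || is.null(names(object@proteins)))
    msg <- c(msg, "proteins must be a named list of peptide vectors")
  if (!all(names(object@proteins) %in% names(object@trueRatios)))
    msg <- c(msg, "every protein needs a planted ratio")
  if (any(object@trueRatios <= 0)) msg <- c(msg, "trueRatios must be > 0")
  if (object@decoyFraction < 0 || object@decoyFraction >= 1)
    msg <- c(msg, "decoyFraction must be in [0, 1)")
  if (object@nPbcPerProtein < 1L) msg <- c(msg, "nPbcPerProtein must be >= 1")
  if (object@intensityCv < 0) msg <- c(msg, "intensityCv must be >= 0")
  if (object@ppmNoiseSd < 0) msg <- c(msg, "ppmNoiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param proteins,trueRatios,nPbcPerProtein,decoyFraction,evalueModel,ppmNoiseSd,intensityCv,seed
#'   see the slots.
#' @return a validated `SynthPsmSpec` object.
#' @rdname SynthPsmSpec-class
#' @export
SynthPsmSpec <- function(proteins, trueRatios, nPbcPerProtein = 5L,
                         decoyFraction = 0.1,
                         evalueModel = list(target = c(-10, -4), decoy = c(-3, 0)),
                         ppmNoiseSd = 1, intensityCv = 0.1, seed = 1L) {
  new("SynthPsmSpec",
    proteins = proteins, trueRatios = trueRatios,
    nPbcPerProtein = as.integer(nPbcPerProtein),
    decoyFraction = decoyFraction, evalueModel = evalueModel,
    ppmNoiseSd = ppmNoiseSd, intensityCv = intensityCv,
    seed = as.integer(seed)
  )
}

#' Specification of a synthetic cell-measurement population
#'
#' Parameter object for [simulateCells()]. Cells are modeled as regular
#' cylinders that grow by a gradual two-fold increase of their height:
#' diameters stay at `unitDiameter` (up to measurement noise) while lengths
#' span `unitLength` to `2 * unitLength` according to the growth model.
#'
#' @slot nCells number of measured cells.
#' @slot unitDiameter diameter of a freshly divided cell, micrometers.
#' @slot unitLength height of a freshly divided cell, micrometers.
#' @slot growthModel `"uniform_phase"` (length factor uniform on `[1, 2]`) or
#'   `"exponential_age"` (age density `2 ln2 2^-a` on `[0, 1]`, factor `2^a`).
#' @slot noiseCv multiplicative measurement noise CV on both dimensions.
#' @slot seed integer seed.
#' @export
setClass("SynthCellSpec",
  representation(
    nCells = "integer", unitDiameter = "numeric", unitLength = "numeric",
    growthModel = "character", noiseCv = "numeric", seed = "integer"
  )
)

setValidity("SynthCellSpec", function(object) {
  msg <- character()
  if (object@nCells < 1L) msg <- c(msg, "nCells must be >= 1")
  if (object@unitDiameter <= 0 || object@unitLength <= 0)
    msg <- c(msg, "cell dimensions must be > 0")
  if (!object@growthModel %in% c("uniform_phase", "exponential_age"))
    msg <- c(msg, "growthModel must be uniform_phase or exponential_age")
  if (object@noiseCv < 0) msg <- c(msg, "noiseCv must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param nCells,unitDiameter,unitLength,growthModel,noiseCv,seed see the slots.
#' @return a validated `SynthCellSpec` object.
#' @rdname SynthCellSpec-class
#' @export
SynthCellSpec <- function(nCells = 20L, unitDiameter = 5.9, unitLength = 5.5,
                          growthModel = c("uniform_phase", "exponential_age"),
                          noiseCv = 0.02, seed = 1L) {
  new("SynthCellSpec",
    nCells = as.integer(nCells), unitDiameter = unitDiameter,
    unitLength = unitLength, growthModel = match.arg(growthModel),
    noiseCv = noiseCv, seed = as.integer(seed)
  )
}

setMethod("show", "SynthGenomeSpec", function(object) {
  cat("SynthGenomeSpec:", object@nGenes, "genes,",
      length(object@plantedGeneIds), "planted with", object@motif,
      "at offset", object@motifOffset, "| seed", object@seed, "\n")
})

setMethod("show", "SynthCountSpec", function(object) {
  cat("SynthCountSpec:", length(object@baselineWeights), "genes, libraries [",
      paste(names(object@librarySizes), object@librarySizes, collapse = ", "),
      "] | seed", object@seed, "\n")
})

setMethod("show", "SynthPsmSpec", function(object) {
  cat("SynthPsmSpec:", length(object@proteins), "proteins x",
      object@nPbcPerProtein, "PBCs, decoy fraction", object@decoyFraction,
      "| seed", object@seed, "\n")
})

setMethod("show", "SynthCellSpec", function(object) {
  cat("SynthCellSpec:", object@nCells, "cells, unit",
      object@unitDiameter, "x", object@unitLength, "um,",
      object@growthModel, "| seed", object@seed, "\n")
})
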