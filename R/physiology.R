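# Cylinder-model cell morphometry with "cellular unit" back-calculation,
# surface/volume comparisons, and delta-delta-Ct for RT-qPCR.

#' Closed-cylinder metrics for cell measurements
#'
#' Volume, surface and surface-to-volume ratio of a regular closed cylinder
#' (both caps included, matching the diatom valve-plus-girdle geometry):
#' `V = pi (d/2)^2 h`, `S = 2 pi (d/2)^2 + pi d h`.
#'
#' @param diameter,length cylinder dimensions in micrometers (vectorized).
#' @return data.frame with `volume` (um^3), `surface` (um^2) and `sv_ratio`
#'   (1/um).
#' @examples
#' cylinderMetrics(2, 1)          # V = pi, S = 4 pi, S/V = 4
#' cylinderMetrics(5.9, 5.5)      # iron-replete mean cell dimensions
#' @export
cylinderMetrics <- function(diameter, length) {
  stopifnot(all(diameter > 0), all(length > 0))
  r <- diameter / 2
  volume <- pi * r^2 * length
  surface <- 2 * pi * r^2 + pi * diameter * length
  data.frame(volume = volume, surface = surface, sv_ratio = surface / volume)
}

#' Back-calculate a population mean to the unit cell
#'
#' An unsynchronized population spans a factor-2 growth range of any
#' size-like parameter. Around the population mean we place a range whose
#' upper end is twice its lower end; the lower end is the "cellular unit"
#' (a freshly divided cell at the start of its cycle). Under the default
#' `arithmetic_center` convention the mean is the arithmetic center of
#' `[L, 2L]`, so `L = mean / 1.5`; `geometric_center` uses `L = mean /
#' sqrt(2)` instead.
#'
#' @param populationMean mean of the parameter over the population (> 0).
#' @param convention `"arithmetic_center"` (default) or `"geometric_center"`.
#' @return the unit-cell value, same units as the input.
#' @examples
#' unitCell(150.4)  # ~100: the unit volume of an iron-replete cell
#' unitCell(1.5)    # 1
#' @export
unitCell <- function(populationMean,
                     convention = c("arithmetic_center", "geometric_center")) {
  convention <- match.arg(convention)
  stopifnot(all(populationMean > 0))
  populationMean / switch(convention,
                          arithmetic_center = 1.5,
                          geometric_center = sqrt(2))
}

#' Unit-cell volume and surface from a measured population
#'
#' Applies [cylinderMetrics()] per cell, averages, and back-calculates the
#' mean volume to the unit cell via [unitCell()]. Because diameters do not
#' change over the cell cycle (growth doubles the height), the unit surface
#' is reported under two conventions without adjudication: the raw mean
#' surface (growth-range position unspecified), the mean surface divided by
#' 1.5, and a surface re-derived from the unit volume at the mean diameter.
#'
#' @param measures data.frame with `diameter` and `length` columns
#'   (micrometers).
#' @param convention back-calculation convention, see [unitCell()].
#' @return a list with `nCells`, `meanDiameter`, `meanLength`, `meanVolume`,
#'   `meanSurface`, `unitVolume`, `unitSurfaceDirect` (mean surface / 1.5),
#'   `surfaceRawMean` and `unitSurfaceFromVolume` (from the unit volume at
#'   the mean diameter). A single-cell table triggers a warning: the /1.5
#'   back-calculation assumes a population spread over the growth range.
#' @examples
#' pop <- simulateCells(SynthCellSpec(200, 5.9, 5.5, noiseCv = 0, seed = 1))
#' unitCellFromPopulation(pop$cells)$unitVolume  # ~ pi * 2.95^2 * 5.5
#' @export
unitCellFromPopulation <- function(measures,
                                   convention = c("arithmetic_center",
                                                  "geometric_center")) {
  convention <- match.arg(convention)
  if (!nrow(measures)) stop("empty measurement table")
  if (nrow(measures) == 1L)
    warning("unit-cell back-calculation from a single cell is biased: ",
            "the population-mean convention is applied verbatim")
  met <- cylinderMetrics(measures$diameter, measures$length)
  meanD <- mean(measures$diameter)
  meanV <- mean(met$volume)
  meanS <- mean(met$surface)
  unitV <- unitCell(meanV, convention)
  unitH <- unitV / (pi * (meanD / 2)^2)
  list(
    nCells = nrow(measures),
    meanDiameter = meanD,
    meanLength = mean(measures$length),
    meanVolume = meanV,
    meanSurface = meanS,
    unitVolume = unitV,
    unitSurfaceDirect = unitCell(meanS, convention),
    surfaceRawMean = meanS,
    unitSurfaceFromVolume = 2 * pi * (meanD / 2)^2 + pi * meanD * unitH
  )
}

#' Percent change between two surface-to-volume ratios
#'
#' @param svA,svB surface/volume ratios (1/um); `svB` is the reference.
#' @return `100 * (svA / svB - 1)`.
#' @examples
#' svChange(1.75, 1.22)  # ~43: the low-iron S/V increase
#' @export
svChange <- function(svA, svB) {
  stopifnot(svB > 0)
  100 * (svA / svB - 1)
}

#' Delta-delta-Ct from a qPCR threshold-cycle table
#'
#' For each gene and its housekeeping reference, computes per condition
#' `dCt = Ct(gene) - Ct(housekeeping)` and then
#' `ddCt = dCt at Fe(+) - dCt at Fe(-)`; positive values indicate
#' up-regulation at low iron. Replicate wells are averaged. Plate offsets
#' common to one condition's run cancel. Genes missing a condition (for
#' themselves or their reference) are skipped with a message.
#'
#' @param records data.frame with `gene_id`, `housekeeping_id`, `condition`
#'   (`"Fe_plus"` / `"Fe_minus"`) and `ct` (threshold cycles, > 0).
#'   Housekeeping genes appear as their own rows (`gene_id` equal to the
#'   housekeeping id).
#' @return data.frame with `gene_id`, `housekeeping_id`, `dct_plus`,
#'   `dct_minus`, `ddct`.
#' @examples
#' ct <- data.frame(gene_id = c("isip1", "isip1", "rpb1", "rpb1"),
#'                  housekeeping_id = "rpb1",
#'                  condition = c("Fe_plus", "Fe_minus", "Fe_plus", "Fe_minus"),
#'                  ct = c(25, 22, 20, 20))
#' ddct(ct)  # ddct = 5 - 2 = 3
#' @export
ddct <- function(records) {
  stopifnot(all(c("gene_id", "housekeeping_id", "condition", "ct")
                %in% names(records)))
  stopifnot(all(records$ct > 0))
  stopifnot(all(records$condition %in% c("Fe_plus", "Fe_minus")))
  ctOf <- function(gene, cond) {
    v <- records$ct[records$gene_id == gene & records$condition == cond]
    if (!length(v)) NA_real_ else mean(v)
  }
  pairs <- unique(records[records$gene_id != records$housekeeping_id,
                          c("gene_id", "housekeeping_id")])
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    g <- pairs$gene_id[k]
    hk <- pairs$housekeeping_id[k]
    cts <- c(ctOf(g, "Fe_plus"), ctOf(g, "Fe_minus"),
             ctOf(hk, "Fe_plus"), ctOf(hk, "Fe_minus"))
    if (anyNA(cts)) {
      message("skipping ", g, " (vs ", hk, "): missing condition")
      next
    }
    dctPlus <- cts[1] - cts[3]
    dctMinus <- cts[2] - cts[4]
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, housekeeping_id = hk,
      dct_plus = dctPlus, dct_minus = dctMinus,
      ddct = dctPlus - dctMinus, stringsAsFactors = FALSE
    )
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), housekeeping_id = character(),
                      dct_plus = numeric(), dct_minus = numeric(),
                      ddct = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
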