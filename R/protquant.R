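# 14N/15N metabolic-labeling proteomics: the filter cascade
# (distinctiveness -> target-decoy FDR -> ppm) applied to peptide-spectrum
# matches, parsimony protein-group inference, and the median-of-PBC
# Fe(-)/Fe(+) ratio per protein group. The cascade order is part of the
# contract; changing it changes the survivor set.

.splitIds <- function(x) strsplit(x, ";", fixed = TRUE)

#' Hit-distinctiveness filter for peptide-spectrum matches
#'
#' Retains matches whose second-best candidate is at least `threshold` times
#' worse than the best, measured as the E-value ratio
#' `evalue_second_best / evalue`. Matches with no recorded second-best
#' candidate are retained; records with non-positive E-values are dropped
#' with a message.
#'
#' @param psms PSM data.frame with `evalue` and `evalue_second_best`
#'   (NA if there was no second candidate).
#' @param threshold minimum second-best/best ratio (> 1).
#' @return the filtered data.frame.
#' @export
filterDistinctiveness <- function(psms, threshold = 2) {
  stopifnot(threshold > 1)
  bad <- psms$evalue <= 0 |
    (!is.na(psms$evalue_second_best) & psms$evalue_second_best <= 0)
  if (any(bad)) {
    message("dropping ", sum(bad), " record(s) with non-positive E-values")
    psms <- psms[!bad, , drop = FALSE]
  }
  ratio <- psms$evalue_second_best / psms$evalue
  keep <- is.na(ratio) | ratio >= threshold
  psms[keep, , drop = FALSE]
}

#' Target-decoy FDR filter with a dynamically determined E-value threshold
#'
#' Selects the largest E-value threshold `t` such that the decoy-estimated
#' false discovery rate, `#decoys(E <= t) / #targets(E <= t)`, does not
#' exceed `fdrTarget`, then returns the target matches at or below `t`
#' (decoys are excluded from the output). The estimate is the plain
#' decoy/target count ratio.
#'
#' @param psms PSM data.frame with `evalue` and logical `is_decoy`.
#' @param fdrTarget target false discovery rate (default 1%).
#' @return a list with `psms` (surviving targets), `threshold` (the chosen
#'   E-value cutoff, NA if none achieves the target) and `fdr` (the
#'   estimated FDR at the threshold). No achievable threshold gives an empty
#'   table with a warning.
#' @examples
#' tab <- data.frame(evalue = c(1e-6, 1e-5, 1e-4, 1e-3),
#'                   is_decoy = c(FALSE, FALSE, TRUE, FALSE))
#' filterFdr(tab, fdrTarget = 0.5)$threshold
#' @export
filterFdr <- function(psms, fdrTarget = 0.01) {
  stopifnot("is_decoy" %in% names(psms))
  if (!any(!psms$is_decoy)) stop("at least one target record is required")
  ord <- order(psms$evalue)
  ev <- psms$evalue[ord]
  dec <- psms$is_decoy[ord]
  cumDecoy <- cumsum(dec)
  cumTarget <- cumsum(!dec)
  # evaluate at the last index of each distinct E-value so ties are atomic
  lastOfValue <- !duplicated(ev, fromLast = TRUE)
  fdr <- ifelse(cumTarget == 0, Inf, cumDecoy / cumTarget)
  ok <- which(lastOfValue & fdr <= fdrTarget)
  if (!length(ok)) {
    warning("no E-value threshold achieves FDR <= ", fdrTarget)
    return(list(psms = psms[0, , drop = FALSE],
                threshold = NA_real_, fdr = NA_real_))
  }
  cut <- max(ok)
  threshold <- ev[cut]
  keep <- !psms$is_decoy & psms$evalue <= threshold
  list(psms = psms[keep, , drop = FALSE],
       threshold = threshold, fdr = fdr[cut])
}

#' Precursor mass accuracy filter
#'
#' Retains matches whose absolute precursor mass deviation is at most
#' `maxPpm` parts per million (the boundary is inclusive; deviations
#' strictly greater than the limit are discarded).
#'
#' @param psms PSM data.frame with `ppm_dev`.
#' @param maxPpm maximum absolute deviation in ppm.
#' @return the filtered data.frame.
#' @export
filterPpm <- function(psms, maxPpm = 5) {
  stopifnot("ppm_dev" %in% names(psms))
  psms[abs(psms$ppm_dev) <= maxPpm, , drop = FALSE]
}

#' Parsimony protein-group inference from surviving peptides
#'
#' Proteins with identical surviving peptide sets are merged into one group;
#' a protein whose peptide set is a strict subset of another's is absorbed
#' into that protein's group. Peptides shared between remaining groups are
#' assigned to all containing groups but flagged as non-unique.
#'
#' @param psms PSM data.frame with `peptide` and `protein_ids`
#'   (`;`-separated when a peptide maps to several proteins).
#' @return a list with `groups` (data.frame: `group_id`, `proteins`,
#'   `peptides`, `n_proteins`, `n_peptides`) and `peptideMap` (data.frame:
#'   `peptide`, `group_id`, `unique`).
#' @export
inferProteinGroups <- function(psms) {
  stopifnot(all(c("peptide", "protein_ids") %in% names(psms)))
  pairs <- unique(data.frame(
    peptide = rep(psms$peptide, lengths(.splitIds(psms$protein_ids))),
    protein = unlist(.splitIds(psms$protein_ids)),
    stringsAsFactors = FALSE
  ))
  pepSets <- split(pairs$peptide, pairs$protein)
  pepSets <- lapply(pepSets, function(p) sort(unique(p)))
  # largest sets first so subsets meet their superset before being kept
  ordNames <- names(pepSets)[order(-lengths(pepSets), names(pepSets))]
  groupProteins <- list()
  groupPeps <- list()
  for (prot in ordNames) {
    set <- pepSets[[prot]]
    placed <- FALSE
    for (gi in seq_along(groupPeps)) {
      if (all(set %in% groupPeps[[gi]])) {
        groupProteins[[gi]] <- c(groupProteins[[gi]], prot)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      groupProteins[[length(groupProteins) + 1L]] <- prot
      groupPeps[[length(groupPeps) + 1L]] <- set
    }
  }
  groups <- data.frame(
    group_id = sprintf("grp%03d", seq_along(groupPeps)),
    proteins = vapply(groupProteins, function(p) paste(sort(p), collapse = ";"), ""),
    peptides = vapply(groupPeps, paste, "", collapse = ";"),
    n_proteins = lengths(groupProteins),
    n_peptides = lengths(groupPeps),
    stringsAsFactors = FALSE
  )
  pepGroup <- data.frame(
    peptide = unlist(groupPeps),
    group_id = rep(groups$group_id, lengths(groupPeps)),
    stringsAsFactors = FALSE
  )
  shared <- names(which(table(pepGroup$peptide) > 1L))
  pepGroup$unique <- !(pepGroup$peptide %in% shared)
  list(groups = groups, peptideMap = pepGroup)
}

#' Fe(-)/Fe(+) ratios per (peptide, band, charge) combination
#'
#' Groups quantified spectra by the PBC key and forms one ratio per
#' combination as mean light over mean heavy intensity, oriented
#' Fe(-)/Fe(+) under the default labeling (heavy 15N = iron-replete;
#' set `heavyIsFePlus = FALSE` for the inverted labeling). Duplicate spectra
#' within a PBC collapse before ratio formation. Records with zero heavy
#' intensity are dropped with a message.
#'
#' @param psms PSM data.frame with `peptide`, `band`, `charge`,
#'   `intensity_light`, `intensity_heavy`.
#' @param heavyIsFePlus logical labeling orientation flag.
#' @return data.frame with `peptide`, `band`, `charge`, `ratio`, `n_spectra`.
#' @export
pbcRatios <- function(psms, heavyIsFePlus = TRUE) {
  quant <- psms[!is.na(psms$intensity_light) & !is.na(psms$intensity_heavy), ,
                drop = FALSE]
  bad <- quant$intensity_heavy == 0 | quant$intensity_light == 0
  if (any(bad)) {
    message("dropping ", sum(bad), " record(s) with zero intensity")
    quant <- quant[!bad, , drop = FALSE]
  }
  if (!nrow(quant))
    return(data.frame(peptide = character(), band = integer(),
                      charge = integer(), ratio = numeric(),
                      n_spectra = integer(), stringsAsFactors = FALSE))
  key <- interaction(quant$peptide, quant$band, quant$charge, drop = TRUE)
  agg <- lapply(split(quant, key), function(d) {
    r <- mean(d$intensity_light) / mean(d$intensity_heavy)
    data.frame(peptide = d$peptide[1], band = d$band[1], charge = d$charge[1],
               ratio = if (heavyIsFePlus) r else 1 / r,
               n_spectra = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Median and interquartile range of PBC ratios per protein group
#'
#' Combines the PBC ratios of each group's member peptides into a total
#' protein-group ratio: the median, with first and third quartiles under the
#' linear-interpolation quantile convention ([stats::quantile()] type 7,
#' fixed so results are reproducible bit-exact).
#'
#' @param pbc PBC ratio table from [pbcRatios()].
#' @param grouping result of [inferProteinGroups()] (uses its `peptideMap`).
#' @param uniqueOnly if TRUE, only peptides unique to one group contribute.
#' @return data.frame with `group_id`, `proteins`, `median_ratio`, `q1`,
#'   `q3`, `n_pbc`; groups without any quantified PBC are excluded.
#' @export
proteinRatios <- function(pbc, grouping, uniqueOnly = FALSE) {
  map <- grouping$peptideMap
  if (uniqueOnly) map <- map[map$unique, , drop = FALSE]
  merged <- merge(pbc, map, by = "peptide")
  if (!nrow(merged))
    return(data.frame(group_id = character(), proteins = character(),
                      median_ratio = numeric(), q1 = numeric(), q3 = numeric(),
                      n_pbc = integer(), stringsAsFactors = FALSE))
  agg <- lapply(split(merged, merged$group_id), function(d) {
    q <- stats::quantile(d$ratio, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group_id = d$group_id[1],
               median_ratio = q[2], q1 = q[1], q3 = q[3],
               n_pbc = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- merge(grouping$groups[, c("group_id", "proteins")], out,
               by = "group_id")
  rownames(out) <- NULL
  out
}

#' Rescale an equal-protein ratio to a per-cell ("cellular unit") ratio
#'
#' Mass-spectrometry ratios refer to equal amounts of total protein in the
#' two conditions. Multiplying by the Fe(-)/Fe(+) cellular protein biomass
#' ratio (from a BCA assay; 0.5 when iron-limited cells hold half the
#' protein) converts them to a per-cell scale.
#'
#' @param ratio equal-protein Fe(-)/Fe(+) ratio(s).
#' @param biomassScale Fe(-)/Fe(+) protein biomass ratio (> 0).
#' @return the per-cell ratio(s).
#' @examples
#' scaleToCellularUnit(1.7, 0.5)  # 0.85
#' @export
scaleToCellularUnit <- function(ratio, biomassScale) {
  stopifnot(biomassScale > 0)
  ratio * biomassScale
}

#' Full proteomics quantification chain
#'
#' Applies the filter cascade in its fixed order (distinctiveness, then
#' target-decoy FDR, then ppm), infers parsimony protein groups, forms PBC
#' ratios and aggregates them into per-group median ratios, optionally
#' rescaled to the cellular unit.
#'
#' @param psms raw PSM table (see [simulatePsms()] for the columns).
#' @param distinctiveness,fdrTarget,maxPpm cascade parameters.
#' @param heavyIsFePlus labeling orientation, see [pbcRatios()].
#' @param biomassScale optional Fe(-)/Fe(+) biomass ratio for per-cell
#'   rescaling.
#' @return a list with `psms` (survivors), `evalueThreshold`, `estimatedFdr`,
#'   `grouping`, `pbc` and `ratios` (with a `per_cell_ratio` column when a
#'   biomass scale is given).
#' @export
protquantPipeline <- function(psms, distinctiveness = 2, fdrTarget = 0.01,
                              maxPpm = 5, heavyIsFePlus = TRUE,
                              biomassScale = NULL) {
  step1 <- filterDistinctiveness(psms, distinctiveness)
  step2 <- filterFdr(step1, fdrTarget)
  step3 <- filterPpm(step2$psms, maxPpm)
  grouping <- inferProteinGroups(step3)
  pbc <- pbcRatios(step3, heavyIsFePlus = heavyIsFePlus)
  ratios <- proteinRatios(pbc, grouping)
  if (!is.null(biomassScale))
    ratios$per_cell_ratio <- scaleToCellularUnit(ratios$median_ratio,
                                                 biomassScale)
  list(psms = step3, evalueThreshold = step2$threshold,
       estimatedFdr = step2$fdr, grouping = grouping, pbc = pbc,
       ratios = ratios)
}
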