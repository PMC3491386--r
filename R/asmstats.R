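# Assembly summary statistics and the coverage-based genome-size estimate.

#' N50 of a contig length distribution
#'
#' The largest length `L` such that contigs of length at least `L` together
#' contain at least half of the total assembly length (ties resolved with
#' ">= half", per the standard definition).
#'
#' @param lengths positive contig lengths in bases.
#' @return the N50 in bases.
#' @examples
#' n50(c(10, 6, 5, 3))  # 6
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("empty length list")
  stopifnot(all(lengths > 0))
  sorted <- sort(lengths, decreasing = TRUE)
  sorted[which(cumsum(sorted) >= sum(sorted) / 2)[1]]
}

#' Coverage-based haploid genome-size estimate
#'
#' Long contigs are the least collapsed/redundant part of an assembly, so
#' the median of their per-contig coverages estimates the true sequencing
#' depth; dividing the total sequenced bases by it estimates the haploid
#' genome size.
#'
#' @param totalReadBases total sequenced bases.
#' @param lengths contig lengths in bases.
#' @param coverages per-contig median coverage, aligned with `lengths`.
#' @param minLen minimum contig length entering the median (default 10 kb).
#' @return a list with `medianCoverage`, `nLongContigs` and `genomeSize`
#'   (bases).
#' @examples
#' estimateGenomeSize(90e6, c(2e4, 3e4, 5e4), c(8, 9, 10))$genomeSize
#' @export
estimateGenomeSize <- function(totalReadBases, lengths, coverages,
                               minLen = 10000) {
  stopifnot(length(lengths) == length(coverages), totalReadBases > 0)
  long <- lengths >= minLen & !is.na(coverages)
  if (!any(long)) stop("no contig of length >= ", minLen, " with coverage")
  med <- stats::median(coverages[long])
  list(medianCoverage = med, nLongContigs = sum(long),
       genomeSize = totalReadBases / med)
}

#' Assembly summary statistics
#'
#' @param lengths contig lengths in bases.
#' @param coverages optional per-contig coverages.
#' @param totalReadBases optional total sequenced bases, enabling the
#'   genome-size estimate.
#' @param minLen long-contig cutoff for the coverage median.
#' @return a list with `nContigs`, `totalLen`, `n50` and, when coverage
#'   information is available, `longContigMedianCov` and `estGenomeSize`.
#' @export
assemblyStats <- function(lengths, coverages = NULL, totalReadBases = NULL,
                          minLen = 10000) {
  out <- list(nContigs = length(lengths), totalLen = sum(lengths),
              n50 = n50(lengths))
  if (!is.null(coverages) && !is.null(totalReadBases)) {
    est <- estimateGenomeSize(totalReadBases, lengths, coverages, minLen)
    out$longContigMedianCov <- est$medianCoverage
    out$estGenomeSize <- est$genomeSize
  }
  out
}
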