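# Differential digital gene expression between cDNA libraries of known
# sizes, using the log-likelihood ratio heterogeneity statistic of Stekel,
# Git & Falciani with a parametric-bootstrap (default) or chi-square null.

.stekelTerms <- function(x, expected) {
  out <- numeric(length(x))
  nz <- x > 0
  out[nz] <- x[nz] * log(x[nz] / expected[nz])
  out
}

#' Stekel log-likelihood ratio statistic for one gene
#'
#' Measures heterogeneity of a gene's read counts `x_i` across libraries of
#' total sizes `N_i`. With the pooled proportion `p = sum(x) / sum(N)` and
#' expectations `xhat_i = N_i * p`, the statistic is
#' `R = sum_i x_i * ln(x_i / xhat_i)` with the convention `0 * ln 0 = 0`.
#' `R = 0` exactly when all per-library proportions are equal, and `R` is
#' invariant under permutation of the libraries.
#'
#' @param counts integer read counts, one per library.
#' @param librarySizes total reads per library, aligned with `counts`.
#' @return the statistic `R` (non-negative).
#' @examples
#' stekelR(c(10, 0), c(100, 100))   # 10 * log(2)
#' stekelR(c(3, 9), c(10, 10))      # ~1.5702
#' @export
stekelR <- function(counts, librarySizes) {
  if (length(counts) != length(librarySizes))
    stop("counts and librarySizes must be aligned")
  if (length(counts) < 2L) stop("at least two libraries are required")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(librarySizes <= 0)) stop("library sizes must be positive")
  if (any(counts > librarySizes)) stop("counts cannot exceed library sizes")
  if (all(counts == 0)) {
    warning("all counts are zero; R = 0")
    return(0)
  }
  phat <- sum(counts) / sum(librarySizes)
  sum(.stekelTerms(counts, librarySizes * phat))
}

# vectorized over genes: X is a genes x libraries matrix
.stekelRMatrix <- function(X, librarySizes) {
  phat <- rowSums(X) / sum(librarySizes)
  expected <- outer(phat, librarySizes)
  terms <- X * log(X / expected)
  terms[X == 0] <- 0
  rowSums(terms)
}

#' Null calibration of the Stekel R statistic
#'
#' Converts an observed statistic into a p-value. `"chi2"` uses the upper
#' tail of a chi-square distribution with `m - 1` degrees of freedom
#' evaluated at `2 R` (fast large-count approximation). The default
#' `"parametric_bootstrap"` redraws each library's count as
#' `Binomial(N_i, phat)` and reports the fraction of replicates with
#' `R* >= R`, with the `(k + 1) / (n + 1)` correction; it is preferred
#' because the chi-square approximation is anticonservative at small counts.
#'
#' @param counts,librarySizes as in [stekelR()].
#' @param method `"parametric_bootstrap"` or `"chi2"`.
#' @param nBoot bootstrap replicates (at least 100).
#' @param seed optional integer seed for the bootstrap.
#' @return a p-value in `(0, 1]`.
#' @examples
#' calibrateSignificance(c(10, 0), c(100, 100), method = "chi2")
#' @export
calibrateSignificance <- function(counts, librarySizes,
                                  method = c("parametric_bootstrap", "chi2"),
                                  nBoot = 999, seed = NULL) {
  method <- match.arg(method)
  R <- suppressWarnings(stekelR(counts, librarySizes))
  m <- length(librarySizes)
  if (method == "chi2")
    return(stats::pchisq(2 * R, df = m - 1, lower.tail = FALSE))
  if (nBoot < 100) stop("nBoot must be at least 100")
  if (!is.null(seed)) set.seed(as.integer(seed))
  phat <- sum(counts) / sum(librarySizes)
  draws <- matrix(
    stats::rbinom(nBoot * m, size = rep(librarySizes, each = nBoot), prob = phat),
    nrow = nBoot
  )
  Rstar <- .stekelRMatrix(draws, librarySizes)
  (1 + sum(Rstar >= R - 1e-12)) / (nBoot + 1)
}

#' Differential expression over a two-library count table
#'
#' Computes the Stekel R statistic, a p-value (bootstrap by default), a
#' Benjamini-Hochberg adjusted p-value and a direction call for every gene.
#' The first library is the iron-limited Fe(-) one by orientation convention:
#' `up_at_low_iron` means the Fe(-) read proportion exceeds the Fe(+) one.
#' Genes absent from one library are kept (a zero count is informative).
#'
#' @param table data.frame with a `gene_id` column and one count column per
#'   library named `count_<library>` for the names of `librarySizes`
#'   (e.g. `count_fe_minus`, `count_fe_plus`).
#' @param librarySizes named totals per library, iron-limited first.
#' @param alpha significance level for the `significant` flag (on the
#'   adjusted p-value).
#' @param method,nBoot,seed as in [calibrateSignificance()].
#' @param mtMethod multiple-testing method for [stats::p.adjust()].
#' @return a [S4Vectors::DataFrame] sorted by decreasing `R` with columns
#'   `gene_id`, `R`, `p_raw`, `p_adj`, `direction`, `significant` and one
#'   proportion column per library.
#' @examples
#' tab <- data.frame(gene_id = c("a", "b"),
#'                   count_fe_minus = c(30, 10), count_fe_plus = c(10, 10))
#' runDE(tab, c(fe_minus = 1000, fe_plus = 1000), method = "chi2")
#' @export
runDE <- function(table, librarySizes, alpha = 0.05,
                  method = c("parametric_bootstrap", "chi2"),
                  nBoot = 999, mtMethod = "BH", seed = NULL) {
  method <- match.arg(method)
  if (anyDuplicated(table$gene_id))
    stop("duplicate gene ids in count table")
  cols <- paste0("count_", names(librarySizes))
  if (!all(cols %in% names(table)))
    stop("count table must contain columns: ", paste(cols, collapse = ", "))
  X <- as.matrix(table[, cols, drop = FALSE])
  if (any(X < 0)) stop("negative counts are not allowed")
  m <- length(librarySizes)
  N <- unname(librarySizes)
  R <- .stekelRMatrix(X, N)
  R[rowSums(X) == 0] <- 0

  if (method == "chi2") {
    p <- stats::pchisq(2 * R, df = m - 1, lower.tail = FALSE)
  } else {
    if (nBoot < 100) stop("nBoot must be at least 100")
    if (!is.null(seed)) set.seed(as.integer(seed))
    p <- vapply(seq_len(nrow(X)), function(i) {
      phat <- sum(X[i, ]) / sum(N)
      draws <- matrix(
        stats::rbinom(nBoot * m, size = rep(N, each = nBoot), prob = phat),
        nrow = nBoot
      )
      Rstar <- .stekelRMatrix(draws, N)
      (1 + sum(Rstar >= R[i] - 1e-12)) / (nBoot + 1)
    }, numeric(1))
  }

  props <- sweep(X, 2, N, "/")
  colnames(props) <- paste0("prop_", names(librarySizes))
  direction <- unname(ifelse(
    abs(props[, 1] - props[, 2]) < .Machine$double.eps * 4, "flat",
    ifelse(props[, 1] > props[, 2], "up_at_low_iron", "down_at_low_iron")
  ))
  res <- S4Vectors::DataFrame(
    gene_id = table$gene_id, R = R, p_raw = p,
    p_adj = stats::p.adjust(p, method = mtMethod),
    direction = direction,
    significant = stats::p.adjust(p, method = mtMethod) <= alpha,
    props
  )
  res[order(res$R, decreasing = TRUE), ]
}

#' Aggregate read counts over a genomic compartment
#'
#' Sums the per-library reads of all genes in one compartment (for example
#' all chloroplast-encoded contigs) and reports the Fe(-)/Fe(+) total-read
#' ratio, the quantity used to describe organellar transcriptional activity.
#'
#' @param table count data.frame with `gene_id`, count columns and a
#'   `compartment` column.
#' @param compartment compartment label to aggregate.
#' @param countCols count column names; defaults to all `count_*` columns,
#'   iron-limited first.
#' @return a one-row data.frame with the compartment, per-library totals and
#'   `ratio_fe_minus_over_fe_plus` (NA with a warning for an empty
#'   compartment).
#' @examples
#' tab <- data.frame(gene_id = c("rbcL", "psbA"),
#'                   count_fe_minus = c(1000, 1026),
#'                   count_fe_plus = c(7000, 7931),
#'                   compartment = "chloroplast")
#' aggregateCompartment(tab, "chloroplast")
#' @export
aggregateCompartment <- function(table, compartment, countCols = NULL) {
  if (is.null(countCols))
    countCols <- grep("^count_", names(table), value = TRUE)
  stopifnot(length(countCols) >= 2L, "compartment" %in% names(table))
  members <- table[table$compartment == compartment, countCols, drop = FALSE]
  totals <- colSums(members)
  if (nrow(members) == 0L) {
    warning("compartment '", compartment, "' is empty; ratio undefined")
    ratio <- NA_real_
  } else if (totals[2] == 0) {
    warning("no Fe(+) reads in compartment '", compartment, "'; ratio undefined")
    ratio <- NA_real_
  } else {
    ratio <- unname(totals[1] / totals[2])
  }
  out <- data.frame(compartment = compartment, n_genes = nrow(members),
                    stringsAsFactors = FALSE)
  for (cc in countCols) out[[paste0("total_", sub("^count_", "", cc))]] <- unname(totals[cc])
  out$ratio_fe_minus_over_fe_plus <- ratio
  out
}
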