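# Independent brute-force oracles used to cross-check the implementation.
# Each is written as plainly as possible and shares no code with the
# package internals it checks.

# 2x2 G-statistic (gene vs remainder x library), summed over all four cells
bruteForceG <- function(x, N) {
  obs <- rbind(x, N - x)
  total <- sum(obs)
  g <- 0
  for (i in 1:2) {
    for (j in seq_along(x)) {
      e <- sum(obs[i, ]) * sum(obs[, j]) / total
      if (obs[i, j] > 0) g <- g + 2 * obs[i, j] * log(obs[i, j] / e)
    }
  }
  unname(g)
}

# resampling p-value for the Stekel statistic computed with its own,
# independently written statistic evaluation
bruteForceBootstrapP <- function(x, N, nBoot, seed) {
  set.seed(seed)
  statOf <- function(counts) {
    p <- sum(counts) / sum(N)
    s <- 0
    for (i in seq_along(counts)) {
      if (counts[i] > 0) s <- s + counts[i] * log(counts[i] / (N[i] * p))
    }
    s
  }
  obs <- statOf(x)
  phat <- sum(x) / sum(N)
  hits <- 0
  for (b in seq_len(nBoot)) {
    draw <- vapply(N, function(n) rbinom(1, n, phat), numeric(1))
    if (statOf(draw) >= obs - 1e-12) hits <- hits + 1
  }
  (1 + hits) / (nBoot + 1)
}

# scan every candidate E-value cut point for the largest one meeting the FDR
bruteForceFdrThreshold <- function(evalues, isDecoy, target) {
  best <- NA_real_
  for (t in sort(unique(evalues))) {
    nd <- sum(isDecoy & evalues <= t)
    nt <- sum(!isDecoy & evalues <= t)
    if (nt > 0 && nd / nt <= target) best <- t
  }
  best
}

# iterate identical-set merge and subset absorption to a fixed point and
# count the remaining maximal peptide sets
bruteForceGroupCount <- function(pepSets) {
  sets <- lapply(pepSets, function(p) sort(unique(p)))
  repeat {
    n <- length(sets)
    drop <- rep(FALSE, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && !drop[i] && !drop[j] &&
            all(sets[[i]] %in% sets[[j]])) {
          # i is a (possibly equal) subset of j; absorb the later index
          if (length(sets[[i]]) < length(sets[[j]]) || i > j) drop[i] <- TRUE
        }
      }
    }
    if (!any(drop)) break
    sets <- sets[!drop]
  }
  length(sets)
}

# enumerate every k-mer and every candidate center in the window; a k-mer
# qualifies when each promoter has an occurrence within the tolerance
bruteForceConservedKmers <- function(proms, k, window, tol) {
  kmersOf <- function(s) {
    L <- nchar(s)
    starts <- seq_len(L - k + 1)
    data.frame(kmer = substring(s, starts, starts + k - 1),
               offset = L - starts + 1, stringsAsFactors = FALSE)
  }
  occ <- lapply(proms, kmersOf)
  allK <- unique(unlist(lapply(occ, function(d) d$kmer)))
  found <- character()
  for (km in allK) {
    ok <- FALSE
    for (center in seq(window[1], window[2])) {
      hit <- vapply(occ, function(d) {
        any(d$kmer == km & abs(d$offset - center) <= tol)
      }, logical(1))
      if (all(hit)) {
        ok <- TRUE
        break
      }
    }
    if (ok) found <- c(found, km)
  }
  sort(found)
}

# exhaustive N50: try every candidate length L
bruteForceN50 <- function(lengths) {
  best <- NA_real_
  for (L in sort(unique(lengths))) {
    if (sum(lengths[lengths >= L]) >= sum(lengths) / 2) best <- L
  }
  best
}

makeCountTable <- function(counts) {
  data.frame(gene_id = paste0("g", seq_len(nrow(counts))),
             count_fe_minus = counts[, 1], count_fe_plus = counts[, 2],
             stringsAsFactors = FALSE)
}
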