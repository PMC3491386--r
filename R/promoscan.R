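# Positional promoter-motif screening. Offsets are measured from the base
# immediately 5' of the start codon: offset n means the motif's 5' end sits
# n bases upstream, occupying positions -n ... -n+|motif|-1. Matching is on
# the coding strand only by default (the screened motif is not its own
# reverse complement).

#' Extract promoter windows upstream of translation starts
#'
#' For plus-strand genes, the `upstreamLen` bases 5' of the start codon; for
#' minus-strand genes, the reverse complement of the downstream genomic
#' flank, so every window reads 5'->3' on the gene's coding strand with its
#' last base adjacent to the start codon. Windows truncated by a contig edge
#' are flagged, not dropped.
#'
#' @param genome a [Biostrings::DNAStringSet] of contigs.
#' @param genes a [GenomicRanges::GRanges] of CDS ranges with a `gene_id`
#'   metadata column; the translation start is the first base of the CDS on
#'   the coding strand.
#' @param upstreamLen window length in bases.
#' @return a list with `promoters` (a [Biostrings::DNAStringSet] named by
#'   gene id) and `info` (data.frame: `gene_id`, `strand`, `width`,
#'   `truncated`).
#' @export
extractPromoters <- function(genome, genes, upstreamLen = 500L) {
  upstreamLen <- as.integer(upstreamLen)
  stopifnot(upstreamLen >= 1L)
  ids <- genes$gene_id
  ctg <- as.character(GenomicRanges::seqnames(genes))
  if (!all(ctg %in% names(genome)))
    stop("gene models reference contigs missing from the genome")
  ctgLen <- Biostrings::width(genome)[match(ctg, names(genome))]
  strand <- as.character(GenomicRanges::strand(genes))
  tss <- ifelse(strand == "+", GenomicRanges::start(genes),
                GenomicRanges::end(genes))
  if (any(tss < 1L | tss > ctgLen))
    stop("translation starts must lie within contig bounds")
  proms <- character(length(ids))
  for (k in seq_along(ids)) {
    subject <- genome[[ctg[k]]]
    if (strand[k] == "+") {
      from <- max(1L, tss[k] - upstreamLen)
      to <- tss[k] - 1L
      proms[k] <- if (to < from) "" else
        as.character(Biostrings::subseq(subject, from, to))
    } else {
      from <- tss[k] + 1L
      to <- min(ctgLen[k], tss[k] + upstreamLen)
      proms[k] <- if (to < from) "" else as.character(
        Biostrings::reverseComplement(Biostrings::subseq(subject, from, to))
      )
    }
  }
  promoters <- Biostrings::DNAStringSet(proms)
  names(promoters) <- ids
  info <- data.frame(
    gene_id = ids, strand = strand,
    width = nchar(proms), truncated = nchar(proms) < upstreamLen,
    stringsAsFactors = FALSE
  )
  list(promoters = promoters, info = info)
}

.asPromoterSet <- function(promoters) {
  if (is.list(promoters) && !is.null(promoters$promoters))
    promoters <- promoters$promoters
  if (is.character(promoters)) {
    nm <- names(promoters)
    promoters <- Biostrings::DNAStringSet(promoters)
    names(promoters) <- nm
  }
  promoters
}

#' Positional scan for a fixed promoter motif
#'
#' Reports every exact occurrence of the motif on the coding strand of each
#' promoter whose 5'-end offset (distance upstream of the translation start)
#' falls in the inclusive window. Promoter positions with ambiguity codes
#' never match. With `bothStrands = TRUE` the reverse complement of the
#' motif is scanned as well (off by default: the screen counts
#' coding-strand perfect matches).
#'
#' @param promoters result of [extractPromoters()], or a named
#'   [Biostrings::DNAStringSet] / character vector of promoter windows whose
#'   last base is adjacent to the start codon.
#' @param motif DNA string over ACGT.
#' @param window inclusive offset window, default `c(150, 250)`.
#' @param bothStrands also report reverse-complement occurrences.
#' @return data.frame with `gene_id`, `offset` (bases upstream of the
#'   translation start to the motif's 5' end) and `strand_of_motif`.
#' @examples
#' p <- c(g1 = paste0(strrep("T", 300), "ACACGTGC", strrep("T", 192)))
#' scanMotif(p, "ACACGTGC")  # one hit at offset 200
#' @export
scanMotif <- function(promoters, motif, window = c(150L, 250L),
                      bothStrands = FALSE) {
  if (!grepl("^[ACGT]+$", motif)) stop("motif must be a string over ACGT")
  promoters <- .asPromoterSet(promoters)
  pats <- stats::setNames(list(Biostrings::DNAString(motif)), "+")
  if (bothStrands)
    pats <- c(pats, stats::setNames(
      list(Biostrings::reverseComplement(Biostrings::DNAString(motif))), "-"))
  hits <- list()
  for (k in seq_along(promoters)) {
    L <- Biostrings::width(promoters)[k]
    for (strand in names(pats)) {
      m <- Biostrings::matchPattern(pats[[strand]], promoters[[k]],
                                    fixed = TRUE)
      if (length(m)) {
        offset <- L - BiocGenerics::start(m) + 1L
        keep <- offset >= window[1] & offset <= window[2]
        if (any(keep))
          hits[[length(hits) + 1L]] <- data.frame(
            gene_id = names(promoters)[k], offset = offset[keep],
            strand_of_motif = strand, stringsAsFactors = FALSE
          )
      }
    }
  }
  if (!length(hits))
    return(data.frame(gene_id = character(), offset = integer(),
                      strand_of_motif = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Conserved positional k-mers across promoters
#'
#' Exact-k-mer stand-in for cross-species promoter comparison: returns every
#' k-mer present in all input promoters such that one occurrence per
#' promoter can be chosen with all offsets within `positionTolerance` of a
#' common center inside the window. Candidates are ranked by their minimal
#' positional spread (ascending).
#'
#' @param promoters named character vector or [Biostrings::DNAStringSet],
#'   one promoter per species/gene, last base adjacent to the start codon.
#' @param k k-mer length.
#' @param window inclusive offset window the common center must lie in.
#' @param positionTolerance maximum distance of each occurrence from the
#'   common center, in bases.
#' @return data.frame with `kmer`, `spread` (range of the chosen offsets)
#'   and `center`, sorted by spread.
#' @examples
#' p <- c(a = paste0(strrep("A", 295), "CACGTG", strrep("A", 199)),
#'        b = paste0(strrep("T", 290), "CACGTG", strrep("T", 204)))
#' findConservedPositionalKmers(p, k = 6)
#' @export
findConservedPositionalKmers <- function(promoters, k, window = c(150L, 250L),
                                         positionTolerance = 50L) {
  promoters <- as.character(.asPromoterSet(promoters))
  if (length(promoters) < 2L) stop("at least two promoters are required")
  if (any(nchar(promoters) < k)) stop("k exceeds the shortest promoter")
  occ <- lapply(promoters, function(s) {
    L <- nchar(s)
    starts <- seq_len(L - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    data.frame(kmer = kmers, offset = L - starts + 1L,
               stringsAsFactors = FALSE)
  })
  shared <- Reduce(intersect, lapply(occ, function(d) unique(d$kmer)))
  shared <- shared[grepl("^[ACGT]+$", shared)]
  res <- list()
  for (km in shared) {
    offs <- lapply(occ, function(d) sort(d$offset[d$kmer == km]))
    # minimal range containing one offset per promoter (sliding window over
    # the pooled sorted offsets), then feasibility of a common center
    pool <- data.frame(
      offset = unlist(offs),
      prom = rep(seq_along(offs), lengths(offs))
    )
    pool <- pool[order(pool$offset), ]
    nProm <- length(offs)
    best <- NULL
    lo <- 1L
    cover <- integer(nProm)
    have <- 0L
    for (hi in seq_len(nrow(pool))) {
      p <- pool$prom[hi]
      cover[p] <- cover[p] + 1L
      if (cover[p] == 1L) have <- have + 1L
      while (have == nProm && cover[pool$prom[lo]] > 1L) {
        cover[pool$prom[lo]] <- cover[pool$prom[lo]] - 1L
        lo <- lo + 1L
      }
      if (have == nProm) {
        oMin <- pool$offset[lo]
        oMax <- pool$offset[hi]
        cLo <- max(oMax - positionTolerance, window[1])
        cHi <- min(oMin + positionTolerance, window[2])
        if (oMax - oMin <= 2 * positionTolerance && cLo <= cHi) {
          cand <- list(spread = oMax - oMin, center = (cLo + cHi) / 2)
          if (is.null(best) || cand$spread < best$spread) best <- cand
        }
      }
    }
    if (!is.null(best))
      res[[length(res) + 1L]] <- data.frame(
        kmer = km, spread = best$spread, center = best$center,
        stringsAsFactors = FALSE
      )
  }
  if (!length(res))
    return(data.frame(kmer = character(), spread = integer(),
                      center = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$spread, out$kmer), ]
  rownames(out) <- NULL
  out
}

#' Base composition and palindromic core of a motif
#'
#' Reports the base counts and the longest core substring that equals its
#' own reverse complement. The screened 8-mer ACACGTGC is often called
#' palindromic; strictly only its 6-base core CACGTG (an E-box) is
#' self-reverse-complementary, and the report exposes both facts.
#'
#' @param motif DNA string over ACGT.
#' @return a list with `motif`, `composition` (named counts over A, C, G,
#'   T), `corePalindrome` and `isFullPalindrome`.
#' @examples
#' motifReport("ACACGTGC")
#' @export
motifReport <- function(motif) {
  if (!grepl("^[ACGT]+$", motif)) stop("motif must be a string over ACGT")
  bases <- strsplit(motif, "")[[1]]
  composition <- vapply(c("A", "C", "G", "T"), function(b) sum(bases == b), 0L)
  revcomp <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  core <- ""
  n <- nchar(motif)
  for (len in seq(n, 1L)) {
    for (st in seq_len(n - len + 1L)) {
      sub <- substr(motif, st, st + len - 1L)
      if (sub == revcomp(sub)) {
        core <- sub
        break
      }
    }
    if (nzchar(core)) break
  }
  list(motif = motif, composition = composition, corePalindrome = core,
       isFullPalindrome = motif == revcomp(motif))
}
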