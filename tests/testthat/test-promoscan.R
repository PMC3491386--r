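test_that("promoter extraction returns the exact coding-strand flank on both strands", {
  # plus-strand gene: promoter is the literal upstream substring
  up <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(ctg1 = paste0(up, "ATGAAATTT")))
  genes <- GenomicRanges::GRanges("ctg1", IRanges::IRanges(41, 49),
                                  strand = "+", gene_id = "gp")
  got <- extractPromoters(genome, genes, 40)
  expect_equal(as.character(got$promoters[["gp"]]), up)
  expect_false(got$info$truncated)
  # minus-strand gene at the other end of the same construct
  rcGenome <- Biostrings::DNAStringSet(c(ctg1 = as.character(
    Biostrings::reverseComplement(genome[[1]]))))
  rcGenes <- GenomicRanges::GRanges("ctg1", IRanges::IRanges(1, 9),
                                    strand = "-", gene_id = "gm")
  gotRc <- extractPromoters(rcGenome, rcGenes, 40)
  expect_equal(as.character(gotRc$promoters[["gm"]]), up)
  # truncated window at a contig edge is flagged, not dropped
  short <- extractPromoters(genome, genes, 100)
  expect_true(short$info$truncated)
  expect_equal(length(short$promoters[["gp"]]), 40)
})

test_that("window bounds are inclusive at 150 and 250 and exclusive beyond", {
  motif <- "ACACGTGC"
  promAt <- function(offset) {
    paste0(strrep("T", 500 - offset), motif, strrep("T", offset - 8))
  }
  proms <- c(p150 = promAt(150), p250 = promAt(250),
             p149 = promAt(149), p251 = promAt(251), p100 = promAt(100))
  hits <- scanMotif(proms, motif)
  expect_setequal(hits$gene_id, c("p150", "p250"))
  expect_setequal(hits$offset, c(150, 250))
  # multiple in-window occurrences are all reported
  multi <- c(m = paste0(strrep("T", 270), motif, strrep("T", 30), motif,
                        strrep("T", 184)))
  expect_equal(sort(scanMotif(multi, motif)$offset), c(192, 230))
  # ambiguity codes never match
  nProm <- c(x = paste0(strrep("T", 300), "ACACNTGC", strrep("T", 192)))
  expect_equal(nrow(scanMotif(nProm, "ACACGTGC", window = c(1, 500))), 0)
})

test_that("planted-motif recall is complete with zero false hits on exclusion-sampled genomes", {
  planted <- paste0("g", 1:15)
  spec <- SynthGenomeSpec(nGenes = 150, plantedGeneIds = planted, seed = 202)
  sim <- simulateGenome(spec)
  proms <- extractPromoters(sim$genome, sim$genes, 500)
  hits <- scanMotif(proms, "ACACGTGC")
  expect_setequal(hits$gene_id, planted)       # 100% recall, 0 false hits
  expect_true(all(hits$offset == 200))
  expect_equal(nrow(hits), 15)
})

test_that("strand consistency: scanning the reverse-complemented genome gives identical hits", {
  spec <- SynthGenomeSpec(nGenes = 20, plantedGeneIds = paste0("g", 1:5),
                          seed = 303)
  sim <- simulateGenome(spec)
  flipped <- Biostrings::reverseComplement(sim$genome)
  L <- Biostrings::width(sim$genome)[match(
    as.character(GenomicRanges::seqnames(sim$genes)), names(sim$genome))]
  flippedGenes <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(sim$genes),
    IRanges::IRanges(L - GenomicRanges::end(sim$genes) + 1L,
                     L - GenomicRanges::start(sim$genes) + 1L),
    strand = ifelse(as.character(GenomicRanges::strand(sim$genes)) == "+",
                    "-", "+"),
    gene_id = sim$genes$gene_id
  )
  h1 <- scanMotif(extractPromoters(sim$genome, sim$genes, 500), "ACACGTGC")
  h2 <- scanMotif(extractPromoters(flipped, flippedGenes, 500), "ACACGTGC")
  expect_identical(h1[order(h1$gene_id), c("gene_id", "offset")],
                   h2[order(h2$gene_id), c("gene_id", "offset")])
})

test_that("conserved positional k-mer finder matches construction and the exhaustive oracle", {
  motif <- "ACACGTGC"
  mk <- function(offset, fill) {
    paste0(strrep(fill, 500 - offset), motif, strrep(fill, offset - 8))
  }
  trio <- c(a = mk(195, "T"), b = mk(200, "T"), c = mk(210, "T"))
  found <- findConservedPositionalKmers(trio, k = 8, positionTolerance = 50)
  expect_true(motif %in% found$kmer)
  # wildly different offsets are rejected at tolerance 50
  far <- c(a = mk(60, "T"), b = mk(400, "T"))
  farFound <- findConservedPositionalKmers(far, k = 8,
                                           window = c(1, 500),
                                           positionTolerance = 50)
  expect_false(motif %in% farFound$kmer)
  # random promoters: reported set equals the brute-force enumeration
  set.seed(61)
  for (i in 1:5) {
    proms <- vapply(1:3, function(j) {
      paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    }, "")
    got <- findConservedPositionalKmers(proms, k = 4, window = c(50, 250),
                                        positionTolerance = 30)
    oracle <- bruteForceConservedKmers(proms, k = 4, window = c(50, 250),
                                       tol = 30)
    expect_identical(sort(got$kmer), oracle)
  }
})

test_that("motif report gives the published composition and the E-box core", {
  rep8 <- motifReport("ACACGTGC")
  expect_equal(rep8$composition, c(A = 2, C = 3, G = 2, T = 1))
  expect_equal(rep8$corePalindrome, "CACGTG")
  expect_false(rep8$isFullPalindrome)
  expect_equal(motifReport("AT")$corePalindrome, "AT")
  expect_true(motifReport("CACGTG")$isFullPalindrome)
  expect_error(motifReport("ACGU"), "ACGT")
})
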