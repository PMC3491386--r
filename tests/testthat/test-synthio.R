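test_that("genome generator plants motifs exactly where configured, on both strands", {
  spec <- SynthGenomeSpec(nGenes = 12, plantedGeneIds = c("g1", "g2"),
                          seed = 101)
  sim <- simulateGenome(spec)
  proms <- extractPromoters(sim$genome, sim$genes, 500)
  hits <- scanMotif(proms, "ACACGTGC", window = c(150, 250))
  expect_setequal(hits$gene_id, c("g1", "g2"))
  expect_true(all(hits$offset == 200))
  # at least sometimes a planted gene lands on the minus strand; the motif
  # must then sit on the coding strand upstream of the start
  minusSpec <- SynthGenomeSpec(nGenes = 30,
                               plantedGeneIds = paste0("g", 1:30), seed = 5)
  minusSim <- simulateGenome(minusSpec)
  expect_true(any(minusSim$truth$strand == "-"))
  mHits <- scanMotif(extractPromoters(minusSim$genome, minusSim$genes, 500),
                     "ACACGTGC")
  expect_setequal(mHits$gene_id, paste0("g", 1:30))
  # invalid spec: motif does not fit the promoter window
  expect_error(SynthGenomeSpec(5, promoterLen = 10, motifOffset = 9),
               "promoter")
})

test_that("genome generation is deterministic and exclusion-sampled promoters are motif-free", {
  spec <- SynthGenomeSpec(nGenes = 40, seed = 77)
  a <- simulateGenome(spec)
  b <- simulateGenome(spec)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  hits <- scanMotif(extractPromoters(a$genome, a$genes, 500), "ACACGTGC",
                    window = c(1, 500))
  expect_equal(nrow(hits), 0)
})

test_that("count generator conserves library sizes and honors planted fold changes", {
  w <- setNames(rep(1, 50), paste0("g", 1:50))
  spec <- SynthCountSpec(w, c(fe_minus = 9500, fe_plus = 9500),
                         foldChanges = c(g1 = 0), seed = 3)
  sim <- suppressMessages(simulateCounts(spec))
  expect_equal(sum(sim$counts$count_fe_minus), 9500)
  expect_equal(sum(sim$counts$count_fe_plus), 9500)
  # fold change 0 silences the gene in the iron-limited library only
  expect_equal(sim$counts$count_fe_minus[sim$counts$gene_id == "g1"], 0)
  expect_gt(sim$counts$count_fe_plus[sim$counts$gene_id == "g1"], 0)
  # degenerate single-gene multinomial receives everything
  single <- simulateCounts(SynthCountSpec(c(solo = 1),
                                          c(fe_minus = 100, fe_plus = 200)))
  expect_equal(unlist(single$counts[1, c("count_fe_minus", "count_fe_plus")],
                      use.names = FALSE), c(100, 200))
  # determinism
  expect_identical(suppressMessages(simulateCounts(spec))$counts, sim$counts)
})

test_that("PSM generator gives exact ratios at zero CV and clean records pass the cascade", {
  spec <- SynthPsmSpec(
    proteins = list(A = c("PEPTIDEK", "SEQENCER"), B = c("MARINEK")),
    trueRatios = c(A = 1, B = 2), nPbcPerProtein = 4,
    decoyFraction = 0, ppmNoiseSd = 0, intensityCv = 0, seed = 2
  )
  sim <- simulatePsms(spec)
  expect_false(any(sim$psms$is_decoy))
  ratios <- sim$psms$intensity_light / sim$psms$intensity_heavy
  expect_equal(sort(unique(round(ratios, 12))), c(1, 2))
  # every record survives the full filter chain
  out <- protquantPipeline(sim$psms)
  expect_equal(nrow(out$psms), nrow(sim$psms))
  expect_equal(sort(out$ratios$median_ratio), c(1, 2))
})

test_that("cell generator spans the doubling range and round-trips the unit volume", {
  spec <- SynthCellSpec(nCells = 4000, unitDiameter = 5.9, unitLength = 5.5,
                        noiseCv = 0, seed = 8)
  cells <- simulateCells(spec)$cells
  expect_true(all(cells$length >= 5.5 & cells$length <= 11))
  expect_equal(unique(cells$diameter), 5.9)
  # uniform phase: mean length 1.5 x unit length
  expect_equal(mean(cells$length), 1.5 * 5.5, tolerance = 0.01)
  unit <- unitCellFromPopulation(cells)
  expect_equal(unit$unitVolume, pi * (5.9 / 2)^2 * 5.5, tolerance = 0.01)
  # the exponential-age model is biased toward young (short) cells
  young <- simulateCells(SynthCellSpec(4000, 5.9, 5.5,
                                       growthModel = "exponential_age",
                                       noiseCv = 0, seed = 8))$cells
  expect_lt(mean(young$length), mean(cells$length))
  expect_true(all(young$length >= 5.5 & young$length <= 11))
})

test_that("tree generator plants recoverable sister-clade compositions", {
  sim <- simulateLgtTrees(n = 30, nLgt = 24, nVertical = 3, seed = 99)
  expect_equal(table(sim$truth$planted_verdict)[["lgt_confirmed"]], 24)
  v <- classifyTrees(sim$trees, sim$queries, sim$lineages)
  expect_identical(v$verdict, sim$truth$planted_verdict)
  # determinism
  sim2 <- simulateLgtTrees(n = 30, nLgt = 24, nVertical = 3, seed = 99)
  expect_identical(ape::write.tree(sim$trees), ape::write.tree(sim2$trees))
})
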