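psmRow <- function(evalue = 1e-6, second = 1e-2, ppm = 0, decoy = FALSE,
                   peptide = "PEPK", proteins = "A", band = 1L, charge = 2L,
                   light = 100, heavy = 100) {
  data.frame(spectrum_id = "s", peptide = peptide, protein_ids = proteins,
             evalue = evalue, evalue_second_best = second, ppm_dev = ppm,
             band = band, charge = charge, is_decoy = decoy,
             intensity_light = light, intensity_heavy = heavy,
             stringsAsFactors = FALSE)
}

test_that("distinctiveness filter keeps clear best hits and drops ambiguous ones", {
  keep <- psmRow(evalue = 1e-6, second = 1e-2)       # ratio 1e4
  dropMe <- psmRow(evalue = 1e-3, second = 1.5e-3)   # ratio 1.5
  noSecond <- psmRow(second = NA)
  batch <- rbind(keep, dropMe, noSecond)
  out <- filterDistinctiveness(batch, threshold = 2)
  expect_equal(nrow(out), 2)
  expect_true(all(is.na(out$evalue_second_best) |
                  out$evalue_second_best / out$evalue >= 2))
  # survivor count equals a brute-force check over a random batch
  set.seed(21)
  big <- do.call(rbind, lapply(1:100, function(i) {
    psmRow(evalue = 10^runif(1, -8, -2), second = 10^runif(1, -8, -1))
  }))
  out2 <- filterDistinctiveness(big)
  expect_equal(nrow(out2),
               sum(big$evalue_second_best / big$evalue >= 2))
  expect_message(filterDistinctiveness(psmRow(evalue = 0)), "non-positive")
})

test_that("FDR filter picks the largest threshold meeting the target and excludes decoys", {
  # 300 targets below 1e-4, decoys interleaved so the 3rd decoy still meets
  # 1% but the 4th does not
  targets <- psmRow()[rep(1, 300), ]
  targets$evalue <- seq(1e-6, 1e-4, length.out = 300)
  decoys <- psmRow(decoy = TRUE)[rep(1, 4), ]
  decoys$evalue <- c(2e-5, 5e-5, 9.9e-5, 1.2e-4)
  batch <- rbind(targets, decoys)
  res <- filterFdr(batch, fdrTarget = 0.01)
  expect_equal(res$fdr, 3 / 300)
  expect_lt(res$threshold, 1.2e-4)
  expect_equal(nrow(res$psms), 300)
  expect_false(any(res$psms$is_decoy))
  # no decoys at all: everything passes at the maximum E-value
  res0 <- filterFdr(targets, fdrTarget = 0.01)
  expect_equal(res0$threshold, max(targets$evalue))
  expect_equal(nrow(res0$psms), 300)
  # threshold equals an independent scan over all candidate cut points,
  # across random instances, and the estimate never exceeds the target
  set.seed(31)
  for (i in 1:20) {
    ev <- 10^runif(80, -8, -1)
    dec <- runif(80) < 0.2
    if (!any(!dec)) next
    inst <- psmRow()[rep(1, 80), ]
    inst$evalue <- ev
    inst$is_decoy <- dec
    got <- suppressWarnings(filterFdr(inst, 0.05))
    oracle <- bruteForceFdrThreshold(ev, dec, 0.05)
    expect_identical(got$threshold, oracle)
    if (!is.na(got$threshold)) expect_lte(got$fdr, 0.05)
  }
})

test_that("ppm filter boundary is inclusive at the limit", {
  batch <- rbind(psmRow(ppm = 0), psmRow(ppm = 5), psmRow(ppm = 5.01),
                 psmRow(ppm = -5), psmRow(ppm = -7))
  out <- filterPpm(batch, maxPpm = 5)
  expect_equal(out$ppm_dev, c(0, 5, -5))
  # survivor set equals the plain definition on a random batch
  set.seed(41)
  mixed <- psmRow()[rep(1, 200), ]
  mixed$ppm_dev <- rnorm(200, 0, 4)
  expect_equal(nrow(filterPpm(mixed)), sum(abs(mixed$ppm_dev) <= 5))
})

test_that("the filter cascade order matters and is fixed", {
  # a decoy with a superb E-value but ambiguous second-best: removing it
  # before the FDR step (cascade order) changes the threshold relative to
  # running the FDR step first
  targets <- psmRow()[rep(1, 50), ]
  targets$evalue <- seq(2e-6, 1e-4, length.out = 50)
  sneakyDecoy <- psmRow(evalue = 1e-6, second = 1.2e-6, decoy = TRUE)
  batch <- rbind(targets, sneakyDecoy)
  cascade <- filterFdr(filterDistinctiveness(batch), fdrTarget = 0.015)
  swapped <- suppressWarnings(filterFdr(batch, fdrTarget = 0.015))
  expect_gt(nrow(cascade$psms), nrow(swapped$psms))
})

test_that("protein grouping merges identical sets and absorbs subsets", {
  twin <- rbind(psmRow(peptide = "AAA", proteins = "P1;P2"),
                psmRow(peptide = "BBB", proteins = "P1;P2"))
  g <- inferProteinGroups(twin)
  expect_equal(nrow(g$groups), 1)
  expect_equal(g$groups$proteins, "P1;P2")
  subsetCase <- rbind(psmRow(peptide = "AAA", proteins = "A;B"),
                      psmRow(peptide = "BBB", proteins = "A"),
                      psmRow(peptide = "CCC", proteins = "A"))
  g2 <- inferProteinGroups(subsetCase)
  expect_equal(nrow(g2$groups), 1)
  expect_equal(g2$groups$proteins, "A;B")
  # shared peptides are flagged non-unique across surviving groups
  shared <- rbind(psmRow(peptide = "AAA", proteins = "X"),
                  psmRow(peptide = "BBB", proteins = "Y"),
                  psmRow(peptide = "SSS", proteins = "X;Y"))
  g3 <- inferProteinGroups(shared)
  expect_equal(nrow(g3$groups), 2)
  expect_false(all(g3$peptideMap$unique))
  expect_true(all(g3$peptideMap$unique[g3$peptideMap$peptide != "SSS"]))
  # random bipartite instances: group count equals brute-force merge
  set.seed(51)
  for (i in 1:15) {
    nProt <- sample(3:8, 1)
    pepPool <- paste0("pep", 1:10)
    sets <- lapply(seq_len(nProt),
                   function(j) sample(pepPool, sample(1:5, 1)))
    names(sets) <- paste0("P", seq_len(nProt))
    psms <- do.call(rbind, lapply(names(sets), function(p) {
      do.call(rbind, lapply(sets[[p]],
                            function(pe) psmRow(peptide = pe, proteins = p)))
    }))
    # collapse duplicated peptide rows into multi-protein annotations
    agg <- aggregate(protein_ids ~ peptide, psms,
                     function(x) paste(sort(unique(x)), collapse = ";"))
    psms2 <- psmRow()[rep(1, nrow(agg)), ]
    psms2$peptide <- agg$peptide
    psms2$protein_ids <- agg$protein_ids
    expect_equal(nrow(inferProteinGroups(psms2)$groups),
                 bruteForceGroupCount(sets))
  }
})

test_that("PBC ratios use the key (peptide, band, charge) and collapse duplicate spectra", {
  one <- psmRow(light = 50, heavy = 50)
  expect_equal(pbcRatios(one)$ratio, 1)
  twoCharges <- rbind(psmRow(charge = 2L), psmRow(charge = 3L))
  expect_equal(nrow(pbcRatios(twoCharges)), 2)
  # duplicates within one PBC collapse before ratio formation
  dup <- rbind(psmRow(light = 10, heavy = 100),
               psmRow(light = 30, heavy = 100))
  expect_equal(pbcRatios(dup)$ratio, 20 / 100)
  expect_equal(pbcRatios(dup)$n_spectra, 2)
  expect_message(z <- pbcRatios(psmRow(heavy = 0)), "zero intensity")
  expect_equal(nrow(z), 0)
  # inverted labeling flips the orientation
  inv <- psmRow(light = 40, heavy = 20)
  expect_equal(pbcRatios(inv, heavyIsFePlus = FALSE)$ratio, 0.5)
})

test_that("protein-group ratios use the linear-interpolation quantile convention", {
  psms <- rbind(psmRow(peptide = "AAA", proteins = "P", band = 1L),
                psmRow(peptide = "AAA", proteins = "P", band = 2L,
                       light = 200),
                psmRow(peptide = "AAA", proteins = "P", band = 3L,
                       light = 300))
  g <- inferProteinGroups(psms)
  pbc <- pbcRatios(psms)
  pr <- proteinRatios(pbc, g)
  expect_equal(pr$median_ratio, 2)
  expect_equal(pr$q1, 1.5)
  expect_equal(pr$q3, 2.5)
  expect_equal(pr$n_pbc, 3)
  # single PBC: quartiles collapse onto the value
  solo <- proteinRatios(pbcRatios(psms[1, ]), inferProteinGroups(psms[1, ]))
  expect_equal(c(solo$q1, solo$median_ratio, solo$q3), c(1, 1, 1))
})

test_that("planted protein ratios are recovered within 10% at moderate noise", {
  spec <- SynthPsmSpec(
    proteins = list(UP = paste0("PEP", 1:5, "K"), DOWN = paste0("QEP", 1:5, "K")),
    trueRatios = c(UP = 2, DOWN = 0.5), nPbcPerProtein = 5,
    decoyFraction = 0, ppmNoiseSd = 0, intensityCv = 0.1, seed = 17
  )
  out <- protquantPipeline(simulatePsms(spec)$psms)
  est <- setNames(out$ratios$median_ratio, out$ratios$proteins)
  expect_equal(unname(est["UP"]), 2, tolerance = 0.1)
  expect_equal(unname(est["DOWN"]), 0.5, tolerance = 0.1)
})

test_that("biomass rescaling converts equal-protein ratios to per-cell ratios", {
  expect_equal(scaleToCellularUnit(1.0, 0.5), 0.5)
  expect_equal(scaleToCellularUnit(1.7, 0.5), 0.85)
  expect_equal(scaleToCellularUnit(3.2, 1), 3.2)
  expect_error(scaleToCellularUnit(1, 0))
})
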