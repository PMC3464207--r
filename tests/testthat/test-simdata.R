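test_that("every cassette event carries exactly 4 probe sets with the expected roles", {
  se <- simulateArray(SimConfig(nGenes = 12, nCassetteEvents = 5, seed = 3))
  ann <- as.data.frame(SummarizedExperiment::rowData(se))
  sets <- ann[!duplicated(ann$probe_set_id), ]
  per_event <- table(sets$event_id[!is.na(sets$event_id)])
  expect_true(all(per_event == 4L))
  for (ev in names(per_event)) {
    roles <- sets$role[sets$event_id %in% ev]
    expect_setequal(roles, c("cassette_exon", "upstream_junction",
                             "downstream_junction", "skipping_junction"))
  }
  # every gene carries constitutive sets beyond the event sets
  n_const <- table(sets$gene_id[sets$role == "constitutive"])
  expect_true(all(n_const >= 2L))
})

test_that("identical config and seed give bit-identical output; seeds differ", {
  cfg <- SimConfig(nGenes = 8, nCassetteEvents = 2, seed = 42)
  a <- SummarizedExperiment::assay(simulateArray(cfg), "intensity")
  b <- SummarizedExperiment::assay(simulateArray(cfg), "intensity")
  expect_identical(a, b)
  c_ <- SummarizedExperiment::assay(
    simulateArray(SimConfig(nGenes = 8, nCassetteEvents = 2, seed = 43)),
    "intensity")
  expect_false(identical(a, c_))
})

test_that("truth table marks exactly the events with unequal psi as differential", {
  cfg <- SimConfig(nGenes = 50, nCassetteEvents = 10,
                   psiControl = 0.8, psiMutant = 0.5, seed = 1)
  truth <- simTruth(simulateArray(cfg))
  expect_equal(nrow(truth), 10L)
  expect_true(all(truth$is_differential))
  mixed <- SimConfig(nGenes = 20, nCassetteEvents = 6,
                     psiControl = c(0.8, 0.5), psiMutant = 0.5, seed = 2)
  truth2 <- simTruth(simulateArray(mixed))
  expect_equal(truth2$is_differential,
               truth2$psi_control != truth2$psi_mutant)
})

test_that("configuration errors are refused", {
  expect_error(SimConfig(nGenes = 5, nCassetteEvents = 6), "exceed")
  expect_error(SimConfig(replicatesPerGenotype = 1), ">= 2")
  expect_error(SimConfig(psiControl = 1.2), "\\[0, 1\\]")
  expect_error(SimConfig(noiseSdLog2 = -0.1), "non-negative")
})

test_that("probe intensities are positive and follow the generative mean", {
  # moment check: background off, many replicates; the sample mean of each
  # probe converges to affinity x expression x psi-factor within 3 SE
  cfg <- SimConfig(nGenes = 2, nUnexpressedGenes = 0, nCassetteEvents = 1,
                   replicatesPerGenotype = 500L, psiControl = 0.8,
                   psiMutant = 0.5, backgroundMean = 0, probesPerSet = 1L,
                   constitutiveSetsPerGene = 2L, seed = 9)
  se <- simulateArray(cfg)
  x <- SummarizedExperiment::assay(se, "intensity")
  expect_true(all(x > 0))
  means <- S4Vectors::metadata(se)$probeMeans
  geno <- sampleGenotype(se)
  for (g in c("control", "mutant")) {
    obs <- x[, geno == g, drop = FALSE]
    m <- rowMeans(obs)
    se3 <- 3 * apply(obs, 1, sd) / sqrt(ncol(obs))
    expect_true(all(abs(m - means[, g]) <= se3))
  }
})

test_that("no-signal no-noise configuration yields zero tier-1 events", {
  cfg <- SimConfig(nGenes = 10, nCassetteEvents = 4, psiControl = 0.6,
                   psiMutant = 0.6, noiseSdLog2 = 0, backgroundMean = 0,
                   seed = 5)
  calls <- screenSplicingEvents(simulateArray(cfg))$calls
  expect_equal(sum(calls$tier == "tier1"), 0L)
})

test_that("splice-site windows carry the planted tract and motif layout", {
  sim <- simulateSpliceSiteWindows(nFg = 10, nBg = 10, seed = 1)
  expect_equal(length(sim$sequences), 20L)
  fg <- as.character(sim$sequences[sim$truth$is_foreground])
  bg <- as.character(sim$sequences[!sim$truth$is_foreground])
  # planted motif in every foreground window, in the tract's last 10 nt
  tr_end <- sim$truth$tract_end[1]
  expect_true(all(vapply(fg, function(s) {
    p <- regexpr("TGC", s)[1] - 1L   # 0-based
    p >= tr_end - 10L && p < tr_end
  }, logical(1))))
  expect_false(any(grepl("TGC", bg)))
  # windows end at the splice acceptor
  expect_true(all(substr(c(fg, bg), 49, 50) == "AG"))
})

test_that("window generator refuses impossible layouts", {
  expect_error(simulateSpliceSiteWindows(5, 5, motif = ""), "non-empty")
  expect_error(simulateSpliceSiteWindows(5, 5, windowLen = 10, tractLen = 15),
               "at least")
  expect_error(simulateSpliceSiteWindows(5, 5, offsetFromPptEnd = 10),
               "outside")
  sim <- simulateSpliceSiteWindows(nFg = 0, nBg = 4, seed = 2)
  expect_true(all(!sim$truth$is_foreground))
})

test_that("RT-PCR simulation is proportional to psi and reproducible", {
  truth <- data.frame(event_id = c("e1", "e2"),
                      psi_control = c(0.5, 0.75),
                      psi_mutant = c(0.5, 0.25),
                      is_differential = c(FALSE, TRUE))
  exact <- simulateRtPcr(truth, bandNoiseCv = 0, seed = 1)
  e1 <- exact[exact$event_id == "e1", ]
  expect_equal(e1$inclusion_band, e1$skipping_band)
  e2c <- exact[exact$event_id == "e2" & exact$genotype == "control", ]
  expect_equal(unique(e2c$inclusion_band / (e2c$inclusion_band + e2c$skipping_band)),
               0.75)
  noisy1 <- simulateRtPcr(truth, bandNoiseCv = 0.1, seed = 7)
  noisy2 <- simulateRtPcr(truth, bandNoiseCv = 0.1, seed = 7)
  expect_identical(noisy1, noisy2)
  expect_true(all(noisy1$inclusion_band >= 0 & noisy1$skipping_band >= 0))
  expect_error(simulateRtPcr(truth, bandNoiseCv = -1), "non-negative")
  expect_error(simulateRtPcr(truth[0, ]), "non-empty")
})

test_that("simulateDeletion splices out exactly the requested interval", {
  expect_equal(simulateDeletion("ACGTACGT", 2, 3)$mutant, "ACCGT")
  expect_equal(simulateDeletion("ACGT", 1, 0)$mutant, "ACGT")
  expect_error(simulateDeletion("ACGT", 3, 5), "out of range")
  expect_error(simulateDeletion("ACGT", -1, 1), "out of range")
})
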