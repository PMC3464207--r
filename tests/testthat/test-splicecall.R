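test_that("pooled t test matches the closed form and is symmetric", {
  res <- pooledTTest(c(1, 2, 3), c(4, 5, 6))
  # closed form: pooled sd 1, se = sqrt(2/3), t = -3/se, df = 4
  t_exact <- -3 / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(res[["t"]], t_exact, tolerance = 1e-12)
  expect_equal(round(res[["t"]], 3), -3.674)
  expect_equal(res[["p"]], 2 * pt(t_exact, df = 4), tolerance = 1e-12)
  expect_equal(round(res[["p"]], 4), 0.0213)
  swapped <- pooledTTest(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped[["t"]], -res[["t"]])
  expect_equal(swapped[["p"]], res[["p"]])
})

test_that("pooled t handles degenerate variance explicitly", {
  expect_equal(pooledTTest(c(2, 2, 2), c(2, 2, 2)), c(t = 0, p = 1))
  zed <- pooledTTest(c(3, 3), c(1, 1))
  expect_equal(zed[["p"]], .Machine$double.xmin)
  expect_true(zed[["t"]] > 0)
  expect_error(pooledTTest(1, c(1, 2)), "at least 2")
})

test_that("t P values agree with the exhaustive 4+4 permutation null", {
  # exact permutation p has 1/35 granularity; with df = 6 the Student
  # approximation tracks it closely in rank and loosely in absolute value
  set.seed(77)
  ps <- t(replicate(20, {
    a <- rnorm(4)
    b <- rnorm(4, sample(c(0, 1.5), 1))
    c(t = pooledTTest(a, b)[["p"]], perm = oracle_perm_p(a, b))
  }))
  expect_lt(mean(abs(ps[, "t"] - ps[, "perm"])), 0.06)
  expect_lt(max(abs(ps[, "t"] - ps[, "perm"])), 0.25)
  expect_gt(cor(ps[, "t"], ps[, "perm"], method = "spearman"), 0.9)
  # significance decisions differ only within the permutation granularity
  clash <- (ps[, "t"] < 0.05) != (ps[, "perm"] < 0.05)
  expect_true(all(abs(ps[clash, "perm"] - 0.05) <= 3 / 35))
})

test_that("splicing index is the probe-set over gene signal ratio", {
  ann <- data.frame(probe_set_id = c("s1", "s2"), gene_id = c("g1", "g1"),
                    event_id = NA_character_,
                    role = c("constitutive", "constitutive"),
                    flag_constitutive = TRUE, flag_multi_gene = FALSE,
                    flag_alt_promoter = FALSE, flag_conserved = FALSE,
                    flag_neuron_specific = FALSE)
  sig <- new("SpliceSignals",
             probeSetSignal = matrix(c(4, 8, 4, 8), 2, 2,
                                     dimnames = list(c("s1", "s2"), c("a", "b"))),
             geneSignal = matrix(4, 1, 2, dimnames = list("g1", c("a", "b"))),
             annotation = ann,
             genotype = factor(c("control", "mutant")))
  inorm <- splicingIndex(sig)
  expect_equal(unname(inorm["s1", ]), c(1, 1))
  expect_equal(unname(inorm["s2", ]), c(2, 2))
})

test_that("constitutive probe sets show no genotype trend in a no-noise simulation", {
  cfg <- SimConfig(nGenes = 20, nCassetteEvents = 5, psiControl = 0.7,
                   psiMutant = 0.7, noiseSdLog2 = 0, backgroundMean = 0,
                   seed = 7)
  sig <- preprocessArray(simulateArray(cfg))
  inorm <- splicingIndex(sig)
  geno <- sig@genotype
  ann <- setAnnotation(sig)
  const <- ann$role == "constitutive" & grepl("^gene0", ann$gene_id)
  ratio <- rowMeans(inorm[const, geno == "mutant"]) /
    rowMeans(inorm[const, geno == "control"])
  expect_true(all(abs(ratio - 1) < 1e-6))
})

test_that("mean I_norm is monotone in psi for each probe-set role", {
  psis <- c(0.2, 0.5, 0.8)
  m <- sapply(psis, function(p) {
    cfg <- SimConfig(nGenes = 10, nCassetteEvents = 3, psiControl = p,
                     psiMutant = p, noiseSdLog2 = 0, seed = 11)
    sig <- preprocessArray(simulateArray(cfg))
    inorm <- splicingIndex(sig)
    ann <- setAnnotation(sig)
    c(incl = mean(inorm[ann$role %in% c("cassette_exon", "upstream_junction",
                                        "downstream_junction"), ]),
      skip = mean(inorm[ann$role == "skipping_junction", ]))
  })
  expect_true(all(diff(m["incl", ]) > 0))
  expect_true(all(diff(m["skip", ]) < 0))
})

test_that("candidate filters drop flagged probe sets and reject unknown roles", {
  rec <- data.frame(probe_set_id = c("a", "b", "c", "d"),
                    role = c("cassette_exon", "skipping_junction",
                             "upstream_junction", "constitutive"),
                    flag_constitutive = c(FALSE, FALSE, FALSE, TRUE),
                    flag_multi_gene = c(TRUE, FALSE, FALSE, FALSE),
                    flag_alt_promoter = c(FALSE, TRUE, FALSE, FALSE))
  kept <- applyProbeSetFilters(rec)
  expect_equal(kept$probe_set_id, "c")
  rec$role[1] <- "mystery"
  expect_error(applyProbeSetFilters(rec), "unknown probe-set role")
})

test_that("event calling applies the voting and opposite-trend rules", {
  base <- data.frame(
    probe_set_id = c("ps_exon", "ps_skip"),
    event_id = "ev1",
    role = c("cassette_exon", "skipping_junction"),
    flag_conserved = TRUE, flag_neuron_specific = TRUE,
    mean_control = c(0.8, 0.2), mean_mutant = c(0.5, 0.5),
    p = c(0.01, 0.02))
  # exon down + skipping up agree on inclusion_down -> tier 1
  call <- callSplicingEvents(base)
  expect_equal(call$tier, "tier1")
  expect_equal(call$direction, "inclusion_down")
  expect_equal(call$n_significant_probe_sets, 2L)

  # two inclusion-reporting sets with opposite trends -> ambiguous, no call
  amb <- base
  amb$role <- c("cassette_exon", "upstream_junction")
  amb$mean_mutant <- c(0.5, 0.9)   # one down, one up
  call2 <- callSplicingEvents(amb)
  expect_equal(call2$tier, "none")
  expect_equal(call2$direction, "ambiguous")

  # a single vote with conservation + neuron-specific flags -> tier 2
  one <- base
  one$p <- c(0.01, 0.5)
  call3 <- callSplicingEvents(one)
  expect_equal(call3$tier, "tier2_candidate")
  expect_equal(call3$n_significant_probe_sets, 1L)

  # same single vote without the flags -> no call
  one$flag_conserved <- FALSE
  expect_equal(callSplicingEvents(one)$tier, "none")

  # no significant probe set -> none
  quiet <- base
  quiet$p <- c(0.5, 0.6)
  expect_equal(callSplicingEvents(quiet)$tier, "none")
})

test_that("tier-1 events are recovered with high recall and precision", {
  cfg <- SimConfig(nGenes = 50, nCassetteEvents = 10, replicatesPerGenotype = 4,
                   psiControl = 0.8, psiMutant = 0.5, noiseSdLog2 = 0.15,
                   seed = 1)
  se <- simulateArray(cfg)
  perf <- tierPerformance(screenSplicingEvents(se)$calls, simTruth(se))
  expect_gte(perf[["recall"]], 0.8)
  expect_gte(perf[["precision"]], 0.9)
})

test_that("null simulations stay below the per-probe-set alpha at event level", {
  n_tier1 <- 0L; n_events <- 0L
  for (s in 1:5) {
    cfg <- SimConfig(nGenes = 50, nCassetteEvents = 10, psiControl = 0.6,
                     psiMutant = 0.6, noiseSdLog2 = 0.15, seed = s)
    calls <- screenSplicingEvents(simulateArray(cfg))$calls
    n_tier1 <- n_tier1 + sum(calls$tier == "tier1")
    n_events <- n_events + nrow(calls)
  }
  expect_lte(n_tier1, qbinom(0.99, n_events, 0.05))
})

test_that("cross-tissue concordance reproduces hand-computed correlations", {
  expect_equal(crossTissueConcordance(1:4, 1:4)[["r"]], 1)
  expect_equal(crossTissueConcordance(1:4, -(1:4))[["r"]], -1)
  expect_equal(crossTissueConcordance(c(1, 2, 3, 4), c(1, 3, 2, 4))[["r"]], 0.8)
  expect_error(crossTissueConcordance(1:2, 1:2), ">= 3")
  expect_error(crossTissueConcordance(c(1, 1, 1), 1:3), "zero variance")
})
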