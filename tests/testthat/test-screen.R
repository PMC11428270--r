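test_that("SE ratio matches the hand oracle in both modes", {
  # two tumors with paired ratios 2 and 4: s = (4, 8), e = (2, 2)
  stroma <- matrix(c(4, 8), nrow = 1, dimnames = list("pA", c("T1", "T2")))
  epi <- matrix(c(2, 2), nrow = 1, dimnames = list("pA", c("T1", "T2")))
  cohort <- housekeepingNormalize(makePairedCohort(stroma, epi, hk = 1))

  expect_equal(unname(seRatio(cohort, "pA", "mean_of_paired_ratios")),
               oracleSE(c(4, 8), c(2, 2), "mean_of_paired_ratios"))
  expect_equal(unname(seRatio(cohort, "pA", "ratio_of_means")),
               oracleSE(c(4, 8), c(2, 2), "ratio_of_means"))
  expect_equal(unname(seRatio(cohort, "pA", "mean_of_paired_ratios")), 3.0)

  # identical compartment profiles give exactly 1 in both modes
  same <- housekeepingNormalize(makePairedCohort(stroma, stroma, hk = 1))
  for (mode in c("mean_of_paired_ratios", "ratio_of_means"))
    expect_identical(unname(seRatio(same, "pA", mode)), 1.0)

  # stochastic instance, probe by probe, both modes
  sim <- simulateCohort(SimParams(nTumors = 7, nBackground = 25,
                                  nAnchorBlock = 5, nSubtypeBlock = 0,
                                  nSubtypeTumors = 0, seed = 21))
  norm <- housekeepingNormalize(sim$cohort)
  x <- SummarizedExperiment::assay(norm, "exprs")
  d <- cohortDesign(norm)
  for (mode in c("mean_of_paired_ratios", "ratio_of_means")) {
    se <- seRatio(norm, mode = mode)
    for (p in rownames(x))
      expect_equal(unname(se[p]),
                   oracleSE(x[p, d$stroma_sample_id],
                            x[p, d$epithelium_sample_id], mode),
                   tolerance = 1e-9)
  }
})

test_that("epithelium zeros skip tumors in paired mode and flag all-zero", {
  stroma <- matrix(c(6, 8, 10,
                     1, 1, 1), nrow = 2, byrow = TRUE,
                   dimnames = list(c("pZ", "pAllZero"),
                                   c("T1", "T2", "T3")))
  epi <- matrix(c(2, 0, 5,
                  0, 0, 0), nrow = 2, byrow = TRUE,
                dimnames = list(c("pZ", "pAllZero"),
                                c("T1", "T2", "T3")))
  cohort <- housekeepingNormalize(makePairedCohort(stroma, epi, hk = 1))
  expect_warning(se <- seRatio(cohort, c("pZ", "pAllZero"),
                               "mean_of_paired_ratios"),
                 "skipped")
  expect_equal(unname(se["pZ"]), (6 / 2 + 10 / 5) / 2)  # T2 skipped
  expect_true(is.na(se["pAllZero"]))                    # all skipped
})

test_that("anchor correlation is Pearson on stroma and flags degeneracy", {
  set.seed(4)
  nT <- 5
  anchor <- c(1, 2, 3, 4, 5)
  probe <- c(2, 1, 4, 3, 5)
  stroma <- rbind(SPARC_at = anchor, pB = probe,
                  pNeg = 10 - 2 * anchor, pFlat = rep(3, nT))
  colnames(stroma) <- paste0("T", 1:nT)
  epi <- matrix(1, nrow(stroma), nT,
                dimnames = dimnames(stroma))
  cohort <- housekeepingNormalize(makePairedCohort(stroma, epi, hk = 1))

  r <- anchorCorrelation(cohort, "SPARC_at")
  expect_identical(unname(r["SPARC_at"]), 1.0)         # anchor vs itself
  expect_equal(unname(r["pNeg"]), -1.0)                # exact negative line
  expect_equal(unname(r["pB"]), oraclePearson(probe, anchor),
               tolerance = 1e-12)
  expect_true(is.na(r["pFlat"]))                       # zero variance

  expect_error(anchorCorrelation(cohort, "nope_at"), "not in matrix")
  expect_error(
    anchorCorrelation(cohort, "SPARC_at",
                      samples = paste0("T", 1:2, "_S")),
    "subset too small")
})

test_that("tier classification uses inclusive boundaries", {
  # boundary and published examples: SPARC-like 17.2 is a CAFG,
  # POSTN-like breast SE 3.6 is an L-CAFG
  se <- c(10.0, 5.0, 4.999, 17.2, 3.6, 9.999)
  expect_identical(as.character(classifyTier(se)),
                   c("CAFG", "semi_CAFG", "L_CAFG", "CAFG", "L_CAFG",
                     "semi_CAFG"))
  expect_true(is.na(classifyTier(NA_real_)))

  # partition property: every defined SE maps to exactly one tier
  set.seed(2)
  grid <- c(10^runif(500, -3, 3), 5, 10, 4.9999999, 9.9999999)
  tiers <- classifyTier(grid)
  expect_false(any(is.na(tiers)))
  expect_identical(as.character(tiers),
                   vapply(grid, oracleTier, character(1)))
})

test_that("the full screen equals a probe-by-probe brute-force pass", {
  sim <- simulateCohort(SimParams(nTumors = 9, nBackground = 40,
                                  nAnchorBlock = 8, nSubtypeBlock = 2,
                                  nSubtypeTumors = 3, seed = 33))
  norm <- housekeepingNormalize(sim$cohort)
  refSample <- stromaSamples(norm)[4]
  cfg <- ScreenConfig(anchorProbe = "SPARC_at",
                      referenceSample = refSample)
  scr <- screenGenes(norm, cfg)
  tab <- as.data.frame(screenTable(scr))

  x <- SummarizedExperiment::assay(norm, "exprs")
  want <- oracleScreen(x, annotationOf(norm), "SPARC_at",
                       "mean_of_paired_ratios", refSample)
  expect_identical(tab$probe_id, want$probe_id)  # same deterministic order
  expect_equal(tab$se_ratio, want$se_ratio, tolerance = 1e-9)
  expect_equal(tab$anchor_r, want$anchor_r, tolerance = 1e-9)
  expect_identical(as.character(tab$tier), want$tier)
  expect_equal(tab$ref_expression, want$ref_expression, tolerance = 1e-12)
  expect_identical(tab$rank_by_expression, seq_len(nrow(tab)))

  # the anchor's own record
  expect_identical(tab$anchor_r[tab$probe_id == "SPARC_at"], 1.0)

  # guard rails
  expect_error(screenGenes(norm, ScreenConfig(anchorProbe = "nope")),
               "not in matrix")
  expect_error(screenGenes(sim$cohort, cfg), "not housekeeping-normalized")
})

test_that("noise-free planted blocks are fully recovered by the screen", {
  sim <- simulateCohort(SimParams(nTumors = 10, nBackground = 10,
                                  nAnchorBlock = 6, nSubtypeBlock = 0,
                                  nSubtypeTumors = 0, noiseSigmaLog2 = 0,
                                  sampleScaleSigmaLog2 = 0, seed = 8))
  norm <- housekeepingNormalize(sim$cohort)
  scr <- screenGenes(norm, ScreenConfig(anchorProbe = "SPARC_at"))
  tab <- as.data.frame(screenTable(scr))
  block <- sim$truth$probe_id[sim$truth$block == "anchor_block"]
  # equal loadings on the shared factor, no noise: correlation is exact
  expect_true(all(tab$anchor_r[tab$probe_id %in% block] >= 0.99))

  # with lambda = 0 and no noise the SE ratio equals planted rho exactly
  sim0 <- simulateCohort(SimParams(nTumors = 6, nBackground = 8,
                                   nAnchorBlock = 0, nSubtypeBlock = 0,
                                   nSubtypeTumors = 0, noiseSigmaLog2 = 0,
                                   sampleScaleSigmaLog2 = 0,
                                   backgroundRho = c(12, 0.5, 3, 7, 22),
                                   seed = 13))
  norm0 <- housekeepingNormalize(sim0$cohort)
  bg <- sim0$truth$probe_id[sim0$truth$block == "background"]
  for (mode in c("mean_of_paired_ratios", "ratio_of_means"))
    expect_equal(unname(seRatio(norm0, bg, mode)),
                 unname(sim0$truth[bg, "rho"]), tolerance = 1e-12)
})

test_that("expression ranking is by descending amount, ties by probe id", {
  stroma <- matrix(c(5, 3, 9, 3), ncol = 1,
                   dimnames = list(c("a", "b", "c", "ab"), "T1"))
  stroma <- cbind(stroma, T2 = c(5, 3, 9, 3), T3 = c(5, 3, 9, 3))
  epi <- matrix(1, 4, 3, dimnames = dimnames(stroma))
  cohort <- housekeepingNormalize(makePairedCohort(stroma, epi, hk = 1))
  rk <- rankByExpression(cohort, "T1_S", probes = c("a", "b", "c", "ab"))
  expect_identical(rk$probe_id, c("c", "a", "ab", "b"))  # tie: ab < b
  expect_identical(rk$rank, 1:4)

  # larger instance vs an independent sort oracle
  sim <- simulateCohort(SimParams(nTumors = 5, nBackground = 100,
                                  seed = 17))
  norm <- housekeepingNormalize(sim$cohort)
  s1 <- stromaSamples(norm)[1]
  rk2 <- rankByExpression(norm, s1)
  e <- SummarizedExperiment::assay(norm, "exprs")[, s1]
  want <- names(e)[order(-e, names(e))]
  expect_identical(rk2$probe_id, want)
  expect_error(rankByExpression(norm, "missing_sample"), "not in matrix")
})

test_that("threshold counts exclude the anchor, NAs, and are inclusive", {
  # exactly representable r = 0.5 between (1,2,3) and (1,3,2)
  stroma <- rbind(A_at = c(1, 2, 3), half = c(1, 3, 2),
                  flat = c(2, 2, 2))
  colnames(stroma) <- paste0("T", 1:3)
  epi <- matrix(1, 3, 3, dimnames = dimnames(stroma))
  cohort <- housekeepingNormalize(makePairedCohort(stroma, epi, hk = 1))
  r <- anchorCorrelation(cohort, "A_at")
  expect_identical(unname(r["half"]), 0.5)
  # inclusive at the threshold; anchor itself and the NA probe not counted
  expect_identical(countProbesAtThreshold(cohort, "A_at", 0.5), 1L)
  expect_identical(countProbesAtThreshold(cohort, "A_at", 0.6), 0L)

  # planted noise-free block of k perfectly correlated probes
  simk <- simulateCohort(SimParams(nTumors = 8, nBackground = 0,
                                   nAnchorBlock = 4, nSubtypeBlock = 0,
                                   nSubtypeTumors = 0, noiseSigmaLog2 = 0,
                                   sampleScaleSigmaLog2 = 0, seed = 2))
  normk <- housekeepingNormalize(simk$cohort)
  expect_identical(countProbesAtThreshold(normk, "SPARC_at", 0.999), 4L)

  # stochastic cohort equals the brute-force recount at several thresholds
  sim <- simulateCohort(SimParams(nTumors = 10, nBackground = 30,
                                  nAnchorBlock = 5, seed = 19))
  norm <- housekeepingNormalize(sim$cohort)
  x <- SummarizedExperiment::assay(norm, "exprs")
  for (rmin in c(0.9, 0.8, 0.6))
    expect_identical(
      countProbesAtThreshold(norm, "SPARC_at", rmin),
      oracleCountAtThreshold(x, stromaSamples(norm), "SPARC_at", rmin))
})

test_that("anchor correlation is invariant to positive affine rescaling", {
  sim <- simulateCohort(SimParams(nTumors = 8, nBackground = 10, seed = 23))
  norm <- housekeepingNormalize(sim$cohort)
  x <- SummarizedExperiment::assay(norm, "exprs")
  p <- "BG_0003_at"
  y <- x
  y[p, ] <- 2.5 * y[p, ] + 7          # positive affine map of one probe
  scaled <- StromaCohort(y, annotationOf(norm))
  r1 <- anchorCorrelation(norm, "SPARC_at", probes = p)
  r2 <- anchorCorrelation(scaled, "SPARC_at", probes = p)
  expect_equal(unname(r1), unname(r2), tolerance = 1e-12)
})
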