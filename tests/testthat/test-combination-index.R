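sham_design <- function(Dm = 10, m = 1.5, ratio = c(1, 1), nDoses = 5L) {
  sim <- simulateConstantRatio(AgentModel("A", Dm, m), AgentModel("B", Dm, m),
                               interactionSpec("loewe_additive", ratio = ratio),
                               nDoses = nDoses, cv = 0)
  constantRatioDesign(sim$drA, sim$drB, sim$drMix)
}

test_that("sham combinations are exactly additive at every effect level", {
  set.seed(11)
  for (i in 1:10) {
    des <- sham_design(Dm = runif(1, 1, 60), m = runif(1, 0.6, 3),
                       ratio = runif(2, 0.2, 1))
    ci <- computeCI(des, seq(0.1, 0.9, by = 0.1))
    expect_equal(ci$ci, rep(1, 9), tolerance = 1e-6)
  }
})

test_that("fixed-ci ground truth is recovered, and doubling the mixture Dm doubles CI", {
  A <- AgentModel("A", 10, 1.5); B <- AgentModel("B", 40, 1.5)
  for (target in c(0.25, 0.5, 2)) {
    sim <- simulateConstantRatio(A, B, interactionSpec("fixed_ci", target),
                                 cv = 0)
    des <- constantRatioDesign(sim$drA, sim$drB, sim$drMix)
    expect_equal(computeCI(des, 0.5)$ci, target, tolerance = 0.01 * target)
  }

  # hand-built check: mixture needing twice the Loewe-additive dose -> CI = 2
  add <- simulateConstantRatio(A, B, interactionSpec("loewe_additive"), cv = 0)
  p <- faValues(add$drMix)
  doubled <- DoseResponse(add$drMix@compoundId, dose = p$dose * 2, fa = p$fa,
                          mixtureRatio = mixtureRatio(add$drMix))
  des2 <- constantRatioDesign(add$drA, add$drB, doubled)
  expect_equal(computeCI(des2, 0.5)$ci, 2, tolerance = 1e-6)
})

test_that("the CI-DRI identity holds on random designs; sham 1:1 gives DRI 2", {
  des <- sham_design()
  d <- dri(des, c(0.3, 0.5, 0.75, 0.9))
  expect_equal(d$dri_a, rep(2, 4), tolerance = 1e-6)
  expect_equal(d$dri_b, rep(2, 4), tolerance = 1e-6)

  set.seed(12)
  for (i in 1:100) {
    sim <- simulateConstantRatio(
      AgentModel("A", runif(1, 2, 40), runif(1, 0.7, 3)),
      AgentModel("B", runif(1, 2, 40), runif(1, 0.7, 3)),
      interactionSpec("fixed_ci", runif(1, 0.2, 3),
                      ratio = runif(2, 0.1, 1)),
      cv = 0)
    des <- constantRatioDesign(sim$drA, sim$drB, sim$drMix)
    fa <- runif(1, 0.1, 0.9)
    ci <- computeCI(des, fa)$ci
    d <- dri(des, fa)
    expect_equal(1 / d$dri_a + 1 / d$dri_b, ci, tolerance = 1e-9)
  }

  # symmetric strong synergy: CI = 0.25 with equal shares -> DRI 8 each
  simS <- simulateConstantRatio(AgentModel("A", 10, 1.5),
                                AgentModel("B", 10, 1.5),
                                interactionSpec("fixed_ci", 0.25,
                                                ratio = c(1, 1)), cv = 0)
  dS <- dri(constantRatioDesign(simS$drA, simS$drB, simS$drMix), 0.5)
  expect_equal(c(dS$dri_a, dS$dri_b), c(8, 8), tolerance = 1e-4)
})

test_that("relabeling the components swaps DRI and leaves CI unchanged", {
  A <- AgentModel("A", 5, 1.2); B <- AgentModel("B", 30, 2.1)
  sim <- simulateConstantRatio(A, B, interactionSpec("fixed_ci", 0.6), cv = 0)
  des <- constantRatioDesign(sim$drA, sim$drB, sim$drMix)
  w <- ratioWeights(des)
  swapped <- constantRatioDesign(sim$drB, sim$drA, sim$drMix,
                                 weights = rev(w))
  fa <- c(0.4, 0.6)
  expect_equal(computeCI(swapped, fa)$ci, computeCI(des, fa)$ci,
               tolerance = 1e-9)
  expect_equal(dri(swapped, fa)$dri_a, dri(des, fa)$dri_b, tolerance = 1e-9)
  expect_equal(dri(swapped, fa)$dri_b, dri(des, fa)$dri_a, tolerance = 1e-9)
})

test_that("the weighted CI is the printed formula", {
  expect_equal(ciWeighted(1, 1, 1, 1), 1)
  expect_equal(ciWeighted(2, 2, 2, 2), 2)
  expect_equal(ciWeighted(0.5, 0.4, 0.3, 0.2), 0.30)
  expect_error(ciWeighted(0.5, -1, 0.3, 0.2))
})

test_that("grading reproduces every published weighted-CI fixture", {
  # all (CI_wt, symbol) pairs of the two reference result tables
  fixtures <- rbind(
    data.frame(ci = c(0.868, 0.376, 0.552, 0.665, 0.340, 0.361, 0.302,
                      0.727, 0.351, 0.077, 0.827),
               sym = c("+", "+++", "+++", "+++", "+++", "+++", "+++",
                       "++", "+++", "+++++", "++")),
    data.frame(ci = c(1.061, 0.337, 0.523, 0.490, 0.588, 0.517, 1.008,
                      1.033, 0.404, 0.694, 0.791, 0.774, 0.559, 1.076,
                      0.895, 1.160, 0.944, 1.349, 1.336),
               sym = c("\u00b1", "+++", "+++", "+++", "+++", "+++", "\u00b1",
                       "\u00b1", "+++", "+++", "++", "++", "+++", "\u00b1",
                       "+", "-", "\u00b1", "--", "--")))
  expect_equal(gradeCI(fixtures$ci), fixtures$sym)
  expect_equal(gradeCI(1), "\u00b1")
})

test_that("grading is a non-increasing step function with closed lower bounds", {
  grid <- sort(c(seq(0.01, 4, by = 0.01),
                 c(0.1, 0.3, 0.7, 0.85, 0.90, 1.10, 1.20, 1.45, 3.3)))
  ranks <- match(gradeCI(grid),
                 c("+++++", "++++", "+++", "++", "+", "\u00b1",
                   "-", "--", "---", "----"))
  expect_true(all(diff(ranks) >= 0))
  # boundary membership: synergy bands closed below, additive band closed
  expect_equal(gradeCI(c(0.1, 0.3, 0.85, 0.90, 1.10, 1.2000001, 3.301)),
               c("++++", "+++", "+", "\u00b1", "\u00b1", "--", "----"))
})

test_that("isobologram geometry is consistent with CI", {
  des <- sham_design()
  iso <- isobologramPoints(des)
  # sham point lies exactly on the additivity line d_a/dx_a + d_b/dx_b = 1
  expect_equal(iso$d_a / iso$dx_a + iso$d_b / iso$dx_b, rep(1, 3),
               tolerance = 1e-6)

  A <- AgentModel("A", 10, 1.5); B <- AgentModel("B", 40, 1.5)
  sim <- simulateConstantRatio(A, B, interactionSpec("fixed_ci", 0.5), cv = 0)
  desS <- constantRatioDesign(sim$drA, sim$drB, sim$drMix)
  isoS <- isobologramPoints(desS, levels = 0.5)
  expect_equal(nrow(isoS), 1)
  # CI 0.5: the combination point sits at half the additivity distance
  expect_equal(isoS$d_a / isoS$dx_a + isoS$d_b / isoS$dx_b, 0.5,
               tolerance = 1e-6)
})

test_that("the Fa-CI curve is flat for level-independent designs and flags extrapolation", {
  des <- sham_design()
  curve <- faCiCurve(des)
  expect_equal(curve$ci, rep(1, nrow(curve)), tolerance = 1e-6)

  A <- AgentModel("A", 10, 1.5); B <- AgentModel("B", 40, 1.5)
  sim <- simulateConstantRatio(A, B, interactionSpec("fixed_ci", 0.5), cv = 0)
  desS <- constantRatioDesign(sim$drA, sim$drB, sim$drMix)
  curveS <- faCiCurve(desS, faGrid = seq(0.2, 0.8, by = 0.1))
  expect_equal(curveS$ci, rep(0.5, 7), tolerance = 1e-6)

  # a grid entirely outside the observed fa window is all-extrapolated
  out <- faCiCurve(des, faGrid = c(0.001, 0.999))
  expect_true(all(out$extrapolated))
})

test_that("sequential deletion: exact data gives zero width, 3x5 doses give 15 deletions", {
  des <- sham_design()
  sda <- sdaConfidence(des, c(0.5, 0.75, 0.9))
  expect_equal(sda$n_deletions, rep(15L, 3))
  expect_equal(sda$mean, rep(1, 3), tolerance = 1e-6)
  expect_equal(sda$halfwidth, rep(0, 3), tolerance = 1e-6)

  short <- sham_design(nDoses = 2L)
  expect_error(sdaConfidence(short), "insufficient data")
})

test_that("sequential-deletion intervals cover the full-data CI on noisy designs", {
  A <- AgentModel("A", 10, 1.5); B <- AgentModel("B", 40, 2)
  inside <- 0; total <- 0
  for (s in 1:40) {
    sim <- simulateConstantRatio(A, B, interactionSpec("fixed_ci", 0.5),
                                 cv = 0.05, seed = 7000 + s)
    des <- tryCatch(constantRatioDesign(sim$drA, sim$drB, sim$drMix),
                    error = function(e) NULL)
    if (is.null(des) || !all(isValidFit(des@fitA), isValidFit(des@fitB),
                             isValidFit(des@fitMix))) next
    full <- computeCI(des, 0.75)$ci
    sda <- sdaConfidence(des, 0.75)
    total <- total + 1
    if (abs(sda$mean - full) <= sda$halfwidth) inside <- inside + 1
  }
  expect_gte(inside / total, 0.9)
})

test_that("analyzeCombination assembles a coherent result object", {
  A <- AgentModel("A", 10, 1.5); B <- AgentModel("B", 40, 1.5)
  sim <- simulateConstantRatio(A, B, interactionSpec("fixed_ci", 0.5),
                               cv = 0, seed = 1)
  res <- analyzeCombination(sim$drA, sim$drB, sim$drMix)
  expect_s4_class(res, "CombinationResult")
  expect_equal(ciWt(res), 0.5, tolerance = 0.01)
  expect_equal(gradeSymbol(res), "+++")
  expect_equal(res@ciAt$fa, c(0.5, 0.75, 0.9, 0.95))
  expect_equal(1 / res@driAt$dri_a + 1 / res@driAt$dri_b, res@ciAt$ci,
               tolerance = 1e-9)
  expect_error(analyzeCombination(sim$drA, sim$drB, sim$drMix,
                                  effectLevels = c(0.5, 0.75)),
               "must include")
})
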