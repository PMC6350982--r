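test_that("scores are anchored at the control means and linear in between", {
  mp <- manual_plate(neg = 1000, pos = 100, extra = c(1000, 100))
  st <- normalizePlate(mp$read, mp$layout)
  s <- scores(st)
  expect_equal(s$score[s$role == "negative_control"], c(0, 0))
  expect_equal(s$score[s$role == "positive_control"], c(1, 1))
  expect_equal(s$score[s$role == "library"], c(0, 1))

  mid <- manual_plate(extra = c(550, 550))  # midway between 1000 and 100
  smid <- scores(normalizePlate(mid$read, mid$layout))
  expect_equal(smid$score[smid$role == "library"], c(0.5, 0.5))
})

test_that("scores and Z' are invariant under affine signal transforms", {
  lay <- primaryScreenLayout("P", sprintf("c%02d", 1:40))
  rd <- simulateScreenPlate(lay, setNames(runif(40), sprintf("c%02d", 1:40)),
                            cv = 0.05, seed = 31)
  base_scores <- scores(normalizePlate(rd, lay))$score
  base_z <- zPrime(rd, lay)$z_prime
  for (k in c(0.2, 3, 17)) {
    scaled <- PlateRead(plateId(rd), within(signals(rd), signal <- signal * k))
    expect_equal(scores(normalizePlate(scaled, lay))$score, base_scores,
                 tolerance = 1e-12)
    expect_equal(zPrime(scaled, lay)$z_prime, base_z, tolerance = 1e-12)
  }
  shifted <- PlateRead(plateId(rd), within(signals(rd), signal <- signal + 500))
  expect_equal(zPrime(shifted, lay)$z_prime, base_z, tolerance = 1e-12)
})

test_that("Z' matches its analytic values and bounds", {
  perfect <- manual_plate(neg = 1000, pos = 100)
  expect_equal(zPrime(perfect$read, perfect$layout)$z_prime, 1)

  # 100 +/- 10 (pos) vs 1000 +/- 20 (neg): Z' = 1 - 3*30/900 = 0.9
  lay_df <- data.frame(row = rep(1:2, 4), col = rep(1:4, each = 2),
                       role = rep(c("negative_control", "positive_control"),
                                  each = 4),
                       compound_id = NA, concentration = NA,
                       pt_drug_id = NA, pt_concentration = NA)
  lay <- PlateLayout("Z", lay_df)
  # 4 control values engineered to mean 1000, sd 20 and mean 100, sd 10
  neg <- 1000 + (c(1, -1, 2, -2) - 0) * (20 / sd(c(1, -1, 2, -2)))
  pos <- 100 + (c(1, -1, 2, -2) - 0) * (10 / sd(c(1, -1, 2, -2)))
  rd <- PlateRead("Z", data.frame(row = lay_df$row, col = lay_df$col,
                                  signal = c(neg, pos)))
  qc <- zPrime(rd, lay, threshold = 0.4)
  expect_equal(qc$z_prime, 0.9, tolerance = 1e-12)
  expect_true(qc$pass)

  # noisy-controls case: 3(SD_pos + SD_neg) > |dAv| drives Z' negative
  wide_neg <- 1000 + (c(1, -1, 2, -2)) * (300 / sd(c(1, -1, 2, -2)))
  rd2 <- PlateRead("Z", data.frame(row = lay_df$row, col = lay_df$col,
                                   signal = c(wide_neg, pos)))
  qc2 <- zPrime(rd2, lay)
  expect_lt(qc2$z_prime, 0)
  expect_false(qc2$pass)
})

test_that("degenerate plates are refused", {
  flat <- manual_plate(neg = 500, pos = 500)
  expect_error(normalizePlate(flat$read, flat$layout), "degenerate")
  expect_error(zPrime(flat$read, flat$layout), "degenerate")
})

test_that("hit calling applies the noise floor and both rule variants", {
  mk <- function(mean, sd, floor = 0.1, above = mean > floor)
    data.frame(compound_id = "c1", mean = mean, sd = sd, n = 2,
               noise_floor = floor, above_noise_floor = above)

  # clear hit under both variants
  hit <- callHits(mk(0.30, 0.05), mk(0.60, 0.05))
  expect_true(hit$is_hit)
  expect_true(callHits(mk(0.30, 0.05), mk(0.60, 0.05),
                       ruleVariant = "strict")$is_hit)

  # below the noise floor: not considered at all
  expect_false(callHits(mk(0.30, 0.05), mk(0.08, 0.02))$is_hit)

  # combination scoring lower than alone (the taxane pattern): not a hit
  expect_false(callHits(mk(0.60, 0.05), mk(0.30, 0.05))$is_hit)

  # near-equal means: as-printed needs the higher combo mean
  expect_false(callHits(mk(0.40, 0.05), mk(0.40, 0.05))$is_hit)
  expect_true(callHits(mk(0.40, 0.05), mk(0.41, 0.05))$is_hit)
  expect_false(callHits(mk(0.40, 0.05), mk(0.41, 0.05),
                        ruleVariant = "strict")$is_hit)

  expect_error(callHits(mk(0.4, 0.1),
                        within(mk(0.5, 0.1), compound_id <- "c9")),
               "pairing error")
})

test_that("a strict hit is always an as-printed hit", {
  set.seed(77)
  for (i in 1:200) {
    alone <- data.frame(compound_id = "c", mean = runif(1, -0.2, 1.2),
                        sd = runif(1, 0, 0.3), n = 2, noise_floor = 0.08,
                        above_noise_floor = NA)
    combo <- data.frame(compound_id = "c", mean = runif(1, -0.2, 1.2),
                        sd = runif(1, 0, 0.3), n = 2, noise_floor = 0.08,
                        above_noise_floor = NA)
    combo$above_noise_floor <- combo$mean > combo$noise_floor
    strict <- callHits(alone, combo, ruleVariant = "strict")$is_hit
    printed <- callHits(alone, combo, ruleVariant = "as_printed")$is_hit
    if (strict) expect_true(printed)
  }
})

test_that("compoundScores pools replicates and flags the floor", {
  ids <- c("c1", "c2")
  lay <- primaryScreenLayout("P", ids)
  truth <- c(c1 = 0.5, c2 = 0.02)
  sts <- lapply(1:2, function(r)
    normalizePlate(simulateScreenPlate(lay, truth, cv = 0.03,
                                       seed = 400 + r,
                                       replicateId = paste0("r", r)), lay))
  cs <- compoundScores(sts)
  expect_equal(cs$n, c(2, 2))
  expect_equal(cs$mean[cs$compound_id == "c1"], 0.5, tolerance = 0.1)
  expect_true(cs$above_noise_floor[cs$compound_id == "c1"])
  expect_false(cs$above_noise_floor[cs$compound_id == "c2"])
})

test_that("score-to-fa clipping keeps the log-linearization defined", {
  expect_equal(scoreToFa(c(-0.5, 0.5, 1.7)), c(0.001, 0.5, 0.999))
  expect_equal(scoreToFa(0.4, clip = NULL), 0.4)
  expect_error(scoreToFa(0.5, clip = c(0, 0.9)))
})
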