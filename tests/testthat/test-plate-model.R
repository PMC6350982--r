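test_that("well names round-trip and malformed names are rejected", {
  rc <- expand.grid(row = 1:16, col = 1:24)
  nm <- wellName(rc$row, rc$col)
  back <- parseWellName(nm)
  expect_equal(back$row, rc$row)
  expect_equal(back$col, rc$col)
  expect_error(parseWellName("1A"), "malformed")
  expect_error(parseWellName("A0x"), "malformed")
})

test_that("layout validation rejects every invariant violation", {
  df <- tiny_layout_df()
  expect_s4_class(PlateLayout("P", df), "PlateLayout")

  dup <- rbind(df, df[1, ])
  expect_error(PlateLayout("P", dup), "duplicate")

  bad_role <- df; bad_role$role[5] <- "mystery"
  expect_error(PlateLayout("P", bad_role), "unknown well role")

  ctrl_cmpd <- df; ctrl_cmpd$compound_id[1] <- "c9"
  expect_error(PlateLayout("P", ctrl_cmpd), "control wells")

  off <- df; off$col[5] <- 99
  expect_error(PlateLayout("P", off), "outside plate geometry")

  loaded_empty <- rbind(df, data.frame(row = 3, col = 1, role = "empty",
                                       compound_id = "c3", concentration = 10,
                                       pt_drug_id = NA, pt_concentration = NA))
  expect_error(PlateLayout("P", loaded_empty), "empty wells")

  mixed_pt <- df
  mixed_pt$pt_drug_id <- "cisplatin"; mixed_pt$pt_concentration <- 15
  mixed_pt$pt_drug_id[6] <- "oxaliplatin"
  expect_error(PlateLayout("P", mixed_pt), "mixed")

  partial_pt <- df
  partial_pt$pt_drug_id[1:5] <- "cisplatin"
  partial_pt$pt_concentration[1:5] <- 15
  expect_error(PlateLayout("P", partial_pt), "mixed|partial")
})

test_that("random mutations of a valid 384-well layout are rejected", {
  lay <- primaryScreenLayout("P", sprintf("c%03d", 1:320))
  w <- wells(lay)
  set.seed(42)
  for (i in 1:20) {
    bad <- w
    mode <- sample(3, 1)
    j <- sample(nrow(w), 1)
    if (mode == 1) {                       # duplicate a well address
      k <- sample(setdiff(seq_len(nrow(w)), j), 1)
      bad$row[j] <- bad$row[k]; bad$col[j] <- bad$col[k]
    } else if (mode == 2) {                # invent a role
      bad$role[j] <- "banana"
    } else {                               # put a compound in a control well
      j <- sample(which(w$role == "negative_control"), 1)
      bad$compound_id[j] <- "c001"
    }
    expect_error(PlateLayout("P", bad))
  }
})

test_that("primary screen layout matches the control-column convention", {
  lay <- primaryScreenLayout("P1", sprintf("c%03d", 1:320))
  w <- wells(lay)
  expect_equal(nrow(w), 384)
  expect_true(all(w$role[w$col %in% 1:2] == "negative_control"))
  expect_true(all(w$role[w$col %in% 23:24] == "positive_control"))
  expect_equal(sum(w$role == "library"), 320)
  # confirmation layout keeps all edges free
  conf <- confirmationLayout("C1", sprintf("c%03d", 1:10))
  wc <- wells(conf)
  expect_false(any(wc$row %in% c(1, 16) | wc$col %in% c(1, 2, 23, 24)))
})

test_that("layout and plate-read files round-trip", {
  dir <- withr::local_tempdir()
  lay <- primaryScreenLayout("P1", sprintf("c%03d", 1:20), ptDrug = "cisplatin",
                             ptConcentration = 15)
  f <- file.path(dir, "layout.csv")
  writePlateLayout(lay, f)
  lay2 <- readPlateLayout(f)
  expect_equal(wells(lay2), wells(lay))
  expect_equal(plateId(lay2), "P1")

  rd <- simulateScreenPlate(lay, setNames(runif(20), sprintf("c%03d", 1:20)),
                            seed = 3)
  g <- file.path(dir, "read.csv")
  writePlateRead(rd, g)
  rd2 <- readPlateRead(g)
  expect_equal(signals(rd2)[order(signals(rd2)$row, signals(rd2)$col), ],
               signals(rd)[order(signals(rd)$row, signals(rd)$col), ],
               ignore_attr = TRUE)
})

test_that("layout reader rejects degenerate files", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "empty.csv")
  writeLines("plate_id,well,role", f)
  expect_error(readPlateLayout(f), "empty")

  g <- file.path(dir, "dup.csv")
  writeLines(c("plate_id,well,role",
               "P,A1,negative_control", "P,A1,negative_control"), g)
  expect_error(readPlateLayout(g), "duplicate")
})

test_that("dose-response files round-trip, including mixtures", {
  dir <- withr::local_tempdir()
  set.seed(7)
  for (i in 1:5) {
    n <- sample(3:6, 1)
    dr <- DoseResponse(paste0("d", i),
                       dose = rep(sort(runif(n, 0.1, 50)), each = 2),
                       fa = runif(2 * n),
                       mixtureRatio = if (i %% 2) NULL else
                         list(components = c("x", "y"),
                              weights = runif(2, 0.1, 1)))
    f <- file.path(dir, "dr.csv")
    writeDoseResponse(dr, f)
    dr2 <- readDoseResponse(f)
    expect_equal(faValues(dr2), faValues(dr))
    expect_equal(mixtureRatio(dr2)$weights, mixtureRatio(dr)$weights,
                 tolerance = 1e-12)
  }
})

test_that("dose-response reader reports offending rows", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.csv")
  writeLines(c("compound_id,dose,replicate,fa",
               "c,1,1,0.2", "c,2,1,1.2", "c,4,1,0.5"), f)
  expect_error(readDoseResponse(f), "fa outside \\[0, 1\\] at row\\(s\\) 2")
  g <- file.path(dir, "bad2.csv")
  writeLines(c("compound_id,dose,replicate,fa", "c,-1,1,0.2"), g)
  expect_error(readDoseResponse(g), "non-positive dose")
})

test_that("the 5-dose, 4-replicate constant-ratio file parses to 20 fa values", {
  dir <- withr::local_tempdir()
  dr <- simulateDoseResponse(AgentModel("cisplatin", 15, 1.5),
                             two_fold_doses(15), nRep = 4, seed = 11)
  f <- file.path(dir, "dr.csv")
  writeDoseResponse(dr, f)
  expect_equal(nrow(faValues(readDoseResponse(f))), 20)
})

test_that("HCA object tables round-trip and validate", {
  dir <- withr::local_tempdir()
  tabs <- list(simulateHCAObjects(50, 10, seed = 1, well = "B3", timepoint = 24),
               simulateHCAObjects(30, 30, seed = 2, well = "B4", timepoint = 72))
  f <- file.path(dir, "hca.csv")
  writeHCAObjects(tabs, f)
  back <- readHCAObjects(f)
  expect_length(back, 2)
  expect_equal(back[[1]]@objects, tabs[[1]]@objects, tolerance = 1e-12)
  expect_equal(back[[2]]@timepoint, 72)
  expect_error(HCAObjectTable("A1", 24,
                              data.frame(hoechst = -1, pi = 1, calcein = 1)),
               "non-negative")
})

test_that("DoseResponse construction enforces its invariants", {
  expect_error(DoseResponse("c", dose = c(1, -2), fa = c(.1, .2)),
               "positive")
  expect_error(DoseResponse("c", dose = c(1, 2), fa = c(.1, 1.2)),
               "fa outside")
  expect_error(DoseResponse("c", dose = 1:2, fa = c(.1, .2),
                            mixtureRatio = list(components = c("a", "b"),
                                                weights = c(1, -1))),
               "positive")
})
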