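makeWell <- function(plate_id, row, col, drug, conc, stim, lum,
                     sample = "S001") {
  data.frame(sample_id = sample, plate_id = plate_id, well_row = row,
             well_col = col, drug = drug, drug_conc_nM = conc,
             stimulus = stim, luminescence = lum, stringsAsFactors = FALSE)
}

test_that("plate normalization divides by the interior DMSO median", {
  wells <- rbind(
    makeWell("P1", 2L, 2L, "DMSO", NA, "none", 1000),
    makeWell("P1", 2L, 3L, "DMSO", NA, "none", 1000),
    makeWell("P1", 2L, 4L, "DMSO", NA, "none", 1000),
    makeWell("P1", 3L, 2L, "DrugA", 100, "none", 1000),
    makeWell("P1", 3L, 3L, "DrugB", 100, "none", 2000)
  )
  se <- normalizeWells(wells)
  v <- SummarizedExperiment::assay(se, "logV")
  expect_equal(v["DrugA_100", "S001"], 0)
  expect_equal(v["DrugB_100", "S001"], log(2), tolerance = 1e-12)
})

test_that("edge DMSO controls are excluded from the reference median", {
  wells <- rbind(
    makeWell("P1", 2L, 2L, "DMSO", NA, "none", 1000),
    makeWell("P1", 2L, 3L, "DMSO", NA, "none", 1200),
    makeWell("P1", 1L, 5L, "DMSO", NA, "none", 10),    # outer edge
    makeWell("P1", 3L, 2L, "DrugA", 100, "none", 1100)
  )
  v <- SummarizedExperiment::assay(normalizeWells(wells), "logV")
  expect_equal(v["DrugA_100", "S001"], 0, tolerance = 1e-12)

  # only edge controls -> normalization impossible
  onlyEdge <- wells[3:4, ]
  expect_error(normalizeWells(onlyEdge), "interior DMSO")
  bad <- wells
  bad$luminescence[4] <- 0
  expect_error(normalizeWells(bad), "positive")
})

test_that("replicate wells of a condition are averaged after the log", {
  wells <- rbind(
    makeWell("P1", 2L, 2L, "DMSO", NA, "none", 1000),
    makeWell("P1", 3L, 2L, "DrugA", 100, "none", 1000),
    makeWell("P1", 3L, 3L, "DrugA", 100, "none", 4000)
  )
  v <- SummarizedExperiment::assay(normalizeWells(wells), "logV")
  expect_equal(v["DrugA_100", "S001"], mean(c(log(1), log(4))),
               tolerance = 1e-12)
})

test_that("multiplying all wells of one plate cancels out", {
  design <- tinyDesign(nSamples = 4L)
  truth <- flatTruth(design, betaD = c(DrugA = -0.4, DrugB = 0.1),
                     betaS = c(Stim1 = 0.2, Stim2 = 0, Stim3 = -0.3))
  sim <- simulateScreen(design, truth, seed = 3)
  v0 <- SummarizedExperiment::assay(normalizeWells(sim$wells), "logV")
  boosted <- sim$wells
  onPlate <- boosted$plate_id == boosted$plate_id[1]
  boosted$luminescence[onPlate] <- boosted$luminescence[onPlate] * 7.3
  v1 <- SummarizedExperiment::assay(normalizeWells(boosted), "logV")
  expect_equal(v0, v1, tolerance = 1e-12)
})

test_that("zero-noise generator output equals the planted effect sums", {
  design <- tinyDesign(nSamples = 4L)
  truth <- flatTruth(design, betaD = c(DrugA = -0.4, DrugB = 0.1),
                     betaS = c(Stim1 = 0.2, Stim2 = 0, Stim3 = -0.3),
                     betaInt = data.frame(drug = "DrugA", stimulus = "Stim1",
                                          feature = "all", beta = 0.5),
                     noiseSd = 1e-13, plateEffectSd = 0)
  sim <- simulateScreen(design, truth, seed = 4)
  v <- SummarizedExperiment::assay(normalizeWells(sim$wells), "logV")
  n <- ncol(v)
  # low concentration carries betaD, high concentration is scaled
  expect_equal(unname(v["DrugA_50", ]), rep(-0.4, n), tolerance = 1e-10)
  expect_equal(unname(v["DrugA_500", ]), rep(-0.8, n), tolerance = 1e-10)
  expect_equal(unname(v["Stim1", ]), rep(0.2, n), tolerance = 1e-10)
  expect_equal(unname(v["DrugA_50:Stim1", ]), rep(-0.4 + 0.2 + 0.5, n),
               tolerance = 1e-10)
  expect_equal(unname(v["DrugB_100:Stim3", ]), rep(0.1 - 0.3, n),
               tolerance = 1e-10)
})

test_that("robust z-scaling centres at the median and scales by the MAD", {
  z <- robustZ(rbind(a = c(1, 2, 3, 4, 5)))$z
  expect_equal(unname(z["a", ]), c(-2, -1, 0, 1, 2))
  # constant row: MAD floor engages, all zeros
  zc <- robustZ(rbind(a = rep(3, 5)))$z
  expect_equal(unname(zc["a", ]), rep(0, 5))
  # centering identity on arbitrary rows
  set.seed(1)
  x <- matrix(rnorm(50), 5)
  zz <- robustZ(x)$z
  expect_equal(unname(apply(zz, 1, median)), rep(0, 5), tolerance = 1e-12)
  # display copy is clipped, stored values are not
  r <- robustZ(rbind(a = c(0, 0, 0, 0.001, 100)), cap = 4)
  expect_gt(max(r$z), 4)
  expect_lte(max(r$display), 4)
  expect_error(robustZ(rbind(a = c(NA_real_, NA_real_))), "no observed")
})

test_that("Benjamini-Hochberg adjustment matches the textbook step-up", {
  expect_equal(bhAdjust(0.05), 0.05)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, bhOracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pairwise correlations flag the right pairs at the FDR", {
  set.seed(7)
  n <- 40
  base <- rnorm(n)
  x <- cbind(a = base + rnorm(n, 0, 0.1),
             b = base + rnorm(n, 0, 0.1),
             c = rnorm(n),
             d = 2 * base + rnorm(n, 0, 0.2))
  res <- pairwiseCorrelations(x, fdr = 0.05)
  expect_equal(diag(res$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(res$r, t(res$r))
  expect_true(res$significant["a", "b"])
  expect_true(res$significant["a", "d"])
  expect_false(res$significant["a", "c"])
  # exact linearity
  lin <- pairwiseCorrelations(cbind(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8)))
  expect_equal(lin$r["x", "y"], 1, tolerance = 1e-12)
  # constant column excluded from estimation and adjustment
  cc <- pairwiseCorrelations(cbind(x = rnorm(10), k = rep(1, 10)))
  expect_true(is.na(cc$r["x", "k"]))
  # positive semi-definite on complete data
  ev <- eigen(res$r, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
})
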