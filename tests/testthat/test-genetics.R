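makeEncodingInputs <- function() {
  samples <- sprintf("S%02d", 1:10)
  g <- cbind(
    TP53 = c(1L, 0L, 0L, 1L, 0L, 0L, 0L, 1L, 0L, 0L),
    KRAS = c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    BRAF = c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    NRAS = c(0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L),
    rare = c(NA, NA, NA, 0L, 1L, 0L, 0L, 0L, 0L, 0L)  # 30% missing
  )
  rownames(g) <- samples
  ann <- data.frame(sample_id = samples,
                    IGHV = c("M", "U", "M", "M", "U", "U", "M", "U", "M", "U"),
                    methylation = c("HP", "LP", "IP", "HP", "LP", "LP", "IP",
                                    "LP", "HP", "LP"),
                    stringsAsFactors = FALSE)
  list(g = g, ann = ann)
}

test_that("feature encoding applies the published conventions", {
  inp <- makeEncodingInputs()
  x <- encodeFeatures(inp$g, inp$ann)
  # RAS/RAF collapsing: 1 if any of KRAS/BRAF/NRAS mutated
  expect_true("RAS/RAF" %in% colnames(x))
  expect_false(any(c("KRAS", "BRAF", "NRAS") %in% colnames(x)))
  expect_equal(unname(x[c("S01", "S02", "S05"), "RAS/RAF"]), c(1, 1, 1))
  expect_equal(unname(x["S03", "RAS/RAF"]), 0)
  # IGHV M = 1 / U = 0; methylation LP = 0, IP = 0.5, HP = 1
  expect_equal(unname(x["S01", "IGHV"]), 1)
  expect_equal(unname(x["S02", "IGHV"]), 0)
  expect_equal(unname(x["S03", "Methylation"]), 0.5)
  expect_equal(unname(x["S01", "Methylation"]), 1)
  expect_equal(unname(x["S02", "Methylation"]), 0)
  # >= 20% missingness drops the feature
  expect_false("rare" %in% colnames(x))
  expect_true("rare" %in% attr(x, "droppedFeatures"))
  expect_false(anyNA(x))
  # complete-case filtering over retained features
  g2 <- inp$g[, "TP53", drop = FALSE]
  g2[1, 1] <- NA  # 10% missing: feature kept, sample dropped
  x2 <- encodeFeatures(g2, inp$ann)
  expect_false("S01" %in% rownames(x2))
  expect_equal(attr(x2, "droppedSamples"), 1L)
})

test_that("univariate carrier tests match the pooled-variance t oracle", {
  responses <- cbind(StimA = c(0.9, 1.0, 1.1, -0.1, 0.0, 0.1),
                     StimB = c(0, 0, 0, 0, 0, 0))
  rownames(responses) <- sprintf("S%d", 1:6)
  features <- cbind(mut = c(1L, 1L, 1L, 0L, 0L, 0L))
  rownames(features) <- rownames(responses)
  res <- univariateResponseTests(responses, features, minPositive = 3L,
                                 fdr = 0.1)
  hit <- res[res$stimulus == "StimA", ]
  oracle <- tOracle(c(0.9, 1.0, 1.1), c(-0.1, 0.0, 0.1))
  expect_equal(hit$t, oracle$t, tolerance = 1e-12)
  expect_equal(hit$t, 12.24745, tolerance = 1e-5)
  expect_equal(hit$p, oracle$p, tolerance = 1e-12)
  expect_equal(oracle$df, 4)
  # zero variance in both groups: p missing, excluded from adjustment
  flat <- res[res$stimulus == "StimB", ]
  expect_true(is.na(flat$p))
  expect_true(is.na(flat$padj))

  # identical group values: t = 0, p = 1
  resp2 <- cbind(S = c(1, 2, 3, 1, 2, 3))
  rownames(resp2) <- rownames(responses)
  sym <- univariateResponseTests(resp2, features, minPositive = 3L)
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)
})

test_that("features below the carrier minimum are excluded", {
  set.seed(1)
  responses <- matrix(rnorm(40), 20, 2,
                      dimnames = list(sprintf("S%02d", 1:20), c("A", "B")))
  features <- cbind(common = rbinom(20, 1, 0.5),
                    rare = c(1L, 1L, rep(0L, 18)))
  rownames(features) <- rownames(responses)
  res <- univariateResponseTests(responses, features, minPositive = 3L)
  expect_false("rare" %in% res$feature)
  expect_true("common" %in% res$feature)
  # t-test oracle equivalence on random instances
  set.seed(2)
  for (i in 1:100) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1))
    tt <- twoSampleTTest(x, y)
    or <- tOracle(x, y)
    expect_equal(tt$t, or$t, tolerance = 1e-12)
    expect_equal(tt$p, or$p, tolerance = 1e-10)
  }
})

test_that("gaussian stability selection recovers a planted predictor", {
  set.seed(10)
  n <- 100
  X <- cbind(trisomy12 = rbinom(n, 1, 0.2),
             matrix(rbinom(n * 10, 1, 0.3), n,
                    dimnames = list(NULL, paste0("noise", 1:10))))
  rownames(X) <- sprintf("S%03d", 1:n)
  y <- 0.8 * X[, "trisomy12"] + rnorm(n, 0, 0.1)
  ss <- lassoStabilityGaussian(X, y, nBoot = 30, freqThreshold = 0.75,
                               seed = 1)
  expect_true("trisomy12" %in% keptPredictors(ss))
  tab <- selectionTable(ss)
  expect_gt(tab$frequency[tab$predictor == "trisomy12"], 0.75)
  expect_gt(tab$meanCoef[tab$predictor == "trisomy12"], 0)
  # frequencies are exact multiples of 1/nBoot
  expect_true(all(abs(tab$frequency * 30 - round(tab$frequency * 30)) < 1e-12))
  # determinism
  ss2 <- lassoStabilityGaussian(X, y, nBoot = 30, freqThreshold = 0.75,
                                seed = 1)
  expect_identical(selectionTable(ss), selectionTable(ss2))
  # kept sets shrink as the threshold grows
  k90 <- sum(selectionTable(lassoStabilityGaussian(X, y, nBoot = 30,
                                                   freqThreshold = 0.9,
                                                   seed = 1))$kept)
  expect_lte(k90, sum(tab$kept))
  # constant response cannot select anything
  expect_warning(empty <- lassoStabilityGaussian(X, rep(1, n), nBoot = 5,
                                                 seed = 1), "constant")
  expect_equal(length(keptPredictors(empty)), 0L)
})

test_that("two bootstraps with threshold 0.75 require selection in both", {
  set.seed(11)
  n <- 60
  X <- cbind(a = rnorm(n), b = rnorm(n))
  rownames(X) <- sprintf("S%03d", 1:n)
  y <- 2 * X[, "a"] + rnorm(n, 0, 0.1)
  ss <- lassoStabilityGaussian(X, y, nBoot = 2, freqThreshold = 0.75, seed = 3)
  tab <- selectionTable(ss)
  expect_true(all(tab$frequency %in% c(0, 0.5, 1)))
  expect_true(all(tab$kept == (tab$frequency == 1)))
})

test_that("multinomial stability selection finds cluster-defining features", {
  set.seed(12)
  n <- 160
  labels <- rep(paste0("C", 1:4), each = n / 4)
  defining <- sapply(1:4, function(k) {
    rbinom(n, 1, ifelse(labels == paste0("C", k), 0.9, 0.1))
  })
  colnames(defining) <- paste0("def", 1:4)
  X <- cbind(defining, noise1 = rbinom(n, 1, 0.3), noise2 = rbinom(n, 1, 0.5))
  rownames(X) <- sprintf("S%03d", 1:n)
  ss <- lassoStabilityMultinomial(X, labels, nBoot = 15, seed = 4)
  tab <- selectionTable(ss)
  for (k in 1:4) {
    row <- tab[tab$class == paste0("C", k) & tab$predictor == paste0("def", k), ]
    expect_true(row$kept)
    expect_gt(row$meanCoef, 0)
  }
  # cluster absent below the minimum size errors out
  expect_error(lassoStabilityMultinomial(X[1:44, ], labels[1:44], nBoot = 2,
                                         seed = 1), ">= 5 samples")
})

test_that("interaction modulators are found only for the planted pair", {
  set.seed(13)
  n <- 150
  X <- cbind(IGHV = rbinom(n, 1, 0.5),
             trisomy12 = rbinom(n, 1, 0.2),
             noise1 = rbinom(n, 1, 0.3),
             noise2 = rbinom(n, 1, 0.4))
  rownames(X) <- sprintf("S%03d", 1:n)
  planted <- 0.4 * X[, "IGHV"] - 0.3 * X[, "trisomy12"] + rnorm(n, 0, 0.1)
  null <- rnorm(n, 0, 0.1)
  tab <- rbind(
    data.frame(sample_id = rownames(X), drug = "DrugA", stimulus = "Stim1",
               beta_int = planted),
    data.frame(sample_id = rownames(X), drug = "DrugB", stimulus = "Stim2",
               beta_int = null)
  )
  mods <- interactionModulators(tab, X, nBoot = 20, freqThreshold = 0.9,
                                seed = 5)
  s <- mods$summary
  expect_equal(s$nModulators[s$drug == "DrugA"] > 0, TRUE)
  expect_equal(s$nModulators[s$drug == "DrugB"], 0L)
  kept <- keptPredictors(mods$selections[["DrugA:Stim1"]])
  expect_true(all(c("IGHV", "trisomy12") %in% kept))
  ktab <- selectionTable(mods$selections[["DrugA:Stim1"]])
  expect_gt(ktab$meanCoef[ktab$predictor == "IGHV"], 0)
  expect_lt(ktab$meanCoef[ktab$predictor == "trisomy12"], 0)
  # pairs with too few complete cases are skipped with a warning
  small <- tab[1:5, ]
  expect_warning(m2 <- interactionModulators(small, X[1:5, , drop = FALSE],
                                             nBoot = 5, seed = 1),
                 "skipped")
  expect_true(is.na(m2$summary$nModulators))
})

test_that("the trisomy-12 read-ratio caller uses a strict 1.4 boundary", {
  mk <- function(m12, mOther) {
    data.frame(chrom = c(rep("chr12", 4), rep("chr1", 4)),
               count = c(rep(m12, 4), rep(mOther, 4)))
  }
  r <- callTrisomy12(mk(15, 10))
  expect_equal(r$ratio, 1.5, tolerance = 1e-12)
  expect_true(r$call)
  r <- callTrisomy12(mk(14, 10))
  expect_equal(r$ratio, 1.4, tolerance = 1e-12)
  expect_false(r$call)  # strict inequality
  expect_false(callTrisomy12(mk(10, 10))$call)
  expect_error(callTrisomy12(data.frame(chrom = "chr1", count = 5)),
               "chromosome 12")
  expect_error(callTrisomy12(data.frame(chrom = "chr12", count = 5)),
               "outside")
  # bare "12" labels are accepted too
  expect_true(callTrisomy12(data.frame(chrom = c("12", "1"),
                                       count = c(20, 10)))$call)
})
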