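# Small designs and "flat" ground truths (no latent structure, no
# heterogeneity) used across the suite, plus independent textbook oracles.

tinyDesign <- function(nSamples = 6L,
                       drugs = list(DrugA = c(500, 50), DrugB = 100),
                       stimuli = c("Stim1", "Stim2", "Stim3")) {
  screenDesign(drugs = drugs, stimuli = stimuli, nSamples = nSamples)
}

# truth with every latent/heterogeneity source switched off; effects and
# noise are set explicitly per test
flatTruth <- function(design, betaD = NULL, betaS = NULL, betaInt = NULL,
                      noiseSd = 0.1, plateEffectSd = 0.15, edgeEffect = -0.3,
                      clusterProportions = c(C1 = 0.25, C2 = 0.25,
                                             C3 = 0.25, C4 = 0.25),
                      hazardScale = NULL, censoringMax = 3000,
                      baseHazard = 1 / 1500,
                      featurePrevalence = c(trisomy12 = 0.2, TP53 = 0.1),
                      featureMissingRate = 0,
                      highConcFactor = 2, baseLuminescence = 1e6) {
  drugs <- names(design@drugs)
  stimuli <- design@stimuli
  if (is.null(betaD)) betaD <- stats::setNames(rep(0, length(drugs)), drugs)
  if (is.null(betaS)) betaS <- stats::setNames(rep(0, length(stimuli)), stimuli)
  if (is.null(betaInt))
    betaInt <- data.frame(drug = character(), stimulus = character(),
                          feature = character(), beta = numeric())
  clusters <- names(clusterProportions)
  if (is.null(hazardScale))
    hazardScale <- stats::setNames(rep(1, length(clusters)), clusters)
  zeroCse <- matrix(0, length(clusters), length(stimuli),
                    dimnames = list(clusters, stimuli))
  groundTruth(drugs = drugs, stimuli = stimuli, betaD = betaD, betaS = betaS,
              betaInt = betaInt, clusterProportions = clusterProportions,
              clusterStimEffect = zeroCse,
              ighvMRateByCluster = stats::setNames(rep(0.5, length(clusters)),
                                                   clusters),
              featurePrevalence = featurePrevalence,
              featureMissingRate = featureMissingRate,
              hazardScale = hazardScale, baseHazard = baseHazard,
              censoringMax = censoringMax, noiseSd = noiseSd,
              plateEffectSd = plateEffectSd, edgeEffect = edgeEffect,
              baseLuminescence = baseLuminescence,
              highConcFactor = highConcFactor,
              drugSensSd = 0, stimSensSd = 0)
}

# textbook Benjamini-Hochberg step-up adjustment
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# textbook pooled-variance two-sample t statistic and two-sided p
tOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2, p = 2 * pt(-abs(t), nx + ny - 2))
}

# brute-force normal-equations least squares
olsOracle <- function(X, y) solve(t(X) %*% X, t(X) %*% y)[, 1]

# Efron/Breslow log partial likelihood for a single binary covariate with
# untied event times (the two coincide without ties)
coxLogPL <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# adjusted Rand index between two labelings
ariOracle <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(v) sum(choose(v, 2))
  sumIj <- comb2(as.vector(tab))
  sumI <- comb2(rowSums(tab))
  sumJ <- comb2(colSums(tab))
  nPairs <- choose(sum(tab), 2)
  expected <- sumI * sumJ / nPairs
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expected) return(1)
  (sumIj - expected) / (maxIdx - expected)
}

# three equidistant Gaussian clouds for k-selection checks
threeCloudData <- function(nPerCluster = 20, sep = 8, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(sep / 2, sep * sqrt(3) / 2))
  x <- do.call(rbind, lapply(1:3, function(k) {
    cbind(rnorm(nPerCluster, centers[k, 1], sd),
          rnorm(nPerCluster, centers[k, 2], sd))
  }))
  rownames(x) <- sprintf("S%03d", seq_len(nrow(x)))
  list(x = x, labels = rep(1:3, each = nPerCluster))
}
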