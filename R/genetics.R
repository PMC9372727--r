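#' Encode genetic and annotation features for regression
#'
#' Builds the numeric predictor matrix used by all multivariate models:
#' IGHV status encoded M = 1 / U = 0; methylation class encoded LP = 0,
#' IP = 0.5, HP = 1; KRAS, BRAF and NRAS mutations collapsed into a single
#' RAS/RAF predictor (1 if any is mutated); features with 20% or more
#' missing values dropped; finally only complete-case samples retained.
#'
#' @param genetics samples x features 0/1/NA matrix (row names = sample
#'   ids).
#' @param annotation data.frame with sample_id, IGHV and (optionally)
#'   methylation.
#' @param maxMissing per-feature missingness threshold; features with a
#'   missing fraction >= this are dropped (default 0.2).
#' @param includeMethylation add the methylation predictor (default TRUE
#'   when the column is present).
#' @return numeric samples x predictors matrix (complete cases only), with
#'   attributes `droppedFeatures` (character) and `droppedSamples`
#'   (integer count), and a `provenance` attribute mapping encoded
#'   predictors to their raw sources.
#' @examples
#' g <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("a", "b"), c("TP53", "KRAS")))
#' ann <- data.frame(sample_id = c("a", "b"), IGHV = c("M", "U"),
#'                   methylation = c("HP", "LP"))
#' encodeFeatures(g, ann)
#' @export
encodeFeatures <- function(genetics, annotation, maxMissing = 0.2,
                           includeMethylation = TRUE) {
  genetics <- as.matrix(genetics)
  samples <- rownames(genetics)
  if (is.null(samples)) stopf("genetics must have sample ids as row names")
  idx <- match(samples, annotation$sample_id)
  if (any(is.na(idx)))
    stopf("annotation is missing %d sample(s) present in the genetic matrix",
          sum(is.na(idx)))
  ann <- annotation[idx, , drop = FALSE]

  provenance <- list()
  m <- genetics
  rasRaf <- intersect(c("KRAS", "BRAF", "NRAS"), colnames(m))
  if (length(rasRaf)) {
    sub <- m[, rasRaf, drop = FALSE]
    collapsed <- apply(sub, 1L, function(v) {
      if (all(is.na(v))) NA_integer_ else as.integer(any(v == 1L, na.rm = TRUE))
    })
    m <- m[, setdiff(colnames(m), rasRaf), drop = FALSE]
    m <- cbind(m, `RAS/RAF` = collapsed)
    provenance[["RAS/RAF"]] <- rasRaf
  }
  ighv <- ifelse(is.na(ann$IGHV), NA_real_, as.numeric(ann$IGHV == "M"))
  m <- cbind(m, IGHV = ighv)
  provenance[["IGHV"]] <- "IGHV status (M = 1, U = 0)"
  if (includeMethylation && "methylation" %in% names(ann)) {
    meth <- c(LP = 0, IP = 0.5, HP = 1)[ann$methylation]
    m <- cbind(m, Methylation = unname(meth))
    provenance[["Methylation"]] <- "methylation class (LP = 0, IP = 0.5, HP = 1)"
  }

  missFrac <- colMeans(is.na(m))
  dropped <- colnames(m)[missFrac >= maxMissing]
  m <- m[, missFrac < maxMissing, drop = FALSE]
  if (!ncol(m)) stopf("all features dropped by the %.0f%% missingness filter",
                      100 * maxMissing)
  cc <- complete.cases(m)
  nDroppedSamples <- sum(!cc)
  m <- m[cc, , drop = FALSE]
  if (!nrow(m)) stopf("no complete-case samples remain after encoding")
  screenLog("info", sprintf(
    "encoded %d predictors for %d complete-case samples (%d feature(s), %d sample(s) dropped)",
    ncol(m), nrow(m), length(dropped), nDroppedSamples))
  storage.mode(m) <- "double"
  attr(m, "droppedFeatures") <- dropped
  attr(m, "droppedSamples") <- nDroppedSamples
  attr(m, "provenance") <- provenance
  m
}

#' Univariate genetic determinants of stimulus responses
#'
#' For every (feature, stimulus) pair, compares the log relative viability
#' of carriers (feature = 1) against non-carriers with a two-sided,
#' equal-variance Student's t-test. Features with fewer than `minPositive`
#' carriers are excluded (associations with rare events are unreliable);
#' missing genotypes are excluded pairwise per test. P-values are adjusted
#' by Benjamini-Hochberg across all performed tests.
#'
#' @param responses samples x stimuli numeric matrix (e.g.
#'   [stimulusResponses()]).
#' @param features samples x features 0/1 matrix (NA allowed); row names
#'   must match `responses`.
#' @param minPositive minimum number of carriers (default 3).
#' @param fdr adjusted-p significance threshold (default 0.1).
#' @return data.frame: feature, stimulus, n_carrier, n_noncarrier, t, p,
#'   padj, significant. Tests with zero variance in both groups have NA p
#'   and are excluded from the adjustment.
#' @export
univariateResponseTests <- function(responses, features, minPositive = 3L,
                                    fdr = 0.1) {
  responses <- as.matrix(responses)
  features <- as.matrix(features)
  common <- intersect(rownames(responses), rownames(features))
  if (length(common) < 4L) stopf("too few samples shared between inputs")
  responses <- responses[common, , drop = FALSE]
  features <- features[common, , drop = FALSE]

  keep <- colSums(features == 1L, na.rm = TRUE) >= minPositive
  excluded <- colnames(features)[!keep]
  if (length(excluded))
    screenLog("info", sprintf("excluding %d feature(s) with < %d carriers: %s",
                              length(excluded), minPositive,
                              paste(excluded, collapse = ", ")))
  features <- features[, keep, drop = FALSE]
  if (!ncol(features)) stopf("no feature has >= %d carriers", minPositive)

  rows <- list()
  for (f in colnames(features)) {
    carrier <- features[, f] == 1L
    for (s in colnames(responses)) {
      y <- responses[, s]
      ok <- !is.na(carrier) & is.finite(y)
      g1 <- y[ok & carrier]; g0 <- y[ok & !carrier]
      t <- p <- NA_real_
      if (length(g1) >= 2L && length(g0) >= 2L &&
          (var(g1) > 0 || var(g0) > 0)) {
        tt <- t.test(g1, g0, var.equal = TRUE, alternative = "two.sided")
        t <- unname(tt$statistic); p <- tt$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, stimulus = s, n_carrier = length(g1),
        n_noncarrier = length(g0), t = t, p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$padj <- NA_real_
  done <- !is.na(out$p)
  out$padj[done] <- bhAdjust(out$p[done])
  out$significant <- !is.na(out$padj) & out$padj < fdr
  out
}

# One bootstrap round of an L1-penalized fit with internal 10-fold CV.
# The penalty is the largest lambda within one standard error of the CV
# minimum (lambda.1se): at the CV minimum the lasso systematically carries
# null predictors into a majority of bootstrap refits, which defeats the
# selection-frequency filter; the one-SE rule restores false-keep control
# without losing planted signals. Multinomial fits use the grouped penalty
# so a feature enters or leaves the model jointly across classes.
# Coefficients are returned on the standardized-predictor scale.
lassoBootFit <- function(x, y, family, nFolds) {
  xs <- scale(x)
  constCols <- !is.finite(attr(xs, "scaled:scale")) |
    attr(xs, "scaled:scale") == 0
  xs[, constCols] <- 0
  args <- list(xs, y, family = family, nfolds = nFolds, standardize = FALSE)
  if (family == "multinomial") args$type.multinomial <- "grouped"
  cv <- suppressWarnings(do.call(glmnet::cv.glmnet, args))
  coef(cv, s = "lambda.1se")
}

#' Gaussian stability-selection lasso
#'
#' Repeatedly resamples the samples with replacement, standardizes the
#' predictors within each bootstrap, fits an L1-penalized least-squares
#' model with the penalty chosen by internal 10-fold cross-validation
#' (one-standard-error rule), and records which predictors receive nonzero
#' coefficients. Predictors selected in strictly more than
#' `freqThreshold` of the bootstraps are kept; their reported coefficient
#' is the mean (on the standardized scale) over the bootstraps in which
#' they were selected.
#'
#' @param x samples x predictors numeric matrix (complete cases; see
#'   [encodeFeatures()]).
#' @param y numeric response vector.
#' @param nBoot number of bootstrap repeats (default 30).
#' @param freqThreshold keep predictors selected in > this fraction of
#'   bootstraps (default 0.75).
#' @param seed integer seed.
#' @param nFolds folds of the internal cross-validation (default 10).
#' @return a [StabilitySelection-class]; frequencies are exact multiples of
#'   `1/nBoot`.
#' @export
lassoStabilityGaussian <- function(x, y, nBoot = 30L, freqThreshold = 0.75,
                                   seed, nFolds = 10L) {
  seed <- assertSeed(seed)
  x <- as.matrix(x); y <- as.numeric(y)
  if (nBoot < 2L) stopf("nBoot must be >= 2")
  if (nrow(x) != length(y)) stopf("x and y disagree on the number of samples")
  if (anyNA(x) || anyNA(y)) stopf("complete cases required")
  preds <- colnames(x)
  settings <- list(family = "gaussian", nBoot = as.integer(nBoot),
                   freqThreshold = freqThreshold, coefThreshold = NA_real_,
                   seed = seed, nFolds = as.integer(nFolds))
  if (sd(y) == 0) {
    warnf("constant response: no predictor can be selected")
    tab <- data.frame(predictor = preds, frequency = 0, meanCoef = NA_real_,
                      sdCoef = NA_real_, kept = FALSE)
    return(new("StabilitySelection", table = tab, settings = settings))
  }
  set.seed(seed)
  n <- nrow(x)
  sel <- matrix(FALSE, nBoot, ncol(x), dimnames = list(NULL, preds))
  coefs <- matrix(NA_real_, nBoot, ncol(x), dimnames = list(NULL, preds))
  for (b in seq_len(nBoot)) {
    idx <- sample.int(n, n, replace = TRUE)
    cf <- lassoBootFit(x[idx, , drop = FALSE], y[idx], "gaussian", nFolds)
    v <- as.numeric(cf)[-1L]  # drop intercept
    sel[b, ] <- v != 0
    coefs[b, ] <- v
  }
  freq <- colMeans(sel)
  meanCoef <- vapply(preds, function(p) {
    hit <- sel[, p]
    if (!any(hit)) NA_real_ else mean(coefs[hit, p])
  }, numeric(1))
  sdCoef <- vapply(preds, function(p) {
    hit <- sel[, p]
    if (sum(hit) < 2L) NA_real_ else sd(coefs[hit, p])
  }, numeric(1))
  tab <- data.frame(predictor = preds, frequency = unname(freq),
                    meanCoef = unname(meanCoef), sdCoef = unname(sdCoef),
                    kept = unname(freq > freqThreshold),
                    stringsAsFactors = FALSE)
  new("StabilitySelection", table = tab, settings = settings)
}

#' Multinomial stability-selection lasso for cluster membership
#'
#' L1-penalized multinomial logistic regression of cluster labels on the
#' encoded genetic features, refit on bootstrap resamples (resamples
#' missing a cluster are redrawn, at most 100 attempts). Per cluster and
#' predictor the mean and standard deviation of the coefficient over the
#' bootstraps in which it was selected are reported; a predictor is kept
#' for a cluster when its selection frequency is at least `freqThreshold`
#' and the magnitude of its mean coefficient is at least `coefThreshold`.
#'
#' @param x samples x predictors numeric matrix (complete cases).
#' @param labels factor or character vector of cluster labels (>= 2
#'   clusters, each with >= 5 samples).
#' @param nBoot bootstrap repeats (default 50).
#' @param freqThreshold selection-frequency cutoff (default 0.60).
#' @param coefThreshold mean-coefficient magnitude cutoff (default 0.35, on
#'   the standardized-predictor scale of the fit).
#' @param seed integer seed.
#' @param nFolds internal CV folds (default 10).
#' @return a [StabilitySelection-class] whose table has one row per
#'   (class, predictor).
#' @export
lassoStabilityMultinomial <- function(x, labels, nBoot = 50L,
                                      freqThreshold = 0.60,
                                      coefThreshold = 0.35, seed,
                                      nFolds = 10L) {
  seed <- assertSeed(seed)
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stopf("need >= 2 clusters")
  if (any(table(labels) < 5L))
    stopf("every cluster needs >= 5 samples (got: %s)",
          paste(sprintf("%s=%d", levels(labels), table(labels)), collapse = ", "))
  if (anyNA(x)) stopf("complete cases required")
  preds <- colnames(x)
  classes <- levels(labels)
  set.seed(seed)
  n <- nrow(x)
  sel <- array(FALSE, c(nBoot, length(classes), length(preds)),
               dimnames = list(NULL, classes, preds))
  coefs <- array(NA_real_, dim(sel), dimnames = dimnames(sel))
  for (b in seq_len(nBoot)) {
    idx <- NULL
    for (attempt in seq_len(100L)) {
      cand <- sample.int(n, n, replace = TRUE)
      if (nlevels(droplevels(labels[cand])) == length(classes)) {
        idx <- cand
        break
      }
    }
    if (is.null(idx))
      stopf("could not draw a bootstrap resample containing every cluster in 100 attempts")
    cf <- lassoBootFit(x[idx, , drop = FALSE], labels[idx], "multinomial",
                       nFolds)
    for (cl in classes) {
      v <- as.numeric(cf[[cl]])[-1L]
      sel[b, cl, ] <- v != 0
      coefs[b, cl, ] <- v
    }
  }
  rows <- list()
  for (cl in classes) {
    for (p in preds) {
      hit <- sel[, cl, p]
      freq <- mean(hit)
      mc <- if (any(hit)) mean(coefs[hit, cl, p]) else NA_real_
      sc <- if (sum(hit) >= 2L) sd(coefs[hit, cl, p]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = p, class = cl, frequency = freq, meanCoef = mc,
        sdCoef = sc,
        kept = freq >= freqThreshold && !is.na(mc) && abs(mc) >= coefThreshold,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  new("StabilitySelection", table = tab,
      settings = list(family = "multinomial", nBoot = as.integer(nBoot),
                      freqThreshold = freqThreshold,
                      coefThreshold = coefThreshold, seed = seed,
                      nFolds = as.integer(nFolds)))
}

#' Genetic modulators of sample-specific interaction coefficients
#'
#' For every drug-stimulus pair, regresses the sample-specific interaction
#' coefficients (see [perSampleInteractions()]) on the encoded genetic
#' features with the gaussian stability-selection lasso, keeping predictors
#' selected in strictly more than `freqThreshold` (default 90%) of the
#' bootstraps. A pair "has genetic modulators" when its kept set is
#' non-empty. Pairs with fewer than `minSamples` complete-case samples are
#' skipped with a warning.
#'
#' @param betaIntTable long data.frame from [perSampleInteractions()]
#'   (columns sample_id, drug, stimulus, beta_int).
#' @param x samples x predictors matrix from [encodeFeatures()].
#' @param nBoot bootstrap repeats (default 30).
#' @param freqThreshold selection-frequency cutoff (default 0.90).
#' @param seed integer seed.
#' @param minSamples minimum complete-case samples per pair (default 10).
#' @param nFolds internal CV folds (default 10).
#' @return list with `summary` (data.frame: drug, stimulus, n, nModulators,
#'   modulators) and `selections` (named list of
#'   [StabilitySelection-class], one per analysed pair).
#' @export
interactionModulators <- function(betaIntTable, x, nBoot = 30L,
                                  freqThreshold = 0.90, seed,
                                  minSamples = 10L, nFolds = 10L) {
  seed <- assertSeed(seed)
  x <- as.matrix(x)
  pairs <- unique(betaIntTable[, c("drug", "stimulus")])
  selections <- list()
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    d <- pairs$drug[i]; s <- pairs$stimulus[i]
    sub <- betaIntTable[betaIntTable$drug == d & betaIntTable$stimulus == s, ]
    y <- setNames(sub$beta_int, sub$sample_id)
    common <- intersect(rownames(x), names(y)[is.finite(y)])
    if (length(common) < minSamples) {
      warnf("pair %s / %s skipped: only %d complete-case samples", d, s,
            length(common))
      rows[[i]] <- data.frame(drug = d, stimulus = s, n = length(common),
                              nModulators = NA_integer_,
                              modulators = NA_character_,
                              stringsAsFactors = FALSE)
      next
    }
    ss <- lassoStabilityGaussian(x[common, , drop = FALSE], y[common],
                                 nBoot = nBoot,
                                 freqThreshold = freqThreshold,
                                 seed = seed + i, nFolds = nFolds)
    kept <- keptPredictors(ss)
    selections[[paste(d, s, sep = ":")]] <- ss
    rows[[i]] <- data.frame(drug = d, stimulus = s, n = length(common),
                            nModulators = length(kept),
                            modulators = paste(kept, collapse = ","),
                            stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, rows), selections = selections)
}

#' Call trisomy 12 from ATAC per-peak read counts
#'
#' Computes the ratio of the mean reads per peak on chromosome 12 to the
#' mean reads per peak on all other chromosomes and calls trisomy 12 when
#' the ratio strictly exceeds the threshold (a third chromosome copy gives
#' an expected ratio of 1.5).
#'
#' @param peaks data.frame with columns `chrom` and `count` (a `peak_id`
#'   column is allowed and ignored).
#' @param threshold call threshold on the read-ratio (default 1.4, strict
#'   inequality).
#' @return list with `ratio`, `call` (logical), `nChr12`, `nOther`.
#' @examples
#' peaks <- data.frame(chrom = c("chr12", "chr12", "chr1", "chr2"),
#'                     count = c(15, 15, 10, 10))
#' callTrisomy12(peaks)  # ratio 1.5, call TRUE
#' @export
callTrisomy12 <- function(peaks, threshold = 1.4) {
  if (!all(c("chrom", "count") %in% names(peaks)))
    stopf("peaks needs columns 'chrom' and 'count'")
  chrom <- sub("^chr", "", tolower(as.character(peaks$chrom)))
  is12 <- chrom == "12"
  if (!any(is12)) stopf("no peaks on chromosome 12")
  if (all(is12)) stopf("no peaks outside chromosome 12")
  ratio <- mean(peaks$count[is12]) / mean(peaks$count[!is12])
  list(ratio = ratio, call = ratio > threshold,
       nChr12 = sum(is12), nOther = sum(!is12))
}
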