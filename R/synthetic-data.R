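isEdgeWell <- function(row, col) row == 1L | row == 16L | col == 1L | col == 24L

#' Default drug panel
#'
#' Twelve drugs covering BCR-pathway kinases, chemotherapy, MDM2, MEK, NFkB,
#' mTOR, JAK, p38, HSP90 and BET bromodomains, each at a higher and a lower
#' screening concentration (nM). The lower concentration induces sublethal
#' effects and is the default for interaction analysis; the higher kills a
#' large fraction of cells.
#'
#' @return named list of numeric concentration vectors (nM), highest first.
#' @export
defaultDrugs <- function() {
  list(
    Ibrutinib   = c(500, 50),
    Idelalisib  = c(500, 50),
    Fludarabine = c(2000, 200),
    `Nutlin-3a` = c(10000, 1000),
    Selumetinib = c(1000, 100),
    `BAY-11-7085` = c(2000, 200),
    Everolimus  = c(500, 50),
    PRT062607   = c(500, 50),
    `Pyridone-6` = c(500, 50),
    Ralimetinib = c(1500, 150),
    Luminespib  = c(200, 20),
    `I-BET-762` = c(1000, 100)
  )
}

#' Default stimulus panel
#'
#' Seventeen soluble microenvironmental stimuli mimicking lymph-node
#' signalling: interleukins, TLR7/8/9 agonists, CD40 ligand, anti-IgM,
#' TGF-beta, chemokine, interferon and stroma-conditioned medium.
#'
#' @return character vector of 17 stimulus names.
#' @export
defaultStimuli <- function() {
  c("IL4", "IL10", "IL2", "Resiquimod", "IL21", "BAFF", "IL1b", "sCD40L",
    "anti-IgM", "TGFb1", "IL15", "IL6", "CpG-ODN", "CXCL12", "IFNg",
    "HS5-CM", "sCD40L+IL4")
}

# Deterministic two-plate 384-well layout: interior wells host the treated
# conditions plus evenly spread interior DMSO controls; a few outer-edge
# wells carry DMSO controls that normalization must ignore.
buildPlateLayout <- function(drugs, stimuli, nInteriorDmso = 16L, nEdgeDmso = 4L) {
  grid <- expand.grid(well_row = 1:16, well_col = 1:24)
  interior <- grid[!isEdgeWell(grid$well_row, grid$well_col), ]
  edge <- grid[isEdgeWell(grid$well_row, grid$well_col), ]

  drugTab <- data.frame(
    drug = rep(names(drugs), lengths(drugs)),
    drug_conc_nM = unlist(drugs, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  conds <- rbind(
    data.frame(drug = drugTab$drug, drug_conc_nM = drugTab$drug_conc_nM,
               stimulus = "none"),
    data.frame(drug = "none", drug_conc_nM = NA_real_, stimulus = stimuli),
    merge(drugTab, data.frame(stimulus = stimuli))[, c("drug", "drug_conc_nM", "stimulus")]
  )

  perPlate <- nrow(interior) - nInteriorDmso
  if (nrow(conds) > 2L * perPlate)
    stopf("design needs %d treated wells but two plates hold only %d",
          nrow(conds), 2L * perPlate)

  makePlate <- function(plate, condSlice) {
    # spread DMSO controls evenly through the interior positions
    nInt <- nrow(interior)
    dmsoIdx <- unique(round(seq(1L, nInt, length.out = nInteriorDmso)))
    treatIdx <- setdiff(seq_len(nInt), dmsoIdx)[seq_len(nrow(condSlice))]
    edgeIdx <- unique(round(seq(2L, nrow(edge) - 1L, length.out = nEdgeDmso)))
    parts <- list(
      data.frame(plate = plate,
                 interior[dmsoIdx, , drop = FALSE],
                 drug = "DMSO", drug_conc_nM = NA_real_, stimulus = "none"),
      data.frame(plate = plate,
                 edge[edgeIdx, , drop = FALSE],
                 drug = "DMSO", drug_conc_nM = NA_real_, stimulus = "none")
    )
    if (nrow(condSlice) > 0L)
      parts <- c(parts, list(
        data.frame(plate = plate,
                   interior[treatIdx, , drop = FALSE],
                   condSlice)))
    do.call(rbind, parts)
  }
  nFirst <- min(perPlate, nrow(conds))
  lay <- rbind(
    makePlate(1L, conds[seq_len(nFirst), , drop = FALSE]),
    makePlate(2L, conds[setdiff(seq_len(nrow(conds)), seq_len(nFirst)), , drop = FALSE])
  )
  rownames(lay) <- NULL
  lay
}

#' Construct a screen design
#'
#' @param drugs named list of numeric concentration vectors (nM), one per
#'   drug (1-2 concentrations each). Defaults to [defaultDrugs()].
#' @param stimuli character vector of stimulus names; defaults to the 17
#'   stimuli of [defaultStimuli()].
#' @param nSamples cohort size.
#' @param nInteriorDmso,nEdgeDmso number of interior / outer-edge DMSO
#'   control wells per plate.
#' @return a [ScreenDesign-class] object whose layout spreads drug-only,
#'   stimulus-only and all drug-stimulus combination wells (every drug
#'   concentration crossed with every stimulus) over two 384-well plates.
#' @examples
#' design <- screenDesign(nSamples = 8)
#' design
#' @export
screenDesign <- function(drugs = defaultDrugs(), stimuli = defaultStimuli(),
                         nSamples = 192L, nInteriorDmso = 16L, nEdgeDmso = 4L) {
  if (nInteriorDmso < 8L) stopf("at least 8 interior DMSO wells per plate are required")
  if (nEdgeDmso < 1L) stopf("at least 1 edge DMSO well per plate is required")
  new("ScreenDesign", drugs = drugs, stimuli = as.character(stimuli),
      nSamples = as.integer(nSamples),
      layout = buildPlateLayout(drugs, stimuli, as.integer(nInteriorDmso),
                                as.integer(nEdgeDmso)))
}

defaultClusterStimEffect <- function(stimuli, clusters = paste0("C", 1:4)) {
  eff <- matrix(0, length(clusters), length(stimuli),
                dimnames = list(clusters, stimuli))
  tlr <- intersect(c("Resiquimod", "CpG-ODN"), stimuli)
  nfkb <- intersect(c("IL1b", "anti-IgM", "sCD40L", "BAFF"), stimuli)
  il4 <- intersect(c("IL4", "sCD40L+IL4"), stimuli)
  # C1/C2 respond strongly to IL4 and TLR agonists; C2 to NFkB agonists on
  # top; C3 responds weakly overall; C4 loses viability under TLR stimulation
  eff["C1", il4] <- eff["C1", il4] + 0.25
  eff["C1", tlr] <- eff["C1", tlr] + 0.25
  eff["C2", il4] <- eff["C2", il4] + 0.35
  eff["C2", tlr] <- eff["C2", tlr] + 0.35
  eff["C2", nfkb] <- eff["C2", nfkb] + 0.30
  eff["C3", ] <- eff["C3", ] - 0.10
  eff["C4", tlr] <- eff["C4", tlr] - 0.45
  eff
}

#' Construct the generative ground truth of a synthetic screen
#'
#' All defaults emulate the statistical structure of a real ex vivo
#' drug-stimulus screen in CLL: mostly pro-survival stimuli (strongest for
#' IL4 and TLR agonists, negative for IL6/TGFb1), toxic drugs, four latent
#' stimulus-response clusters with IGHV-linked composition and
#' cluster-specific hazards, recurrent genetic lesions at realistic
#' prevalences, and a handful of planted drug-stimulus interactions of all
#' four categories.
#'
#' @param drugs,stimuli panels as in [screenDesign()]; effects default to
#'   plausible values for any unrecognised name.
#' @param betaD,betaS named numeric vectors of log-scale effects; defaults
#'   are filled per panel.
#' @param betaInt data.frame(drug, stimulus, feature, beta) of planted
#'   interactions (`feature = "all"` for unconditional effects).
#' @param clusterProportions,clusterStimEffect,ighvMRateByCluster latent
#'   cluster structure; see [GroundTruth-class].
#' @param featurePrevalence named prevalences of binary genetic features.
#' @param featureMissingRate MCAR missingness rate of the genetic matrix.
#' @param hazardScale,baseHazard,censoringMax survival parameters.
#' @param noiseSd,plateEffectSd,edgeEffect,baseLuminescence,highConcFactor,drugSensSd,stimSensSd
#'   assay parameters; see [GroundTruth-class].
#' @return a validated [GroundTruth-class] object.
#' @examples
#' truth <- groundTruth()
#' truth
#' @export
groundTruth <- function(drugs = names(defaultDrugs()),
                        stimuli = defaultStimuli(),
                        betaD = NULL, betaS = NULL, betaInt = NULL,
                        clusterProportions = c(C1 = 0.35, C2 = 0.12,
                                               C3 = 0.23, C4 = 0.30),
                        clusterStimEffect = NULL,
                        ighvMRateByCluster = c(C1 = 0.20, C2 = 0.30,
                                               C3 = 0.80, C4 = 0.85),
                        featurePrevalence = c(trisomy12 = 0.20, TP53 = 0.12,
                                              del11q = 0.15, del13q = 0.55,
                                              SF3B1 = 0.10, ATM = 0.10,
                                              POT1 = 0.08, NOTCH1 = 0.10,
                                              KRAS = 0.05, BRAF = 0.03,
                                              NRAS = 0.02, gain8q = 0.05),
                        featureMissingRate = 0.05,
                        hazardScale = c(C1 = 1.5, C2 = 2.0, C3 = 1.8, C4 = 0.6),
                        baseHazard = 1 / 1500, censoringMax = 3000,
                        noiseSd = 0.10, plateEffectSd = 0.15,
                        edgeEffect = -0.30, baseLuminescence = 1e6,
                        highConcFactor = 2, drugSensSd = 0.3, stimSensSd = 0.3) {
  fillBeta <- function(given, nms, default) {
    out <- setNames(rep(default, length(nms)), nms)
    if (!is.null(given)) {
      bad <- setdiff(names(given), nms)
      if (length(bad)) stopf("unknown names in beta vector: %s", paste(bad, collapse = ", "))
      out[names(given)] <- given
    }
    out
  }
  dDefault <- setNames(rep(-0.30, length(drugs)), drugs)
  toxic <- intersect(c("Fludarabine", "Nutlin-3a", "Luminespib"), drugs)
  dDefault[toxic] <- -0.55
  mild <- intersect(c("Everolimus", "Ralimetinib", "Selumetinib"), drugs)
  dDefault[mild] <- -0.15
  if (is.null(betaD)) betaD <- dDefault else betaD <- fillBeta(betaD, drugs, -0.30)

  sDefault <- setNames(rep(0.10, length(stimuli)), stimuli)
  strong <- intersect(c("IL4", "Resiquimod", "CpG-ODN", "sCD40L+IL4"), stimuli)
  sDefault[strong] <- 0.35
  neg <- intersect(c("IL6", "TGFb1"), stimuli)
  sDefault[neg] <- -0.10
  if (is.null(betaS)) betaS <- sDefault else betaS <- fillBeta(betaS, stimuli, 0.10)

  if (is.null(betaInt)) {
    betaInt <- data.frame(
      drug = c("Ibrutinib", "Ibrutinib", "Pyridone-6", "Ralimetinib",
               "Ibrutinib", "Luminespib", "Fludarabine", "Fludarabine"),
      stimulus = c("IL4", "IFNg", "sCD40L+IL4", "IFNg",
                   "CpG-ODN", "anti-IgM", "CpG-ODN", "IL4"),
      feature = c("all", "all", "all", "all", "all", "all", "trisomy12", "all"),
      # IL4/IFNg cancel ibrutinib toxicity (antagonistic, category I);
      # pyridone-6 blocks the sCD40L+IL4 survival signal (II); IFNg +
      # ralimetinib is the lone pro-survival synergy (III); CpG-ODN and
      # anti-IgM sensitize to ibrutinib/luminespib (IV)
      beta = c(0.28, 0.25, -0.35, 0.40, -0.40, -0.35, 0.50, 0.40),
      stringsAsFactors = FALSE
    )
    betaInt <- betaInt[betaInt$drug %in% drugs & betaInt$stimulus %in% stimuli, ]
  }
  if (is.null(clusterStimEffect))
    clusterStimEffect <- defaultClusterStimEffect(stimuli,
                                                  names(clusterProportions))
  methylationByIghv <- matrix(c(0.10, 0.25, 0.65,   # IGHV-M: mostly HP
                                0.70, 0.25, 0.05),  # IGHV-U: mostly LP
                              nrow = 2, byrow = TRUE,
                              dimnames = list(c("M", "U"), c("LP", "IP", "HP")))
  new("GroundTruth", betaD = betaD, betaS = betaS, betaInt = betaInt,
      clusterProportions = clusterProportions,
      clusterStimEffect = clusterStimEffect,
      ighvMRateByCluster = ighvMRateByCluster,
      methylationByIghv = methylationByIghv,
      featurePrevalence = featurePrevalence,
      featureMissingRate = featureMissingRate,
      hazardScale = hazardScale, baseHazard = baseHazard,
      censoringMax = censoringMax, noiseSd = noiseSd,
      plateEffectSd = plateEffectSd, edgeEffect = edgeEffect,
      baseLuminescence = baseLuminescence, highConcFactor = highConcFactor,
      drugSensSd = drugSensSd, stimSensSd = stimSensSd)
}

# largest-remainder allocation of n samples to planted cluster proportions,
# forcing every cluster to be non-empty
stratifiedClusterCounts <- function(proportions, n) {
  k <- length(proportions)
  base <- floor(proportions * n)
  base[base == 0L] <- 1L
  while (sum(base) > n) {
    i <- which.max(base)
    base[i] <- base[i] - 1L
  }
  rem <- n - sum(base)
  if (rem > 0L) {
    frac <- proportions * n - floor(proportions * n)
    ord <- order(frac, decreasing = TRUE)
    for (i in seq_len(rem)) {
      j <- ord[(i - 1L) %% k + 1L]
      base[j] <- base[j] + 1L
    }
  }
  as.integer(base)
}

#' Generate a synthetic cohort: annotation and genetic matrix
#'
#' Assigns every sample a latent stimulus-response cluster (stratified
#' largest-remainder allocation so tiny cohorts still contain every
#' cluster), IGHV status with cluster-linked mutation rates, a methylation
#' class conditional on IGHV, sex, pre-treatment status, and a binary
#' genetic feature matrix with missing-completely-at-random gaps.
#'
#' @param design a [ScreenDesign-class].
#' @param truth a [GroundTruth-class].
#' @param seed integer seed; identical inputs give byte-identical output.
#' @return list with elements `annotation` (data.frame: sample_id, cluster,
#'   IGHV, methylation, sex, pretreated) and `genetics` (samples x features
#'   0/1/NA matrix).
#' @examples
#' cohort <- generateCohort(screenDesign(nSamples = 12), groundTruth(), seed = 1)
#' table(cohort$annotation$cluster)
#' @export
generateCohort <- function(design, truth, seed) {
  seed <- assertSeed(seed)
  n <- design@nSamples
  clusters <- names(truth@clusterProportions)
  if (n < length(clusters))
    stopf("n_samples (%d) must be >= the number of clusters (%d)",
          n, length(clusters))
  set.seed(seed)
  counts <- stratifiedClusterCounts(truth@clusterProportions, n)
  cluster <- sample(rep(clusters, counts))
  sampleId <- sprintf("S%03d", seq_len(n))

  ighv <- ifelse(rbinom(n, 1L, truth@ighvMRateByCluster[cluster]) == 1L, "M", "U")
  meth <- vapply(ighv, function(st) {
    sample(colnames(truth@methylationByIghv), 1L,
           prob = truth@methylationByIghv[st, ])
  }, character(1))
  sex <- sample(c("m", "f"), n, replace = TRUE, prob = c(0.6, 0.4))
  pretreated <- rbinom(n, 1L, 0.3)

  feats <- names(truth@featurePrevalence)
  genetics <- vapply(feats, function(f) rbinom(n, 1L, truth@featurePrevalence[[f]]),
                     integer(n))
  genetics <- matrix(genetics, nrow = n,
                     dimnames = list(sampleId, feats))
  if (truth@featureMissingRate > 0) {
    miss <- matrix(rbinom(length(genetics), 1L, truth@featureMissingRate) == 1L,
                   nrow = n)
    genetics[miss] <- NA_integer_
  }
  annotation <- data.frame(
    sample_id = sampleId, cluster = cluster, IGHV = ighv,
    methylation = unname(meth), sex = sex, pretreated = pretreated,
    stringsAsFactors = FALSE
  )
  list(annotation = annotation, genetics = genetics)
}

#' Generate raw plate luminescence for a cohort
#'
#' Every well's luminescence follows the log-normal generative model
#' `base * exp(plateEffect + bd*Xd + bs*Xs + bint*Xd*Xs + eps)` with
#' `eps ~ Normal(0, noiseSd^2)`. Plate effects are per-plate Normal
#' intercepts shared by all wells of a plate, so they cancel exactly under
#' within-plate DMSO normalization. Stimulus effects combine the global
#' effect, the sample's latent-cluster modulation and per-sample
#' heterogeneity; drug effects scale with concentration; outer-edge wells
#' receive the edge bias. DMSO wells have `Xd = Xs = 0`.
#'
#' @param design a [ScreenDesign-class].
#' @param cohort output of [generateCohort()].
#' @param truth a [GroundTruth-class].
#' @param seed integer seed.
#' @return data.frame of well records: sample_id, plate_id, well_row,
#'   well_col, drug, drug_conc_nM, stimulus, luminescence.
#' @examples
#' design <- screenDesign(nSamples = 4)
#' truth <- groundTruth()
#' wells <- generatePlates(design, generateCohort(design, truth, 1), truth, 1)
#' head(wells)
#' @export
generatePlates <- function(design, cohort, truth, seed) {
  seed <- assertSeed(seed)
  annotation <- cohort$annotation
  n <- nrow(annotation)
  lay <- design@layout
  edge <- isEdgeWell(lay$well_row, lay$well_col)
  if (sum(lay$drug == "DMSO" & !edge) == 0L)
    stopf("layout has no interior DMSO wells; normalization would be impossible")

  set.seed(seed)
  # per-sample multiplicative heterogeneity of drug / stimulus sensitivity
  gammaD <- 1 + rnorm(n, 0, truth@drugSensSd)
  gammaS <- 1 + rnorm(n, 0, truth@stimSensSd)
  plateEff <- matrix(rnorm(2L * n, 0, truth@plateEffectSd), nrow = n)

  lowConc <- vapply(design@drugs, min, numeric(1))
  nw <- nrow(lay)
  drugIdx <- match(lay$drug, names(truth@betaD))       # NA for DMSO/none
  stimIdx <- match(lay$stimulus, names(truth@betaS))   # NA for none
  hasDrug <- !is.na(drugIdx)
  # the higher concentration amplifies the drug effect
  concScale <- rep(1, nw)
  concScale[hasDrug] <- ifelse(
    lay$drug_conc_nM[hasDrug] > lowConc[lay$drug[hasDrug]],
    truth@highConcFactor, 1)

  # precompute each sample's (drug x stimulus) interaction effects once
  drugsAll <- names(truth@betaD); stimAll <- names(truth@betaS)
  intBySample <- array(0, dim = c(n, length(drugsAll), length(stimAll)),
                       dimnames = list(annotation$sample_id, drugsAll, stimAll))
  if (nrow(truth@betaInt)) {
    for (r in seq_len(nrow(truth@betaInt))) {
      b <- truth@betaInt[r, ]
      carrier <- if (b$feature == "all") rep(TRUE, n)
      else if (b$feature == "IGHV") annotation$IGHV == "M"
      else if (!b$feature %in% colnames(cohort$genetics))
        stopf("betaInt references unknown feature '%s'", b$feature)
      else !is.na(cohort$genetics[, b$feature]) & cohort$genetics[, b$feature] == 1L
      intBySample[, b$drug, b$stimulus] <-
        intBySample[, b$drug, b$stimulus] + b$beta * as.numeric(carrier)
    }
  }

  comboRows <- which(hasDrug & !is.na(stimIdx))
  comboDrug <- match(lay$drug[comboRows], drugsAll)
  comboStim <- match(lay$stimulus[comboRows], stimAll)
  edgeTerm <- ifelse(edge, truth@edgeEffect, 0)

  perWell <- function(i) {
    mu <- log(truth@baseLuminescence) + plateEff[i, lay$plate]
    bd <- numeric(nw)
    bd[hasDrug] <- truth@betaD[drugIdx[hasDrug]] * concScale[hasDrug] * gammaD[i]
    clEff <- truth@clusterStimEffect[annotation$cluster[i], ]
    bs <- numeric(nw)
    hasStim <- !is.na(stimIdx)
    bs[hasStim] <- (truth@betaS[stimIdx[hasStim]] +
                      clEff[stimIdx[hasStim]]) * gammaS[i]
    bint <- numeric(nw)
    if (length(comboRows))
      bint[comboRows] <- intBySample[cbind(i, comboDrug, comboStim)]
    mu <- mu + bd + bs + bint + edgeTerm
    exp(mu + rnorm(nw, 0, truth@noiseSd))
  }

  out <- vector("list", n)
  for (i in seq_len(n)) {
    lum <- perWell(i)
    out[[i]] <- data.frame(
      sample_id = annotation$sample_id[i],
      plate_id = sprintf("%s_P%d", annotation$sample_id[i], lay$plate),
      well_row = lay$well_row, well_col = lay$well_col,
      drug = lay$drug, drug_conc_nM = lay$drug_conc_nM,
      stimulus = lay$stimulus, luminescence = lum,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Generate right-censored time-to-event records for a cohort
#'
#' Event times are exponential with a cluster-specific rate
#' (`baseHazard * hazardScale[cluster]`); censoring times are independent
#' Uniform(0, `censoringMax`). `censoringMax = 0` disables censoring, so all
#' events are observed.
#'
#' @param cohort output of [generateCohort()].
#' @param truth a [GroundTruth-class].
#' @param seed integer seed.
#' @return data.frame: sample_id, time (days, > 0), event (0/1), cluster.
#' @examples
#' design <- screenDesign(nSamples = 8)
#' truth <- groundTruth()
#' surv <- generateSurvival(generateCohort(design, truth, 1), truth, 1)
#' @export
generateSurvival <- function(cohort, truth, seed) {
  seed <- assertSeed(seed)
  ann <- cohort$annotation
  missing <- setdiff(unique(ann$cluster), names(truth@hazardScale))
  if (length(missing))
    stopf("hazardScale is undefined for cluster(s): %s",
          paste(missing, collapse = ", "))
  if (any(truth@hazardScale <= 0))
    stopf("hazard multipliers must be > 0")
  set.seed(seed)
  n <- nrow(ann)
  rate <- truth@baseHazard * truth@hazardScale[ann$cluster]
  tEvent <- rexp(n, rate)
  if (truth@censoringMax > 0) {
    tCens <- runif(n, 0, truth@censoringMax)
  } else {
    tCens <- rep(Inf, n)
  }
  time <- pmin(tEvent, tCens)
  time <- pmax(time, .Machine$double.eps)
  data.frame(sample_id = ann$sample_id,
             time = time,
             event = as.integer(tEvent <= tCens),
             cluster = ann$cluster,
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic screen
#'
#' Convenience wrapper running [generateCohort()], [generatePlates()] and
#' [generateSurvival()] with sub-seeds derived deterministically from
#' `seed`.
#'
#' @param design a [ScreenDesign-class].
#' @param truth a [GroundTruth-class].
#' @param seed integer seed.
#' @return list with `wells`, `annotation`, `genetics`, `survival`, and the
#'   `design`/`truth` used.
#' @examples
#' sim <- simulateScreen(screenDesign(nSamples = 4), groundTruth(), seed = 1)
#' names(sim)
#' @export
simulateScreen <- function(design, truth = groundTruth(), seed) {
  seed <- assertSeed(seed)
  cohort <- generateCohort(design, truth, seed)
  wells <- generatePlates(design, cohort, truth, seed + 1L)
  surv <- generateSurvival(cohort, truth, seed + 2L)
  list(wells = wells, annotation = cohort$annotation,
       genetics = cohort$genetics, survival = surv,
       design = design, truth = truth)
}

#' Simulate per-peak ATAC read counts with a trisomy-12 dosage effect
#'
#' Generates a per-peak count table for one sample: negative-binomial-like
#' (Poisson-lognormal) counts with chromosome labels, where trisomy-12
#' samples carry a 1.5-fold mean increase on chromosome 12 (the extra copy).
#'
#' @param trisomy12 logical; does the sample carry trisomy 12?
#' @param nPeaks total number of peaks (distributed over chromosomes 1-22).
#' @param meanCount expected reads per peak on disomic chromosomes.
#' @param dosageFactor chr12 mean multiplier for trisomic samples (3/2 copy
#'   ratio by default).
#' @param seed integer seed.
#' @return data.frame: peak_id, chrom, count.
#' @examples
#' counts <- simulatePeakCounts(trisomy12 = TRUE, seed = 1)
#' callTrisomy12(counts)
#' @export
simulatePeakCounts <- function(trisomy12, nPeaks = 2000L, meanCount = 50,
                               dosageFactor = 1.5, seed) {
  seed <- assertSeed(seed)
  set.seed(seed)
  chrom <- sample(paste0("chr", 1:22), nPeaks, replace = TRUE)
  mu <- rep(meanCount, nPeaks)
  if (isTRUE(trisomy12)) mu[chrom == "chr12"] <- mu[chrom == "chr12"] * dosageFactor
  count <- stats::rpois(nPeaks, mu * exp(rnorm(nPeaks, 0, 0.2)))
  data.frame(peak_id = sprintf("peak_%05d", seq_len(nPeaks)),
             chrom = chrom, count = count, stringsAsFactors = FALSE)
}
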