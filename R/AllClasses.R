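#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ScreenDesign: layout of a combinatorial drug-stimulus viability screen
#'
#' Describes the experimental design of a 384-well ex vivo screen: the drug
#' panel (each drug at one or two concentrations), the stimulus panel, the
#' cohort size, and the assignment of conditions and DMSO controls to wells
#' across the two culture plates used per sample.
#'
#' The plate layout places interior DMSO control wells (used for
#' normalization) as well as DMSO wells on the outer plate edge (row 1,
#' row 16, column 1, column 24), which are deliberately excluded from the
#' normalization median and exist to exercise that exclusion.
#'
#' @slot drugs named list; one numeric vector of concentrations (nM) per drug.
#' @slot stimuli character vector of stimulus names.
#' @slot nSamples integer, number of samples in the cohort.
#' @slot layout data.frame with one row per plated well of the two-plate set
#'   used for every sample: columns `plate` (1 or 2), `well_row` (1-16),
#'   `well_col` (1-24), `drug` ("DMSO" for controls), `drug_conc_nM`
#'   (NA for controls), `stimulus` ("none" where absent).
#'
#' @seealso [screenDesign()]
#' @export
setClass("ScreenDesign",
  representation(
    drugs = "list",
    stimuli = "character",
    nSamples = "integer",
    layout = "data.frame"
  )
)

setValidity("ScreenDesign", function(object) {
  msg <- character()
  lay <- object@layout
  need <- c("plate", "well_row", "well_col", "drug", "drug_conc_nM", "stimulus")
  if (!all(need %in% names(lay)))
    return(sprintf("layout must have columns: %s", paste(need, collapse = ", ")))
  if (length(object@drugs) < 1L || is.null(names(object@drugs)))
    msg <- c(msg, "drugs must be a non-empty named list of concentration vectors")
  if (any(vapply(object@drugs, function(d) length(d) < 1L || length(d) > 2L, logical(1))))
    msg <- c(msg, "each drug must have 1 or 2 concentrations")
  if (length(object@stimuli) < 1L)
    msg <- c(msg, "at least one stimulus is required")
  if (any(lay$well_row < 1L | lay$well_row > 16L | lay$well_col < 1L | lay$well_col > 24L))
    msg <- c(msg, "well coordinates must lie in the 16 x 24 grid")
  edge <- isEdgeWell(lay$well_row, lay$well_col)
  for (p in unique(lay$plate)) {
    onP <- lay$plate == p
    dmso <- onP & lay$drug == "DMSO"
    if (sum(dmso & !edge) < 8L)
      msg <- c(msg, sprintf("plate %d needs >= 8 interior DMSO wells", p))
    if (sum(dmso & edge) < 1L)
      msg <- c(msg, sprintf("plate %d needs >= 1 edge DMSO well", p))
  }
  if (length(unique(lay$plate)) != 2L)
    msg <- c(msg, "each sample must occupy exactly 2 plates")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: generative parameters of the synthetic screen
#'
#' Holds every parameter of the synthetic data generator: log-scale treatment
#' effects, planted drug-stimulus interactions (optionally conditional on a
#' genetic subgroup), latent response-cluster structure, genetic feature
#' prevalences, survival hazards, and noise magnitudes. Wells are generated as
#' `luminescence = base * exp(plateEffect + bd*Xd + bs*Xs + bint*Xd*Xs + eps)`
#' with `eps ~ Normal(0, noiseSd^2)`, so all effects live on the natural-log
#' viability scale.
#'
#' @slot betaD named numeric; per-drug log viability effect at the analysis
#'   (lowest) concentration. The higher concentration scales this by
#'   `highConcFactor`.
#' @slot betaS named numeric; per-stimulus log viability effect.
#' @slot betaInt data.frame(drug, stimulus, feature, beta); planted
#'   interaction effects. `feature = "all"` applies to every sample, otherwise
#'   the effect applies only to carriers of the named genetic feature (or to
#'   IGHV-mutated samples for `feature = "IGHV"`). Unlisted combinations
#'   default to zero interaction.
#' @slot clusterProportions named numeric summing to 1; planted proportions
#'   of the latent stimulus-response clusters.
#' @slot clusterStimEffect numeric matrix (clusters x stimuli) added to
#'   `betaS` for samples of each cluster; this is what makes the clusters
#'   separable in stimulus-response space.
#' @slot ighvMRateByCluster named numeric; P(IGHV mutated | cluster).
#' @slot methylationByIghv 2 x 3 probability matrix (rows "M","U"; columns
#'   "LP","IP","HP") for the methylation class given IGHV status.
#' @slot featurePrevalence named numeric in (0,1); Bernoulli prevalence of
#'   each binary genetic feature (e.g. trisomy12, TP53).
#' @slot featureMissingRate numeric; per-feature missing-completely-at-random
#'   rate applied to the genetic matrix.
#' @slot hazardScale named numeric > 0; per-cluster multiplier on the
#'   baseline event hazard.
#' @slot baseHazard numeric > 0; baseline exponential event rate (per day).
#' @slot censoringMax numeric >= 0; upper bound of the independent uniform
#'   censoring time in days (0 disables censoring).
#' @slot noiseSd numeric > 0; well-level log-scale noise.
#' @slot plateEffectSd numeric >= 0; sd of the per-plate log intercept,
#'   shared by all wells of a plate (cancels under within-plate
#'   normalization).
#' @slot edgeEffect numeric; log-scale bias applied to outer-edge wells
#'   (mimicking evaporation), present so that including edge controls in the
#'   normalization median is detectably wrong.
#' @slot baseLuminescence numeric > 0; expected DMSO luminescence.
#' @slot highConcFactor numeric; multiplier on `betaD` for the higher drug
#'   concentration.
#' @slot drugSensSd,stimSensSd numeric >= 0; sd of per-sample multiplicative
#'   heterogeneity of drug and stimulus effects (drives the correlation
#'   structure across samples).
#'
#' @seealso [groundTruth()]
#' @export
setClass("GroundTruth",
  representation(
    betaD = "numeric",
    betaS = "numeric",
    betaInt = "data.frame",
    clusterProportions = "numeric",
    clusterStimEffect = "matrix",
    ighvMRateByCluster = "numeric",
    methylationByIghv = "matrix",
    featurePrevalence = "numeric",
    featureMissingRate = "numeric",
    hazardScale = "numeric",
    baseHazard = "numeric",
    censoringMax = "numeric",
    noiseSd = "numeric",
    plateEffectSd = "numeric",
    edgeEffect = "numeric",
    baseLuminescence = "numeric",
    highConcFactor = "numeric",
    drugSensSd = "numeric",
    stimSensSd = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (abs(sum(object@clusterProportions) - 1) > 1e-8)
    msg <- c(msg, "clusterProportions must sum to 1")
  if (is.null(names(object@clusterProportions)))
    msg <- c(msg, "clusterProportions must be named")
  if (!identical(sort(names(object@hazardScale)),
                 sort(names(object@clusterProportions))))
    msg <- c(msg, "hazardScale must name every cluster")
  if (any(object@hazardScale <= 0))
    msg <- c(msg, "hazard multipliers must be > 0")
  if (object@noiseSd <= 0)
    msg <- c(msg, "noiseSd must be > 0")
  if (object@plateEffectSd < 0 || object@drugSensSd < 0 || object@stimSensSd < 0)
    msg <- c(msg, "standard deviations must be >= 0")
  if (object@baseLuminescence <= 0)
    msg <- c(msg, "baseLuminescence must be > 0")
  if (nrow(object@betaInt) &&
      !all(c("drug", "stimulus", "feature", "beta") %in% names(object@betaInt)))
    msg <- c(msg, "betaInt needs columns drug, stimulus, feature, beta")
  if (any(object@featurePrevalence <= 0 | object@featurePrevalence >= 1))
    msg <- c(msg, "featurePrevalence values must lie in (0,1)")
  if (object@featureMissingRate < 0 || object@featureMissingRate >= 1)
    msg <- c(msg, "featureMissingRate must lie in [0,1)")
  if (length(msg)) msg else TRUE
})

#' ScreenExperiment: normalized log relative viability
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay `"logV"`
#' holding the natural-log relative viability (treated luminescence over the
#' within-plate median of interior DMSO controls), conditions in rows and
#' samples in columns. `rowData` carries `condition`, `drug`,
#' `drug_conc_nM`, `stimulus` and `type` (one of `"drug"`, `"stimulus"`,
#' `"combination"`); `colData` carries the sample annotation when supplied.
#'
#' Negative values indicate drug- or stimulus-induced toxicity relative to
#' the DMSO control, positive values a pro-survival effect.
#'
#' @seealso [normalizeWells()], [stimulusResponses()], [drugResponses()]
#' @export
setClass("ScreenExperiment", contains = "SummarizedExperiment")

setValidity("ScreenExperiment", function(object) {
  msg <- character()
  if (!"logV" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'logV' is required")
  need <- c("condition", "drug", "drug_conc_nM", "stimulus", "type")
  if (!all(need %in% names(SummarizedExperiment::rowData(object))))
    msg <- c(msg, sprintf("rowData must have columns: %s",
                          paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' ConsensusResult: subsampled consensus clustering of response profiles
#'
#' Result of repeated hierarchical clustering (Euclidean distance, average
#' linkage) on random sample subsets. For each candidate number of clusters
#' k the consensus matrix entry (i, j) is the fraction of subsamples
#' containing both samples in which they co-clustered; final labels come from
#' hierarchical clustering of `1 - consensus` at the chosen k.
#'
#' @slot consensus named list (by k) of samples x samples consensus matrices.
#' @slot labels named list (by k) of integer cluster labels per sample.
#' @slot auc named numeric; area under the consensus CDF per k.
#' @slot deltaAuc named numeric; relative change of `auc` along k (for the
#'   smallest k this is the area itself).
#' @slot chosenK integer; k maximizing `deltaAuc`.
#' @slot weakStructure logical; TRUE when no relative change beyond the
#'   smallest k exceeds 0.1, i.e. the selection curve is flat.
#' @slot settings list of the call parameters (nReps, subsampleFrac, seed).
#'
#' @seealso [consensusCluster()], [selectK()], [clusterLabels()]
#' @export
setClass("ConsensusResult",
  representation(
    consensus = "list",
    labels = "list",
    auc = "numeric",
    deltaAuc = "numeric",
    chosenK = "integer",
    weakStructure = "logical",
    settings = "list"
  )
)

#' StabilitySelection: bootstrap selection frequencies of a penalized model
#'
#' Summarises repeated L1-penalized fits on bootstrap resamples: for each
#' predictor (and, for multinomial models, each class) the fraction of
#' bootstraps in which its coefficient was nonzero at the cross-validated
#' penalty, together with the mean and sd of the coefficient over the
#' bootstraps in which it was selected. Predictors are kept when their
#' selection frequency (and, where applicable, mean coefficient magnitude)
#' clears the configured thresholds.
#'
#' @slot table data.frame with columns `predictor`, optionally `class`,
#'   `frequency`, `meanCoef`, `sdCoef`, `kept`.
#' @slot settings list (family, nBoot, freqThreshold, coefThreshold, seed).
#'
#' @seealso [lassoStabilityGaussian()], [lassoStabilityMultinomial()],
#'   [interactionModulators()], [selectionTable()], [keptPredictors()]
#' @export
setClass("StabilitySelection",
  representation(
    table = "data.frame",
    settings = "list"
  )
)

setValidity("StabilitySelection", function(object) {
  tab <- object@table
  need <- c("predictor", "frequency", "meanCoef", "kept")
  if (!all(need %in% names(tab)))
    return(sprintf("table must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(tab) && any(tab$frequency < 0 | tab$frequency > 1))
    return("selection frequencies must lie in [0,1]")
  TRUE
})
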