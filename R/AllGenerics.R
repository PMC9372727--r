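#' Consensus matrix accessor
#'
#' @param x a [ConsensusResult-class] object.
#' @param k number of clusters; defaults to the chosen k.
#' @return samples x samples numeric matrix with entries in `[0, 1]`.
#' @export
setGeneric("consensusMatrix", function(x, k) standardGeneric("consensusMatrix"))

#' Cluster label accessor
#'
#' @param x a [ConsensusResult-class] object.
#' @param k number of clusters; defaults to the chosen k.
#' @return named integer vector of cluster labels.
#' @export
setGeneric("clusterLabels", function(x, k) standardGeneric("clusterLabels"))

#' Chosen number of clusters
#'
#' @param x a [ConsensusResult-class] object.
#' @return integer, the k maximizing the relative change in consensus-CDF
#'   area.
#' @export
setGeneric("selectedK", function(x) standardGeneric("selectedK"))

#' Selection-frequency table accessor
#'
#' @param x a [StabilitySelection-class] object.
#' @return data.frame of per-predictor bootstrap selection frequencies and
#'   coefficient summaries.
#' @export
setGeneric("selectionTable", function(x) standardGeneric("selectionTable"))

#' Kept predictors of a stability selection
#'
#' @param x a [StabilitySelection-class] object.
#' @return character vector of predictors whose selection frequency (and,
#'   where applicable, coefficient magnitude) cleared the thresholds.
#' @export
setGeneric("keptPredictors", function(x) standardGeneric("keptPredictors"))

#' @rdname consensusMatrix
setMethod("consensusMatrix", "ConsensusResult", function(x, k) {
  if (missing(k)) k <- x@chosenK
  key <- as.character(k)
  if (!key %in% names(x@consensus))
    stopf("k = %s was not part of the evaluated range (%s)", key,
          paste(names(x@consensus), collapse = ", "))
  x@consensus[[key]]
})

#' @rdname clusterLabels
setMethod("clusterLabels", "ConsensusResult", function(x, k) {
  if (missing(k)) k <- x@chosenK
  key <- as.character(k)
  if (!key %in% names(x@labels))
    stopf("k = %s was not part of the evaluated range (%s)", key,
          paste(names(x@labels), collapse = ", "))
  x@labels[[key]]
})

#' @rdname selectedK
setMethod("selectedK", "ConsensusResult", function(x) x@chosenK)

#' @rdname selectionTable
setMethod("selectionTable", "StabilitySelection", function(x) x@table)

#' @rdname keptPredictors
setMethod("keptPredictors", "StabilitySelection", function(x) {
  unique(x@table$predictor[x@table$kept])
})

setMethod("show", "ConsensusResult", function(object) {
  ks <- names(object@auc)
  cat("ConsensusResult\n")
  cat(sprintf("  samples: %d\n", length(object@labels[[1L]])))
  cat(sprintf("  k evaluated: %s\n", paste(ks, collapse = ", ")))
  cat(sprintf("  chosen k: %d%s\n", object@chosenK,
              if (object@weakStructure) " (weak structure)" else ""))
  cat(sprintf("  repetitions: %d at subsample fraction %.2f\n",
              object@settings$nReps, object@settings$subsampleFrac))
  invisible(NULL)
})

setMethod("show", "StabilitySelection", function(object) {
  kept <- keptPredictors(object)
  cat(sprintf("StabilitySelection (%s, %d bootstraps)\n",
              object@settings$family, object@settings$nBoot))
  cat(sprintf("  predictors: %d, kept: %d\n",
              length(unique(object@table$predictor)), length(kept)))
  if (length(kept))
    cat("  kept:", paste(kept, collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "ScreenDesign", function(object) {
  cat("ScreenDesign\n")
  cat(sprintf("  drugs: %d (%d drug-concentration conditions)\n",
              length(object@drugs), sum(lengths(object@drugs))))
  cat(sprintf("  stimuli: %d\n", length(object@stimuli)))
  cat(sprintf("  drug-stimulus combinations: %d\n",
              length(object@drugs) * length(object@stimuli)))
  cat(sprintf("  samples: %d, plated wells per sample: %d (2 plates)\n",
              object@nSamples, nrow(object@layout)))
  invisible(NULL)
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth\n")
  cat(sprintf("  drugs: %d, stimuli: %d, clusters: %s\n",
              length(object@betaD), length(object@betaS),
              paste(names(object@clusterProportions), collapse = ", ")))
  cat(sprintf("  planted interactions: %d\n", nrow(object@betaInt)))
  cat(sprintf("  genetic features: %d (missing rate %.2f)\n",
              length(object@featurePrevalence), object@featureMissingRate))
  cat(sprintf("  noiseSd: %.3f, plateEffectSd: %.3f\n",
              object@noiseSd, object@plateEffectSd))
  invisible(NULL)
})
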