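#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData colData assayNames
#' @importFrom S4Vectors DataFrame
NULL

conditionId <- function(drug, conc, stimulus) {
  hasDrug <- drug != "none"
  hasStim <- stimulus != "none"
  ifelse(hasDrug & hasStim, sprintf("%s_%g:%s", drug, conc, stimulus),
         ifelse(hasDrug, sprintf("%s_%g", drug, conc), stimulus))
}

#' Normalize raw luminescence to log relative viability
#'
#' For each plate, the median luminescence of the interior DMSO control
#' wells (controls on the outer plate edge - row 1, row 16, column 1,
#' column 24 - are excluded) defines the reference; every treated well
#' becomes `ln(luminescence / reference)`. Replicate wells of the same
#' sample and condition are averaged after the log transform. Because the
#' reference is computed within plate, any multiplicative plate effect
#' cancels exactly.
#'
#' @param wells data.frame of well records (see [readWells()]).
#' @param annotation optional sample annotation joined into `colData`.
#' @param keepDmso keep the per-plate DMSO conditions (values ~ 0 by
#'   construction)? Dropped by default.
#' @return a [ScreenExperiment-class] (conditions x samples) with assay
#'   `"logV"`.
#' @examples
#' design <- screenDesign(nSamples = 4)
#' sim <- simulateScreen(design, groundTruth(), seed = 1)
#' se <- normalizeWells(sim$wells, sim$annotation)
#' se
#' @export
normalizeWells <- function(wells, annotation = NULL, keepDmso = FALSE) {
  need <- setdiff(WELL_COLUMNS, names(wells))
  if (length(need))
    stopf("wells table is missing column(s): %s", paste(need, collapse = ", "))
  if (any(!is.finite(wells$luminescence) | wells$luminescence <= 0))
    stopf("luminescence must be positive for all wells")

  edge <- isEdgeWell(wells$well_row, wells$well_col)
  isDmso <- wells$drug == "DMSO"
  interiorDmso <- isDmso & !edge
  plates <- unique(wells$plate_id)
  noCtrl <- setdiff(plates, unique(wells$plate_id[interiorDmso]))
  if (length(noCtrl))
    stopf("plate(s) without interior DMSO controls: %s",
          paste(head(noCtrl, 5L), collapse = ", "))

  ref <- tapply(wells$luminescence[interiorDmso],
                wells$plate_id[interiorDmso], median)
  logV <- log(wells$luminescence) - log(ref[wells$plate_id])

  keep <- if (keepDmso) rep(TRUE, nrow(wells)) else !isDmso
  df <- data.frame(
    sample_id = wells$sample_id[keep],
    condition = conditionId(wells$drug[keep], wells$drug_conc_nM[keep],
                            wells$stimulus[keep]),
    drug = wells$drug[keep],
    drug_conc_nM = wells$drug_conc_nM[keep],
    stimulus = wells$stimulus[keep],
    logV = as.numeric(logV[keep]),
    stringsAsFactors = FALSE
  )
  # replicate wells of the same condition: average after log transform
  agg <- aggregate(logV ~ sample_id + condition, data = df, FUN = mean)

  samples <- unique(wells$sample_id)
  conditions <- unique(df$condition)
  mat <- matrix(NA_real_, length(conditions), length(samples),
                dimnames = list(conditions, samples))
  mat[cbind(match(agg$condition, conditions), match(agg$sample_id, samples))] <-
    agg$logV

  condMeta <- df[!duplicated(df$condition),
                 c("condition", "drug", "drug_conc_nM", "stimulus")]
  condMeta <- condMeta[match(conditions, condMeta$condition), ]
  condMeta$type <- ifelse(condMeta$drug == "DMSO", "control",
                   ifelse(condMeta$drug != "none" & condMeta$stimulus != "none",
                          "combination",
                   ifelse(condMeta$drug != "none", "drug", "stimulus")))

  cd <- DataFrame(sample_id = samples, row.names = samples)
  if (!is.null(annotation)) {
    idx <- match(samples, annotation$sample_id)
    extra <- annotation[idx, setdiff(names(annotation), "sample_id"),
                        drop = FALSE]
    rownames(extra) <- samples
    cd <- cbind(cd, DataFrame(extra))
  }
  se <- SummarizedExperiment(
    assays = list(logV = mat),
    rowData = DataFrame(condMeta, row.names = conditions),
    colData = cd
  )
  new("ScreenExperiment", se)
}

#' Extract the samples x stimuli single-treatment matrix
#'
#' @param se a [ScreenExperiment-class].
#' @return numeric matrix, samples in rows, stimulus-only conditions in
#'   columns.
#' @export
stimulusResponses <- function(se) {
  rd <- rowData(se)
  t(assay(se, "logV")[rd$type == "stimulus", , drop = FALSE])
}

#' Extract the samples x drugs single-treatment matrix
#'
#' @param se a [ScreenExperiment-class].
#' @param concPolicy which drug concentration represents each drug:
#'   `"low"` (default), `"high"`, or `"average"` over concentrations.
#' @return numeric matrix, samples in rows, one column per drug.
#' @export
drugResponses <- function(se, concPolicy = c("low", "high", "average")) {
  concPolicy <- match.arg(concPolicy)
  rd <- rowData(se)
  rows <- which(rd$type == "drug")
  m <- assay(se, "logV")[rows, , drop = FALSE]
  drug <- rd$drug[rows]; conc <- rd$drug_conc_nM[rows]
  out <- sapply(unique(drug), function(d) {
    i <- which(drug == d)
    pick <- switch(concPolicy,
                   low = i[which.min(conc[i])],
                   high = i[which.max(conc[i])],
                   average = i)
    if (length(pick) > 1L) colMeans(m[pick, , drop = FALSE]) else m[pick, ]
  })
  rownames(out) <- colnames(se)
  out
}

#' Robust z-scaling of a response matrix
#'
#' Each row (sample) is centred at its median and scaled by its median
#' absolute deviation (without the 1.4826 consistency constant), with the
#' scaling factor floored at `madFloor` so constant rows map to zero rather
#' than infinity. The returned values are uncapped; `display` is a copy
#' clipped to `+/- cap` for plotting.
#'
#' @param x numeric matrix, samples in rows.
#' @param cap display clipping limit (default 4).
#' @param madFloor lower bound on the row MAD (default 1e-8).
#' @return list with `z` (uncapped matrix) and `display` (clipped copy).
#' @examples
#' robustZ(rbind(a = 1:5))$z
#' @export
robustZ <- function(x, cap = 4, madFloor = 1e-8) {
  x <- as.matrix(x)
  if (ncol(x) < 2L)
    stopf("robust z-scaling needs >= 2 conditions per row")
  empty <- apply(x, 1L, function(r) all(is.na(r)))
  if (any(empty))
    stopf("row(s) with no observed values: %s",
          paste(head(rownames(x)[empty], 5L), collapse = ", "))
  ctr <- apply(x, 1L, median, na.rm = TRUE)
  scl <- pmax(rowMad(x, ctr), madFloor)
  z <- (x - ctr) / scl
  list(z = z, display = pmin(pmax(z, -cap), cap))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin validated wrapper over
#' [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return adjusted p-values, elementwise >= the input and <= 1.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pairwise Pearson correlations with FDR control
#'
#' Correlates every pair of single-treatment columns across samples
#' (pairwise-complete observations), tests each correlation against zero
#' (two-sided) and adjusts the p-values by Benjamini-Hochberg within the
#' supplied block. Call once for the drug block and once for the stimulus
#' block to adjust them separately. Constant columns yield undefined
#' correlations, reported as NA and excluded from the adjustment.
#'
#' @param x numeric matrix, samples in rows, treatments in columns.
#' @param fdr significance threshold on the adjusted p-value (default 0.05).
#' @param minPairs minimum complete pairs per correlation (default 3).
#' @return list with symmetric matrices `r`, `p`, `padj` and logical
#'   `significant` (unit diagonal in `r`, NA diagonal elsewhere).
#' @export
pairwiseCorrelations <- function(x, fdr = 0.05, minPairs = 3L) {
  x <- as.matrix(x)
  k <- ncol(x)
  if (k < 2L) stopf("need at least two treatments to correlate")
  r <- p <- matrix(NA_real_, k, k, dimnames = list(colnames(x), colnames(x)))
  diag(r) <- 1
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ok <- is.finite(x[, i]) & is.finite(x[, j])
      if (sum(ok) < minPairs) next
      if (sd(x[ok, i]) == 0 || sd(x[ok, j]) == 0) next  # undefined
      ct <- cor.test(x[ok, i], x[ok, j], method = "pearson",
                     alternative = "two.sided")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  up <- upper.tri(p)
  padj <- matrix(NA_real_, k, k, dimnames = dimnames(p))
  adj <- rep(NA_real_, sum(up))
  notNa <- !is.na(p[up])
  adj[notNa] <- bhAdjust(p[up][notNa])
  padj[up] <- adj
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  significant <- !is.na(padj) & padj < fdr
  list(r = r, p = p, padj = padj, significant = significant)
}
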