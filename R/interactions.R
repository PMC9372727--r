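#' Fit the pooled drug-stimulus interaction model for one pair
#'
#' Least-squares fit of the no-intercept linear model
#' `logV = bd*Xd + bs*Xs + bint*Xd*Xs + eps` on the drug-only,
#' stimulus-only and combination observations of one drug-stimulus pair
#' across samples. DMSO rows (`Xd = Xs = 0`) carry no information under
#' this parameterization and are excluded. With balanced data the
#' estimates equal condition means: `bd = mean(logV | drug)`,
#' `bs = mean(logV | stimulus)`,
#' `bint = mean(logV | combination) - bd - bs`; with unbalanced data the
#' least-squares solution is authoritative. The interaction p-value is the
#' two-sided t-test on `bint` with residual degrees of freedom.
#'
#' @param observations data.frame with columns `logV`, `Xd`, `Xs` (0/1
#'   indicators) and optionally `sample_id`.
#' @return one-row data.frame: beta_d, beta_s, beta_int, se_int, p_int,
#'   sigma (residual sd), df, n_obs.
#' @examples
#' obs <- data.frame(logV = c(-0.5, 0.3, 0.1), Xd = c(1, 0, 1), Xs = c(0, 1, 1))
#' fitInteractionPooled(rbind(obs, obs))  # beta_int = 0.1 - (-0.5) - 0.3
#' @export
fitInteractionPooled <- function(observations) {
  obs <- observations[!(observations$Xd == 0 & observations$Xs == 0), ,
                      drop = FALSE]
  if (!all(obs$Xd %in% c(0, 1)) || !all(obs$Xs %in% c(0, 1)))
    stopf("Xd and Xs must be 0/1 indicators")
  obs <- obs[is.finite(obs$logV), , drop = FALSE]
  for (cond in list(c(1, 0, "drug-only"), c(0, 1, "stimulus-only"),
                    c(1, 1, "combination"))) {
    if (!any(obs$Xd == as.numeric(cond[1]) & obs$Xs == as.numeric(cond[2])))
      stopf("no %s observations for this pair", cond[3])
  }
  X <- cbind(Xd = obs$Xd, Xs = obs$Xs, Xint = obs$Xd * obs$Xs)
  fit <- stats::lm.fit(X, obs$logV)
  beta <- fit$coefficients
  n <- nrow(obs)
  df <- n - 3L
  if (df > 0L) {
    sigma2 <- sum(fit$residuals^2) / df
    XtXinv <- chol2inv(chol(crossprod(X)))
    seInt <- sqrt(sigma2 * XtXinv[3L, 3L])
    tInt <- beta[["Xint"]] / seInt
    pInt <- 2 * pt(-abs(tInt), df)
    sigma <- sqrt(sigma2)
  } else {
    seInt <- NA_real_; pInt <- NA_real_; sigma <- NA_real_
  }
  data.frame(beta_d = beta[["Xd"]], beta_s = beta[["Xs"]],
             beta_int = beta[["Xint"]], se_int = seInt, p_int = pInt,
             sigma = sigma, df = df, n_obs = n)
}

#' Sample-specific interaction coefficient
#'
#' In a single sample the no-intercept model is saturated, so the
#' interaction coefficient is the algebraic identity
#' `beta_int = logV(combination) - logV(drug) - logV(stimulus)` (replicates
#' averaged first).
#'
#' @param logVDrug,logVStimulus,logVCombination log relative viability of
#'   the three treated conditions (each may be a vector of replicates).
#' @return the sample-specific interaction coefficient; NA (with a logged
#'   reason) when a condition is missing.
#' @examples
#' fitInteractionPerSample(-0.4, 0.1, 0.2)  # 0.5
#' @export
fitInteractionPerSample <- function(logVDrug, logVStimulus, logVCombination) {
  m <- vapply(list(logVDrug, logVStimulus, logVCombination),
              function(v) mean(v[is.finite(v)]), numeric(1))
  if (any(is.na(m))) {
    screenLog("debug", "per-sample fit skipped: missing condition")
    return(NA_real_)
  }
  m[3L] - m[1L] - m[2L]
}

#' Classify a significant interaction into categories I-IV
#'
#' Categories follow the sign of the interaction coefficient and whether
#' the combination effect is antagonistic or synergistic:
#' \describe{
#'   \item{I}{positive `beta_int`, antagonistic - the stimulus offsets a
#'     toxic drug (`beta_d < 0` and `beta_int <= |beta_d|`).}
#'   \item{III}{positive `beta_int`, synergistic pro-survival effect
#'     (otherwise).}
#'   \item{II}{negative `beta_int`, antagonistic - the drug offsets a
#'     pro-survival stimulus (`beta_s > 0` and `|beta_int| <= beta_s`).}
#'   \item{IV}{negative `beta_int`, synergistic toxicity (otherwise).}
#' }
#' Non-significant interactions (`p_int >= alpha`) are `"none"`. Boundary
#' ties (the interaction exactly cancelling the single-agent effect)
#' classify as antagonistic, the cancellation limit.
#'
#' @param betaD,betaS,betaInt model coefficients (vectorized).
#' @param pInt interaction p-value(s).
#' @param alpha significance threshold (default 0.05, unadjusted).
#' @return character vector in `c("I","II","III","IV","none")`.
#' @examples
#' categorizeInteraction(-0.69, 0.10, 0.55, 0.001)  # "I"
#' @export
categorizeInteraction <- function(betaD, betaS, betaInt, pInt, alpha = 0.05) {
  out <- rep("none", length(betaInt))
  sig <- !is.na(pInt) & pInt < alpha & betaInt != 0
  pos <- sig & betaInt > 0
  neg <- sig & betaInt < 0
  out[pos] <- ifelse(betaD[pos] < 0 & betaInt[pos] <= abs(betaD[pos]),
                     "I", "III")
  out[neg] <- ifelse(betaS[neg] > 0 & abs(betaInt[neg]) <= betaS[neg],
                     "II", "IV")
  out
}

# assemble per-pair observations from a ScreenExperiment
pairObservations <- function(se, concPolicy = "low") {
  rd <- as.data.frame(rowData(se))
  logV <- assay(se, "logV")
  drugs <- unique(rd$drug[rd$type == "drug"])
  stimuli <- unique(rd$stimulus[rd$type == "stimulus"])

  pickRows <- function(rows, conc) {
    if (length(rows) <= 1L) return(rows)
    switch(concPolicy,
           low = rows[which.min(conc)],
           high = rows[which.max(conc)],
           average = rows)
  }
  rowValues <- function(rows) {
    if (length(rows) > 1L) colMeans(logV[rows, , drop = FALSE])
    else logV[rows, ]
  }
  drugRows <- lapply(drugs, function(d) {
    r <- which(rd$type == "drug" & rd$drug == d)
    pickRows(r, rd$drug_conc_nM[r])
  })
  names(drugRows) <- drugs
  stimRows <- lapply(stimuli, function(s) which(rd$type == "stimulus" &
                                                  rd$stimulus == s))
  names(stimRows) <- stimuli
  comboRows <- function(d, s) {
    r <- which(rd$type == "combination" & rd$drug == d & rd$stimulus == s)
    pickRows(r, rd$drug_conc_nM[r])
  }
  list(drugs = drugs, stimuli = stimuli,
       drugV = lapply(drugRows, rowValues),
       stimV = lapply(stimRows, rowValues),
       comboV = function(d, s) {
         r <- comboRows(d, s)
         if (!length(r)) return(NULL)
         rowValues(r)
       },
       samples = colnames(se))
}

#' Screen all drug-stimulus pairs for interactions
#'
#' Fits the pooled no-intercept interaction model for every drug-stimulus
#' pair of the experiment (one effective condition per drug, chosen by the
#' concentration policy) and classifies the significant interactions into
#' categories I-IV. Per-pair failures are propagated as flagged rows; the
#' screen never aborts.
#'
#' @param se a [ScreenExperiment-class].
#' @param alpha unadjusted significance threshold for the interaction term
#'   (default 0.05).
#' @param concPolicy `"low"` (default), `"high"` or `"average"`: which drug
#'   concentration enters the analysis.
#' @return data.frame with one row per pair: drug, stimulus, beta_d,
#'   beta_s, beta_int, se_int, p_int, df, n_obs, category, error. The
#'   attribute `"categoryCounts"` tabulates categories I-IV.
#' @examples
#' sim <- simulateScreen(screenDesign(nSamples = 6), groundTruth(), seed = 1)
#' fits <- interactionScreen(normalizeWells(sim$wells))
#' head(fits)
#' @export
interactionScreen <- function(se, alpha = 0.05,
                              concPolicy = c("low", "high", "average")) {
  concPolicy <- match.arg(concPolicy)
  po <- pairObservations(se, concPolicy)
  grid <- expand.grid(drug = po$drugs, stimulus = po$stimuli,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    d <- grid$drug[i]; s <- grid$stimulus[i]
    res <- tryCatch({
      dv <- po$drugV[[d]]; sv <- po$stimV[[s]]; cv <- po$comboV(d, s)
      if (is.null(cv)) stopf("no combination observations for this pair")
      obs <- data.frame(
        logV = c(dv, sv, cv),
        Xd = rep(c(1, 0, 1), each = length(po$samples)),
        Xs = rep(c(0, 1, 1), each = length(po$samples))
      )
      fit <- fitInteractionPooled(obs)
      fit$error <- NA_character_
      fit
    }, error = function(e) {
      data.frame(beta_d = NA_real_, beta_s = NA_real_, beta_int = NA_real_,
                 se_int = NA_real_, p_int = NA_real_, sigma = NA_real_,
                 df = NA_integer_, n_obs = 0L, error = conditionMessage(e))
    })
    out[[i]] <- cbind(grid[i, , drop = FALSE], res)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$category <- categorizeInteraction(out$beta_d, out$beta_s, out$beta_int,
                                        out$p_int, alpha)
  counts <- table(factor(out$category, levels = c("I", "II", "III", "IV")))
  attr(out, "categoryCounts") <- counts
  screenLog("info", sprintf(
    "interaction screen: %d pairs, %d significant at alpha = %g (I:%d II:%d III:%d IV:%d)",
    nrow(out), sum(out$category != "none"), alpha,
    counts[["I"]], counts[["II"]], counts[["III"]], counts[["IV"]]))
  out
}

#' Sample-specific interaction coefficients for all pairs
#'
#' Applies the saturated-model identity of [fitInteractionPerSample()] to
#' every sample and drug-stimulus pair.
#'
#' @inheritParams interactionScreen
#' @return long data.frame: sample_id, drug, stimulus, beta_int (NA where a
#'   condition is missing for that sample).
#' @export
perSampleInteractions <- function(se, concPolicy = c("low", "high", "average")) {
  concPolicy <- match.arg(concPolicy)
  po <- pairObservations(se, concPolicy)
  grid <- expand.grid(drug = po$drugs, stimulus = po$stimuli,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    d <- grid$drug[i]; s <- grid$stimulus[i]
    cv <- po$comboV(d, s)
    bint <- if (is.null(cv)) rep(NA_real_, length(po$samples))
            else cv - po$drugV[[d]] - po$stimV[[s]]
    out[[i]] <- data.frame(sample_id = po$samples, drug = d, stimulus = s,
                           beta_int = as.numeric(bint),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
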