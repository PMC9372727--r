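#' Cox proportional hazards regression
#'
#' Maximum partial likelihood estimation with Efron handling of tied event
#' times, via [survival::coxph()]. Categorical covariates are expanded
#' against the supplied reference levels, so hazard ratios read as "level
#' vs reference".
#'
#' @param records data.frame with `time`, `event` and covariate columns.
#' @param covariates character vector of covariate column names.
#' @param reference optional named list of reference levels for categorical
#'   covariates (e.g. `list(cluster = "C4")`).
#' @return data.frame: term, logHR, se, z, p; the fitted
#'   [survival::coxph] object is attached as attribute `"model"`.
#' @examples
#' rec <- data.frame(time = c(5, 8, 12, 20), event = 1,
#'                   group = c("a", "a", "b", "b"))
#' fitCox(rec, "group")
#' @export
fitCox <- function(records, covariates, reference = list()) {
  if (!all(c("time", "event") %in% names(records)))
    stopf("records needs 'time' and 'event' columns")
  missing <- setdiff(covariates, names(records))
  if (length(missing))
    stopf("covariate(s) not found: %s", paste(missing, collapse = ", "))
  if (sum(records$event) < 2L) stopf("need >= 2 observed events")
  dat <- records
  for (cv in covariates) {
    v <- dat[[cv]]
    if (length(unique(v[!is.na(v)])) < 2L)
      stopf("covariate '%s' is constant", cv)
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      if (cv %in% names(reference))
        v <- stats::relevel(v, ref = reference[[cv]])
      dat[[cv]] <- v
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron",
                    control = survival::coxph.control(iter.max = 100L)),
    warning = function(w) {
      if (grepl("converge|infinite", conditionMessage(w)))
        stopf("Cox model did not converge in 100 iterations (possible complete separation): %s",
              conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(!is.finite(coef(fit))))
    stopf("Cox model did not converge (possible complete separation)")
  s <- summary(fit)
  out <- data.frame(
    term = rownames(s$coefficients),
    logHR = s$coefficients[, "coef"],
    se = s$coefficients[, "se(coef)"],
    z = s$coefficients[, "z"],
    p = s$coefficients[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "model") <- fit
  out
}

#' Kaplan-Meier product-limit estimator
#'
#' @param time,event numeric vectors (days, 0/1 indicator).
#' @param group optional grouping vector; one curve per group.
#' @return data.frame of right-continuous steps: group, time, n_risk,
#'   n_event, survival; each curve starts at S(0) = 1 and steps only at
#'   event times.
#' @examples
#' kaplanMeier(c(1, 2, 3), c(1, 1, 1))
#' @export
kaplanMeier <- function(time, event, group = NULL) {
  if (is.null(group)) group <- rep("all", length(time))
  if (any(table(group) < 1L)) stopf("every group needs >= 1 record")
  dat <- data.frame(time = time, event = event, group = as.character(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = dat,
                           conf.type = "none")
  strata <- if (is.null(fit$strata)) setNames(length(fit$time), unique(dat$group))
            else fit$strata
  grpNames <- sub("^group=", "", names(strata))
  out <- data.frame(
    group = rep(grpNames, strata),
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    survival = fit$surv, stringsAsFactors = FALSE
  )
  start <- data.frame(group = grpNames, time = 0,
                      n_risk = as.vector(table(dat$group)[grpNames]),
                      n_event = 0L, survival = 1,
                      stringsAsFactors = FALSE)
  out <- rbind(start, out)
  out[order(out$group, out$time), , drop = FALSE]
}

# standardized two-group log-rank statistic; grp is logical (TRUE = group 1)
logRankZ <- function(time, event, grp) {
  eventTimes <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (t in eventTimes) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & grp)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & grp)
    U <- U + d1 - d * n1 / n
    if (n > 1L)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) return(NA_real_)
  U / sqrt(V)
}

#' Maximally selected rank statistics for marker dichotomization
#'
#' Scans all candidate cutpoints of a continuous marker (observed marker
#' values inside the given quantile window), computes the standardized
#' two-group log-rank statistic of "marker <= cutpoint" vs "marker >
#' cutpoint" at each, and returns the cutpoint maximizing the absolute
#' statistic. Because the maximally selected statistic is not chi-squared
#' distributed, the p-value is obtained by permutation of the marker values
#' (the same scan applied to `nPerm` seeded permutations).
#'
#' @param marker numeric marker per sample (e.g. staining intensity).
#' @param time,event survival outcome of the same samples.
#' @param window quantile window `(low, high)` restricting candidate
#'   cutpoints (default `c(0.1, 0.9)`).
#' @param nPerm permutation resamples for the p-value (default 1000).
#' @param seed integer seed.
#' @return list: cutpoint, statistic (signed z at the cutpoint), maxAbsZ,
#'   p, and the scan table `candidates` (cutpoint, z).
#' @export
maxstatCutpoint <- function(marker, time, event, window = c(0.1, 0.9),
                            nPerm = 1000L, seed) {
  seed <- assertSeed(seed)
  n <- length(marker)
  if (n < 10L) stopf("need >= 10 samples")
  if (length(time) != n || length(event) != n)
    stopf("marker, time and event must have the same length")
  if (length(unique(marker)) < 2L) stopf("marker is constant")
  if (!(window[1] > 0 && window[1] < window[2] && window[2] < 1))
    stopf("window must satisfy 0 < low < high < 1")

  scanMax <- function(mk) {
    q <- quantile(mk, window, names = FALSE)
    cand <- sort(unique(mk))
    cand <- cand[cand >= q[1] & cand < max(mk)]  # both groups non-empty
    cand <- cand[cand <= q[2]]
    if (length(cand) < 2L) return(NULL)
    z <- vapply(cand, function(cp) logRankZ(time, event, mk <= cp), numeric(1))
    list(cand = cand, z = z)
  }
  obs <- scanMax(marker)
  if (is.null(obs))
    stopf("fewer than 2 candidate cutpoints inside the quantile window")
  best <- which.max(abs(obs$z))
  maxAbs <- abs(obs$z[best])

  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(nPerm)) {
    perm <- scanMax(sample(marker))
    pz <- if (is.null(perm)) 0 else max(abs(perm$z), na.rm = TRUE)
    if (pz >= maxAbs) exceed <- exceed + 1L
  }
  list(cutpoint = obs$cand[best], statistic = obs$z[best], maxAbsZ = maxAbs,
       p = (1L + exceed) / (nPerm + 1L),
       candidates = data.frame(cutpoint = obs$cand, z = obs$z))
}

#' Student's t-test (pooled-variance or paired)
#'
#' Two-sided Student's t-test: the unpaired variant uses the pooled
#' (equal-variance) estimate; the paired variant tests the mean
#' within-pair difference.
#'
#' @param x,y numeric vectors (equal lengths when paired).
#' @param paired logical (default FALSE).
#' @return list: t, df, p, and `degenerate = TRUE` with NA statistics when
#'   there is no variance to test against.
#' @examples
#' twoSampleTTest(c(0.9, 1.0, 1.1), c(-0.1, 0.0, 0.1))
#' @export
twoSampleTTest <- function(x, y, paired = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (paired && length(x) != length(y))
    stopf("paired test requires equal-length vectors")
  if (length(x) < 2L || length(y) < 2L)
    stopf("need >= 2 observations per group")
  if (paired && var(x - y) == 0) {
    if (mean(x - y) == 0)  # identical pairs: no difference to detect
      return(list(t = 0, df = length(x) - 1L, p = 1, degenerate = FALSE))
    warnf("zero variance of the paired differences: t statistic undefined")
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  if (!paired && var(x) == 0 && var(y) == 0) {
    warnf("zero variance in both groups: t statistic undefined")
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  tt <- t.test(x, y, paired = paired, var.equal = TRUE,
               alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       degenerate = FALSE)
}
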