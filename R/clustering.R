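consensusCdfArea <- function(consensus) {
  vals <- consensus[upper.tri(consensus)]
  F <- ecdf(vals)
  kn <- sort(unique(c(0, vals, 1)))
  sum(F(head(kn, -1L)) * diff(kn))
}

#' Consensus clustering of stimulus-response profiles
#'
#' Repeats hierarchical clustering (Euclidean distance, average linkage) on
#' random subsets of the samples: in each repetition a fraction
#' `subsampleFrac` of samples is drawn without replacement, clustered, and
#' cut at each candidate k. The consensus matrix entry (i, j) is the number
#' of co-clusterings divided by the number of co-samplings of the pair.
#' Final labels at each k come from hierarchical clustering of
#' `1 - consensus` as a distance, cut at k. The number of clusters is
#' chosen by [selectK()]; the full area-under-CDF curve is retained so the
#' choice can be overridden (e.g. fixed to k = 4).
#'
#' Rows containing missing values are dropped with a warning before
#' clustering.
#'
#' @param x numeric matrix, samples in rows (typically the robust-z scaled
#'   stimulus-only response matrix).
#' @param kRange candidate numbers of clusters (subset of 2..n-1).
#' @param nReps number of subsampling repetitions (default 1000; increase
#'   to 10000 for production runs).
#' @param subsampleFrac fraction of samples drawn per repetition (default
#'   0.8).
#' @param seed integer seed; identical seeds give identical results.
#' @return a [ConsensusResult-class].
#' @examples
#' x <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 6), 10))
#' rownames(x) <- paste0("S", 1:20)
#' res <- consensusCluster(x, kRange = 2:4, nReps = 50, seed = 1)
#' selectedK(res)
#' @export
consensusCluster <- function(x, kRange = 2:6, nReps = 1000L,
                             subsampleFrac = 0.8, seed) {
  seed <- assertSeed(seed)
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("S%03d", seq_len(nrow(x)))
  hasNa <- apply(x, 1L, function(r) any(!is.finite(r)))
  if (any(hasNa)) {
    warnf("dropping %d sample(s) with missing values before clustering",
          sum(hasNa))
    screenLog("warn", sprintf("dropped: %s",
                              paste(rownames(x)[hasNa], collapse = ", ")))
    x <- x[!hasNa, , drop = FALSE]
  }
  n <- nrow(x)
  if (nReps < 1L) stopf("nReps must be >= 1")
  if (subsampleFrac <= 0 || subsampleFrac > 1)
    stopf("subsampleFrac must lie in (0, 1]")
  kRange <- sort(unique(as.integer(kRange)))
  if (any(kRange < 2L) || any(kRange > n - 1L))
    stopf("kRange must lie within 2..%d for %d samples", n - 1L, n)

  m <- ceiling(subsampleFrac * n)
  coSampled <- matrix(0, n, n)
  coClustered <- lapply(kRange, function(k) matrix(0, n, n))
  names(coClustered) <- as.character(kRange)

  set.seed(seed)
  for (rep in seq_len(nReps)) {
    idx <- if (m == n) seq_len(n) else sort(sample.int(n, m))
    hc <- hclust(dist(x[idx, , drop = FALSE], method = "euclidean"),
                 method = "average")
    coSampled[idx, idx] <- coSampled[idx, idx] + 1
    for (k in kRange) {
      ct <- cutree(hc, k = k)
      same <- outer(ct, ct, "==")
      key <- as.character(k)
      coClustered[[key]][idx, idx] <- coClustered[[key]][idx, idx] + same
    }
  }

  neverCoSampled <- coSampled == 0 & upper.tri(coSampled)
  if (any(neverCoSampled))
    warnf("%d sample pair(s) were never co-sampled; their consensus is 0",
          sum(neverCoSampled))

  consensus <- labels <- list()
  auc <- numeric(length(kRange))
  names(auc) <- as.character(kRange)
  for (key in as.character(kRange)) {
    cons <- coClustered[[key]] / pmax(coSampled, 1)
    cons[coSampled == 0] <- 0
    diag(cons) <- 1
    dimnames(cons) <- list(rownames(x), rownames(x))
    fin <- hclust(as.dist(1 - cons), method = "average")
    lab <- cutree(fin, k = as.integer(key))
    consensus[[key]] <- cons
    labels[[key]] <- lab
    auc[key] <- consensusCdfArea(cons)
  }

  res <- new("ConsensusResult", consensus = consensus, labels = labels,
             auc = auc, deltaAuc = numeric(0), chosenK = kRange[1L],
             weakStructure = FALSE,
             settings = list(nReps = as.integer(nReps),
                             subsampleFrac = subsampleFrac, seed = seed))
  selectK(res)
}

#' Choose the number of clusters from the consensus-CDF curve
#'
#' Computes the relative change in area under the consensus CDF along the
#' evaluated k (for the smallest k, the area itself) and chooses the k that
#' maximizes it - the standard consensus-clustering criterion. The result
#' is flagged as weak structure when either the relative-change curve
#' beyond the smallest k is flat (all below 0.1) or the consensus matrix at
#' the chosen k is ambiguous: more than 20% of sample pairs have consensus
#' strictly between 0.1 and 0.9 (the proportion-of-ambiguous-clustering
#' criterion), which is the signature of subsampled clustering on
#' unstructured data.
#'
#' @param x a [ConsensusResult-class].
#' @return the same object with `deltaAuc`, `chosenK` and `weakStructure`
#'   filled in; retrieve the choice with [selectedK()].
#' @export
selectK <- function(x) {
  stopifnot(is(x, "ConsensusResult"))
  auc <- x@auc
  ks <- as.integer(names(auc))
  delta <- auc
  if (length(auc) > 1L) {
    delta[-1L] <- diff(auc) / head(auc, -1L)
  }
  x@deltaAuc <- delta
  x@chosenK <- ks[which.max(delta)]
  cons <- x@consensus[[as.character(x@chosenK)]]
  vals <- cons[upper.tri(cons)]
  pac <- mean(vals > 0.1 & vals < 0.9)
  flatCurve <- length(auc) > 1L && max(delta[-1L]) < 0.1
  x@weakStructure <- flatCurve || pac > 0.2
  x
}
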