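simSurv <- function(n, rate1, rate2, censMax = 0, seed = 1) {
  set.seed(seed)
  g <- rep(c("a", "b"), each = n)
  t <- c(rexp(n, rate1), rexp(n, rate2))
  cens <- if (censMax > 0) runif(2 * n, 0, censMax) else rep(Inf, 2 * n)
  data.frame(time = pmin(t, cens), event = as.integer(t <= cens), group = g)
}

test_that("Cox estimates match a brute-force partial-likelihood search", {
  # interleaved groups keep the partial likelihood bounded (a toy with all
  # of one group failing first is completely separated)
  toy <- data.frame(time = c(1, 2, 3, 4), event = 1, group = c(0, 1, 0, 1))
  fit <- fitCox(toy, "group")
  grid <- optimize(function(b) -coxLogPL(b, toy$time, toy$event, toy$group),
                   c(-10, 10), tol = 1e-9)
  expect_equal(fit$logHR, grid$minimum, tolerance = 1e-6)
  # separation is reported, not silently returned
  sep <- data.frame(time = c(1, 2, 3, 4), event = 1, group = c(0, 0, 1, 1))
  expect_error(fitCox(sep, "group"), "converge")
})

test_that("Cox recovers a planted hazard ratio and is time-scale invariant", {
  d <- simSurv(500, 1 / 1000, 2 / 1000, seed = 2)
  fit <- fitCox(d, "group")
  expect_lt(abs(fit$logHR - log(2)), 0.15)
  scaled <- d
  scaled$time <- scaled$time * 3.7
  expect_equal(fitCox(scaled, "group")$logHR, fit$logHR, tolerance = 1e-8)

  nullD <- simSurv(500, 1 / 1000, 1 / 1000, seed = 3)
  expect_lt(abs(fitCox(nullD, "group")$logHR), 0.05 + 0.1)

  expect_error(fitCox(data.frame(time = 1:4, event = c(1, 0, 0, 0),
                                 group = c(0, 0, 1, 1)), "group"),
               ">= 2")
  expect_error(fitCox(data.frame(time = 1:4, event = 1, group = 1), "group"),
               "constant")
})

test_that("multivariate Cox expands categorical covariates vs the reference", {
  d <- simSurv(100, 1 / 500, 2 / 500, seed = 4)
  d$cluster <- sample(c("C3", "C4"), nrow(d), replace = TRUE)
  fit <- fitCox(d, c("group", "cluster"), reference = list(cluster = "C4"))
  expect_true(any(grepl("C3", fit$term)))
  expect_equal(nrow(fit), 2L)
})

test_that("Kaplan-Meier matches the hand-computed product limit", {
  km <- kaplanMeier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(1, 2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(km$time, c(0, 1, 2, 3))
  # all censored: S stays at 1
  kmC <- kaplanMeier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(kmC$survival == 1))
  # monotone non-increasing within [0, 1]
  set.seed(5)
  km2 <- kaplanMeier(rexp(50), rbinom(50, 1, 0.7))
  expect_true(all(diff(km2$survival) <= 1e-12))
  expect_true(all(km2$survival >= 0 & km2$survival <= 1))
  # no censoring: equals the empirical survival function
  tt <- c(2, 5, 1, 7, 3)
  km3 <- kaplanMeier(tt, rep(1, 5))
  emp <- sapply(km3$time, function(t) mean(tt > t))
  expect_equal(km3$survival, emp, tolerance = 1e-12)
})

test_that("the log-rank z agrees with survdiff and the Cox score test", {
  set.seed(6)
  d <- simSurv(40, 1 / 100, 2 / 100, censMax = 300, seed = 6)
  grp <- d$group == "a"
  z <- DrugStimScreen:::logRankZ(d$time, d$event, grp)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  expect_equal(z^2, sd$chisq, tolerance = 1e-8)
  # score test of the two-group Cox model at beta = 0
  cox <- survival::coxph(survival::Surv(time, event) ~ I(group == "a"),
                         data = d, ties = "breslow")
  expect_equal(z^2, unname(cox$score), tolerance = 1e-6)
})

test_that("maxstat scan equals an exhaustive survdiff scan exactly", {
  set.seed(7)
  n <- 40
  marker <- rnorm(n)
  time <- rexp(n, ifelse(marker > median(marker), 2 / 100, 1 / 100))
  event <- rbinom(n, 1, 0.8)
  res <- maxstatCutpoint(marker, time, event, nPerm = 50, seed = 1)
  q <- quantile(marker, c(0.1, 0.9), names = FALSE)
  cand <- sort(unique(marker))
  cand <- cand[cand >= q[1] & cand <= q[2] & cand < max(marker)]
  oracle <- sapply(cand, function(cp) {
    grp <- marker <= cp
    sdf <- survival::survdiff(survival::Surv(time, event) ~ grp)
    sqrt(sdf$chisq)
  })
  expect_equal(res$maxAbsZ, max(oracle), tolerance = 1e-10)
  expect_equal(res$cutpoint, cand[which.max(oracle)])
  expect_equal(nrow(res$candidates), length(cand))

  expect_error(maxstatCutpoint(rep(1, 20), rexp(20), rbinom(20, 1, 0.5),
                               seed = 1), "constant")
})

test_that("a marker separating early and late events is found at the gap", {
  set.seed(8)
  n <- 40
  marker <- seq_len(n)  # rank marker
  time <- c(rexp(n / 2, 1 / 20), rexp(n / 2, 1 / 400))  # early | late
  event <- rep(1L, n)
  res <- maxstatCutpoint(marker, time, event, nPerm = 200, seed = 2)
  expect_gt(res$cutpoint, n * 0.25)
  expect_lt(res$cutpoint, n * 0.75)
  expect_lt(res$p, 0.05)
})

test_that("maxstat permutation p is well behaved under the null", {
  set.seed(9)
  over <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 30
    marker <- rnorm(n)
    time <- rexp(n, 1 / 100)
    event <- rbinom(n, 1, 0.8)
    res <- maxstatCutpoint(marker, time, event, nPerm = 200, seed = s)
    if (res$p > 0.05) over <- over + 1
  }
  expect_gte(over, 8)  # null markers rarely reach significance
})

test_that("t-tests handle paired, degenerate and hand-computed cases", {
  r <- twoSampleTTest(c(0.9, 1.0, 1.1), c(-0.1, 0.0, 0.1))
  expect_equal(r$t, 12.24745, tolerance = 1e-5)
  expect_equal(r$df, 4)
  x <- c(1.2, 0.8, 1.4)
  p <- twoSampleTTest(x, x, paired = TRUE)
  expect_equal(p$t, 0)
  expect_equal(p$p, 1)
  expect_warning(dg <- twoSampleTTest(c(1, 1, 1), c(2, 2, 2)), "variance")
  expect_true(dg$degenerate)
  expect_true(is.na(dg$p))
  expect_error(twoSampleTTest(1:3, 1:4, paired = TRUE), "equal-length")
})
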