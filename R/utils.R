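#' @importFrom stats median mad quantile rnorm rexp runif rbinom sd var
#'   p.adjust pt cor cor.test t.test cutree hclust dist as.dist ecdf
#'   complete.cases setNames coef predict aggregate
#' @importFrom utils read.delim write.table head tail
NULL

# package-level log levels, in increasing verbosity
.LOG_LEVELS <- c(error = 1L, warn = 2L, info = 3L, debug = 4L)

screenLogLevel <- function() {
  lv <- getOption("DrugStimScreen.logLevel", "info")
  if (!lv %in% names(.LOG_LEVELS)) lv <- "info"
  lv
}

# messages go to stderr so result tables on stdout stay clean
screenLog <- function(level = "info", ...) {
  if (.LOG_LEVELS[[level]] <= .LOG_LEVELS[[screenLogLevel()]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

# fail with a consistent message style
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assertScalarNumber <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single non-missing number", name)
  if (positive && x <= 0)
    stopf("'%s' must be > 0", name)
  invisible(x)
}

assertSeed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("a single integer 'seed' is required for reproducibility")
  invisible(as.integer(seed))
}

# row-wise median absolute deviation without the 1.4826 consistency constant
rowMad <- function(x, center) {
  apply(abs(x - center), 1L, median, na.rm = TRUE)
}
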