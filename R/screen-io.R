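WELL_COLUMNS <- c("sample_id", "plate_id", "well_row", "well_col",
                  "drug", "drug_conc_nM", "stimulus", "luminescence")

# apply an optional standard-name -> file-column mapping, then check headers
resolveColumns <- function(df, required, columnMap = NULL, path = "") {
  if (!is.null(columnMap)) {
    for (std in names(columnMap)) {
      src <- columnMap[[std]]
      if (!src %in% names(df))
        stopf("column '%s' (mapped to '%s') not found in %s", src, std, path)
      names(df)[names(df) == src] <- std
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("%s is missing required column(s): %s", path,
          paste(missing, collapse = ", "))
  df
}

failRows <- function(bad, path, what) {
  if (any(bad, na.rm = TRUE)) {
    rows <- which(bad)
    stopf("%s: %s in row(s) %s", path, what,
          paste(head(rows, 5L), collapse = ", "))
  }
}

#' Read a well-level luminescence table
#'
#' Reads a TSV of raw well records and validates every row: positive
#' luminescence, well coordinates inside the 384-well (16 x 24) grid, and
#' DMSO control wells without a stimulus. Rejected values are reported with
#' their row number; nothing is silently coerced. Row order is preserved.
#'
#' @param path TSV file with columns sample_id, plate_id, well_row,
#'   well_col, drug, drug_conc_nM, stimulus, luminescence ("NA" for missing
#'   concentration).
#' @param columnMap optional named character vector mapping standard column
#'   names to the file's column names (for externally deposited tables).
#' @return validated data.frame of well records.
#' @seealso [writeWells()], [normalizeWells()]
#' @export
readWells <- function(path, columnMap = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "NA", check.names = FALSE)
  df <- resolveColumns(df, WELL_COLUMNS, columnMap, path)
  df <- df[, WELL_COLUMNS]
  failRows(!is.finite(df$luminescence) | df$luminescence <= 0, path,
           "non-positive or missing luminescence")
  failRows(is.na(df$well_row) | df$well_row < 1 | df$well_row > 16 |
             df$well_row != as.integer(df$well_row), path,
           "malformed well_row (must be integer 1-16)")
  failRows(is.na(df$well_col) | df$well_col < 1 | df$well_col > 24 |
             df$well_col != as.integer(df$well_col), path,
           "malformed well_col (must be integer 1-24)")
  failRows(df$drug == "DMSO" & df$stimulus != "none", path,
           "DMSO control wells must have stimulus 'none'")
  df$well_row <- as.integer(df$well_row)
  df$well_col <- as.integer(df$well_col)
  screenLog("info", sprintf("read %d wells from %s", nrow(df), path))
  df
}

#' Write tabular screen artifacts with a JSON run-metadata sidecar
#'
#' All writers emit UTF-8, tab-delimited files with "NA" for missing values,
#' plus `<path>.json` recording the package version, timestamp and any
#' parameters passed, so every result table is self-describing.
#'
#' @param df data.frame to write.
#' @param path output TSV path.
#' @param meta named list of run parameters for the sidecar (e.g. seed).
#' @param rowNames write row names as a leading `sample_id` column.
#' @return `path`, invisibly.
#' @export
writeScreenTable <- function(df, path, meta = list(), rowNames = FALSE) {
  if (rowNames) {
    df <- data.frame(sample_id = rownames(df), df, check.names = FALSE,
                     stringsAsFactors = FALSE)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  sidecar <- c(list(
    package = "DrugStimScreen",
    version = as.character(utils::packageVersion("DrugStimScreen")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    rows = nrow(df)
  ), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname readWells
#' @param wells data.frame of well records.
#' @param meta named list for the JSON sidecar.
#' @export
writeWells <- function(wells, path, meta = list()) {
  writeScreenTable(wells[, WELL_COLUMNS], path, meta)
}

#' Read a binary genetic feature matrix
#'
#' @param path TSV whose first column is `sample_id`, remaining columns are
#'   features with values 0, 1 or NA.
#' @return samples x features integer matrix (0/1/NA) with sample_id row
#'   names; feature names preserved.
#' @seealso [writeGeneticMatrix()]
#' @export
readGeneticMatrix <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "NA", check.names = FALSE)
  if (names(df)[1L] != "sample_id")
    stopf("%s: first column must be 'sample_id'", path)
  dup <- duplicated(df$sample_id)
  failRows(dup, path, "duplicate sample_id")
  m <- as.matrix(df[, -1L, drop = FALSE])
  bad <- !is.na(m) & !(m %in% c(0, 1))
  if (any(bad)) {
    rows <- unique(which(bad, arr.ind = TRUE)[, 1L])
    stopf("%s: values outside {0, 1, NA} in row(s) %s", path,
          paste(head(rows, 5L), collapse = ", "))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample_id
  m
}

#' @rdname readGeneticMatrix
#' @param genetics samples x features matrix with sample ids as row names.
#' @param meta named list for the JSON sidecar.
#' @export
writeGeneticMatrix <- function(genetics, path, meta = list()) {
  writeScreenTable(as.data.frame(genetics, check.names = FALSE), path,
                   meta, rowNames = TRUE)
}

#' Read a sample annotation table
#'
#' @param path TSV with at least `sample_id`; recognised columns include
#'   IGHV (M/U), methylation (LP/IP/HP), cluster, sex, pretreated,
#'   doubling_time_days, time, event.
#' @return validated data.frame.
#' @export
readAnnotation <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "NA", check.names = FALSE)
  if (!"sample_id" %in% names(df))
    stopf("%s: column 'sample_id' is required", path)
  failRows(duplicated(df$sample_id), path, "duplicate sample_id")
  if ("IGHV" %in% names(df))
    failRows(!is.na(df$IGHV) & !df$IGHV %in% c("M", "U"), path,
             "IGHV must be 'M', 'U' or NA")
  if ("methylation" %in% names(df))
    failRows(!is.na(df$methylation) & !df$methylation %in% c("LP", "IP", "HP"),
             path, "methylation must be 'LP', 'IP', 'HP' or NA")
  if ("doubling_time_days" %in% names(df))
    failRows(!is.na(df$doubling_time_days) & df$doubling_time_days <= 0,
             path, "doubling_time_days must be > 0")
  df
}

#' @rdname readAnnotation
#' @param annotation data.frame with a `sample_id` column.
#' @param meta named list for the JSON sidecar.
#' @export
writeAnnotation <- function(annotation, path, meta = list()) {
  writeScreenTable(annotation, path, meta)
}

#' Read right-censored time-to-event records
#'
#' @param path TSV with columns sample_id, time (days > 0), event (0/1);
#'   further columns are kept as covariates.
#' @return validated data.frame.
#' @export
readSurvival <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "NA", check.names = FALSE)
  df <- resolveColumns(df, c("sample_id", "time", "event"), NULL, path)
  failRows(!is.finite(df$time) | df$time <= 0, path, "time must be > 0")
  failRows(!df$event %in% c(0L, 1L), path, "event must be 0 or 1")
  df
}

#' @rdname readSurvival
#' @param survival data.frame with sample_id, time, event.
#' @param meta named list for the JSON sidecar.
#' @export
writeSurvival <- function(survival, path, meta = list()) {
  writeScreenTable(survival, path, meta)
}

#' Read a nested key-value configuration file
#'
#' YAML-formatted configuration driving all pipeline stages; command-line
#' flags of the bundled CLI script override values read here. A
#' `column_map` section, if present, is passed to [readWells()] so
#' externally deposited tables with different headers can be consumed.
#'
#' @param path YAML file.
#' @return named list.
#' @export
readScreenConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("reading config files requires the 'yaml' package")
  yaml::read_yaml(path)
}
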