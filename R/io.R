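#' Write a table as CSV with a units comment line
#'
#' Writes a data.frame as plain CSV preceded by a \code{# units:} comment
#' line (e.g. \code{# units: temp_C=degC,ch4_nM=nmol/L}) so files stay
#' self-describing while remaining spreadsheet-readable.
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param units optional named character vector mapping column names to
#'   unit strings.
#' @return \code{path}, invisibly.
#' @export
write_units_csv <- function(x, path, units = NULL) {
  stopifnot(is.data.frame(x))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(units)) {
    bad <- setdiff(names(units), names(x))
    if (length(bad) > 0) stop("units given for absent columns: ",
                              paste(bad, collapse = ", "), call. = FALSE)
    writeLines(paste0("# units: ",
                      paste(names(units), units, sep = "=", collapse = ",")),
               con)
  }
  write.csv(x, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a units-annotated CSV with schema validation
#'
#' Reads a CSV written by [write_units_csv()] (the \code{# units:} comment
#' line, if present, is parsed into an attribute). Required columns and
#' column types are validated with errors naming the first offending
#' column or cell.
#'
#' @param path input path.
#' @param required character vector of required column names.
#' @param numeric_cols columns that must parse as finite numerics.
#' @return data.frame with attribute \code{units} (named character vector
#'   or NULL).
#' @export
read_units_csv <- function(path, required = character(),
                           numeric_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  units <- NULL
  if (startsWith(first, "# units:")) {
    spec <- strsplit(sub("^# units:\\s*", "", first), ",")[[1]]
    kv <- strsplit(spec, "=")
    units <- vapply(kv, `[`, character(1), 2)
    names(units) <- vapply(kv, `[`, character(1), 1)
  }
  x <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), " in ", path, call. = FALSE)
  }
  for (col in intersect(numeric_cols, names(x))) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(!is.finite(v) & !is.na(x[[col]]))
    if (length(bad) > 0) {
      stop("column '", col, "' has unparsable value '",
           x[[col]][bad[1]], "' at data row ", bad[1], call. = FALSE)
    }
    x[[col]] <- v
  }
  attr(x, "units") <- units
  x
}

#' Run the survey-to-flux pipeline
#'
#' Chains the field stages end to end: per-record percent saturation from
#' the survey table, then the three-scenario sea-air flux bounds against a
#' wind record. This is the programmatic equivalent of running the survey
#' analysis scripts in sequence.
#'
#' @param survey data.frame with \code{site}, \code{temp_C},
#'   \code{salinity}, \code{ch4_nM} (e.g. from [generate_survey()] or
#'   [read_units_csv()]).
#' @param wind numeric U10 vector or a data.frame with \code{u10_m_s}.
#' @param atm an [atmosphere_spec()].
#' @param mode gas-transfer-velocity mode.
#' @return list with \code{saturation} (survey plus saturation columns)
#'   and \code{bounds} (the three-row flux table); both carry provenance
#'   attributes (package version, atmosphere used).
#' @export
run_survey_pipeline <- function(survey, wind, atm = atmosphere_spec(),
                                mode = "as-printed") {
  need <- c("site", "temp_C", "salinity", "ch4_nM")
  stopifnot(is.data.frame(survey), all(need %in% names(survey)))
  if (is.data.frame(wind)) wind <- wind$u10_m_s
  sat <- percent_saturation(survey$ch4_nM * 1e-9, survey$temp_C,
                            survey$salinity, atm = atm)
  saturation <- cbind(survey,
                      c_eq_nM = sat$c_eq_mol_l * 1e9,
                      saturation_pct = sat$saturation_pct,
                      saturation_pct_sd = sat$saturation_pct_sd)
  bounds <- flux_bounds(saturation, wind, atm = atm, mode = mode)
  out <- list(saturation = saturation, bounds = bounds)
  attr(out, "package_version") <- as.character(packageVersion("sandch4"))
  attr(out, "atmosphere") <- atm
  out
}
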