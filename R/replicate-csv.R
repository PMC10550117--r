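#' Read a replicate summary CSV in one of the three supplementary dialects
#'
#' Three CSV layouts carry replicate-level summaries in this workflow:
#' \describe{
#'   \item{`s11`}{per-replicate flow statistics: `CRM`, `Replicate`, `MFI`,
#'     `SI`, `FoldChange`.}
#'   \item{`s12`}{bulk luminescence time series: `CRM`, `Replicate`, `Time`,
#'     `Luminescence`.}
#'   \item{`s13`}{flow medians underlying the bulk comparison: `CRM`,
#'     `Replicate`, `Time`, `ControlLucFluorescenceMedian`,
#'     `SampleLucFluorescenceMedian`.}
#' }
#' Column names are matched case-insensitively and ignoring punctuation and
#' spaces (`Fold Change`, `fold_change` and `FoldChange` are equivalent).
#' Unrecognized columns are preserved in the `"extra_columns"` attribute but
#' never interpreted.
#'
#' @param path path to a comma-separated file with a header row.
#' @param dialect one of `"s11"`, `"s12"`, `"s13"`.
#' @return a data.frame with normalized column names (`construct`,
#'   `replicate`, then the dialect's statistics: `mfi`/`si`/`fold_change`,
#'   `time_hours`/`luminescence`, or `time_hours`/`control_median`/
#'   `sample_median`), one row per data row.
#' @export
read_replicate_csv <- function(path, dialect = c("s11", "s12", "s13")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) lf_contract(sprintf("file does not exist: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")

  schema <- switch(dialect,
    s11 = c(CRM = "construct", Replicate = "replicate", MFI = "mfi",
            SI = "si", FoldChange = "fold_change"),
    s12 = c(CRM = "construct", Replicate = "replicate", Time = "time_hours",
            Luminescence = "luminescence"),
    s13 = c(CRM = "construct", Replicate = "replicate", Time = "time_hours",
            ControlLucFluorescenceMedian = "control_median",
            SampleLucFluorescenceMedian = "sample_median"))
  numeric_cols <- setdiff(unname(schema), "construct")

  norm <- function(x) tolower(gsub("[^A-Za-z0-9]", "", x))
  have <- norm(names(raw))
  idx <- match(norm(names(schema)), have)
  missing <- names(schema)[is.na(idx)]
  if (length(missing))
    lf_abort("schema", sprintf("dialect '%s' is missing mandatory column(s): %s",
                               dialect, paste(missing, collapse = ", ")))

  out <- stats::setNames(raw[idx], unname(schema))
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    nav <- which(is.na(v))
    if (length(nav))
      lf_abort("parse", sprintf(
        "non-numeric value in column '%s' at data row %d ('%s')",
        col, nav[1], out[[col]][nav[1]]))
    out[[col]] <- v
  }
  if (any(out$replicate < 1 | out$replicate != round(out$replicate)))
    lf_abort("parse", "Replicate must be a positive integer")
  out$replicate <- as.integer(out$replicate)

  extra <- raw[setdiff(seq_along(raw), idx)]
  if (ncol(extra) > 0) {
    lf_warn("extra_columns",
            sprintf("ignoring unrecognized column(s): %s",
                    paste(names(extra), collapse = ", ")))
    attr(out, "extra_columns") <- extra
  }
  out
}
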