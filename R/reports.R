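#' Replicate precision report
#'
#' For each construct, computes the mean, n-1 sample SD, and coefficient of
#' variation of each statistic (MFI, SI, fold change) across biological
#' replicates, plus the across-construct min and max CV per statistic — the
#' ranges by which the precision of the three statistics is compared.
#' Groups with fewer than two replicates are skipped with a warning.
#'
#' @param records a data.frame in the `s11` layout of
#'   [read_replicate_csv()]: columns `construct`, `replicate`, and one or
#'   more of `mfi`, `si`, `fold_change`.
#' @return an object of class `lucflow_precision_report`: `per_construct`
#'   (construct x statistic rows with `n`, `mean`, `sd`, `cv`) and `ranges`
#'   (per statistic: `min_cv`, `max_cv`).
#' @export
precision_report <- function(records) {
  stats_cols <- intersect(c("mfi", "si", "fold_change"), names(records))
  if (!all(c("construct", "replicate") %in% names(records)) || !length(stats_cols))
    lf_abort("schema",
             "records need 'construct', 'replicate' and at least one of mfi/si/fold_change")

  rows <- list()
  for (construct in unique(records$construct)) {
    grp <- records[records$construct == construct, , drop = FALSE]
    if (nrow(grp) < 2) {
      lf_warn("skipped_group", sprintf(
        "construct '%s' has %d replicate(s); CV needs >= 2 — skipped",
        construct, nrow(grp)))
      next
    }
    for (s in stats_cols) {
      v <- grp[[s]]
      rows[[length(rows) + 1]] <- data.frame(
        construct = construct, statistic = s, n = length(v),
        mean = mean(v), sd = stats::sd(v),
        cv = coefficient_of_variation(v),
        stringsAsFactors = FALSE)
    }
  }
  per_construct <- if (length(rows)) do.call(rbind, rows) else
    data.frame(construct = character(), statistic = character(),
               n = integer(), mean = numeric(), sd = numeric(), cv = numeric())

  ranges <- do.call(rbind, lapply(stats_cols, function(s) {
    cv <- per_construct$cv[per_construct$statistic == s]
    data.frame(statistic = s,
               min_cv = if (length(cv)) min(cv) else NA_real_,
               max_cv = if (length(cv)) max(cv) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_construct = per_construct, ranges = ranges),
            class = "lucflow_precision_report")
}

#' @export
print.lucflow_precision_report <- function(x, ...) {
  cat("<PrecisionReport>\n")
  if (nrow(x$per_construct)) {
    print(transform(x$per_construct, mean = signif(mean, 4), sd = signif(sd, 4),
                    cv = round(cv, 1)), row.names = FALSE)
    cat("CV ranges (%):\n")
    print(transform(x$ranges, min_cv = round(min_cv, 1), max_cv = round(max_cv, 1)),
          row.names = FALSE)
  } else cat("(no groups with >= 2 replicates)\n")
  invisible(x)
}

#' Agreement between flow and bulk fold changes
#'
#' Converts bulk luminescence to fold changes relative to the mean
#' luminescence of the undifferentiated reference (default the `Promoter`
#' construct at -48 h), pairs them with flow fold changes by (construct,
#' time), and returns the squared Pearson correlation across the matched
#' points. By default replicates are averaged before correlating (one point
#' per construct x time); set `replicate_level = TRUE` to pair individual
#' replicates instead.
#'
#' @param bulk data.frame in the `s12` layout of [read_replicate_csv()]:
#'   `construct`, `replicate`, `time_hours`, `luminescence`.
#' @param flow data.frame of flow fold changes with columns `construct`,
#'   `time_hours`, `fold_change` (and `replicate` if pairing at replicate
#'   level).
#' @param reference_construct,reference_time the bulk reference group
#'   (fold change 1).
#' @param replicate_level pair replicate-by-replicate instead of by group
#'   means.
#' @return `r_squared` (scalar in `[0, 1]`) with the matched points in the
#'   `"points"` attribute (`construct`, `time_hours`, `bulk_fold`,
#'   `flow_fold`).
#' @export
compare_to_bulk <- function(bulk, flow,
                            reference_construct = "Promoter",
                            reference_time = -48,
                            replicate_level = FALSE) {
  ref <- bulk$construct == reference_construct & bulk$time_hours == reference_time
  if (!any(ref))
    lf_contract(sprintf("bulk reference group (%s, %g h) not found",
                        reference_construct, reference_time))
  ref_lum <- mean(bulk$luminescence[ref])
  if (ref_lum == 0) lf_contract("bulk reference luminescence is zero")
  bulk$bulk_fold <- bulk$luminescence / ref_lum

  key_cols <- if (replicate_level) c("construct", "time_hours", "replicate")
              else c("construct", "time_hours")
  agg <- function(df, value) {
    stats::aggregate(df[[value]], df[key_cols], mean) |>
      stats::setNames(c(key_cols, value))
  }
  b <- agg(bulk, "bulk_fold")
  f <- agg(transform(flow, flow_fold = fold_change), "flow_fold")
  pts <- merge(b, f, by = key_cols)
  if (nrow(pts) < 3)
    lf_contract(sprintf("need >= 3 matched (construct, time) points, got %d",
                        nrow(pts)))
  if (stats::var(pts$bulk_fold) == 0 || stats::var(pts$flow_fold) == 0)
    lf_abort("undefined_correlation",
             "one method's fold changes have zero variance across matched points")
  r2 <- stats::cor(pts$bulk_fold, pts$flow_fold)^2
  attr(r2, "points") <- pts
  r2
}

#' Recompute the replicate-precision comparison from an s11-dialect CSV
#'
#' Reads the per-replicate MFI / SI / fold-change table and produces the
#' [precision_report()] whose CV ranges quantify how much the internal
#' control (SI) and the fold-change normalization improve precision over
#' raw MFI.
#'
#' @param s11_path path to an s11-dialect CSV.
#' @return a `lucflow_precision_report`.
#' @export
reproduce_fig4 <- function(s11_path) {
  precision_report(read_replicate_csv(s11_path, "s11"))
}

#' Recompute the flow-vs-bulk comparison from s12/s13-dialect CSVs
#'
#' Bulk fold changes come from the s12 luminescence table (relative to the
#' mean reference luminescence); flow fold changes are computed from the
#' s13 per-tube medians by scheme A, using the mean reference-tube medians
#' as the denominator. Returns the per-point table (with the flow/bulk
#' ratio, the sensitivity comparison) and the squared correlation between
#' methods.
#'
#' @param s12_path,s13_path paths to s12/s13-dialect CSVs.
#' @param reference_construct,reference_time the undifferentiated reference
#'   group.
#' @return list with `table` (construct, time_hours, bulk_fold, flow_fold,
#'   flow_bulk_ratio) and `r_squared`.
#' @export
reproduce_fig5 <- function(s12_path, s13_path,
                           reference_construct = "Promoter",
                           reference_time = -48) {
  bulk <- read_replicate_csv(s12_path, "s12")
  flow <- read_replicate_csv(s13_path, "s13")

  only_bulk <- setdiff(unique(bulk$construct), unique(flow$construct))
  only_flow <- setdiff(unique(flow$construct), unique(bulk$construct))
  if (length(only_bulk) || length(only_flow))
    lf_contract(sprintf(
      "construct labels do not match between files (bulk only: %s; flow only: %s)",
      paste(only_bulk, collapse = ", ") %e% "none",
      paste(only_flow, collapse = ", ") %e% "none"))

  ref <- flow$construct == reference_construct & flow$time_hours == reference_time
  if (!any(ref))
    lf_contract(sprintf("flow reference group (%s, %g h) not found",
                        reference_construct, reference_time))
  f_sample1 <- mean(flow$sample_median[ref])
  f_control1 <- mean(flow$control_median[ref])
  flow$fold_change <- vapply(seq_len(nrow(flow)), function(i) {
    fold_change_scheme_A(f_sample1, f_control1,
                         flow$sample_median[i], flow$control_median[i],
                         reference_tube_id = sprintf("%s_%gh", reference_construct,
                                                     reference_time))$L_sample
  }, numeric(1))

  r2 <- compare_to_bulk(bulk, flow,
                        reference_construct = reference_construct,
                        reference_time = reference_time)
  tab <- attr(r2, "points")
  tab$flow_bulk_ratio <- tab$flow_fold / tab$bulk_fold
  list(table = tab[order(tab$construct, tab$time_hours), ],
       r_squared = as.numeric(r2))
}

`%e%` <- function(a, b) if (nzchar(a)) a else b
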