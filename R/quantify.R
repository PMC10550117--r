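#' Median fluorescence intensity
#'
#' The statistical median of a gated subpopulation's fluorescence values;
#' for even counts, the mean of the two central order statistics.
#'
#' @param values numeric vector, at least one finite value.
#' @return the median.
#' @export
median_fluorescence <- function(values) {
  if (length(values) == 0) lf_contract("median of an empty vector is undefined")
  if (!all(is.finite(values))) lf_contract("values must be finite")
  stats::median(values)
}

#' 84th percentile with linear interpolation
#'
#' The 84th percentile of a subpopulation's fluorescence, linearly
#' interpolated between the closest order statistics (the rule of
#' [stats::quantile()] type 7: at position `1 + 0.84 * (n - 1)` in the
#' sorted sample). For a Gaussian, `p84 - median` is one standard
#' deviation, which is what the separation index's 0.995 constant assumes.
#'
#' @param values numeric vector, at least two finite values.
#' @return the 84th percentile.
#' @export
percentile_84 <- function(values) {
  if (length(values) < 2)
    lf_contract("84th percentile needs at least two values")
  if (!all(is.finite(values))) lf_contract("values must be finite")
  unname(stats::quantile(values, probs = 0.84, type = 7))
}

#' Separation index
#'
#' A robust effect size between a sample and a negative (Luc-) reference
#' population:
#' \deqn{SI = 0.995 (\mu_{sample} - \mu_{neg}) / (p84_{neg} - \mu_{neg})}
#' where the \eqn{\mu} are medians and \eqn{p84_{neg}} the negative
#' population's 84th percentile, so the denominator is a robust one-sigma
#' spread of the negative population. Invariant under scaling all three
#' arguments; sign follows the numerator.
#'
#' @param mu_sample median fluorescence of the sample population.
#' @param mu_puer median fluorescence of the negative (Luc-) population.
#' @param p84_puer 84th percentile of the negative population; must exceed
#'   `mu_puer`.
#' @return the separation index.
#' @export
separation_index <- function(mu_sample, mu_puer, p84_puer) {
  if (!all(is.finite(c(mu_sample, mu_puer, p84_puer))))
    lf_contract("separation index arguments must be finite")
  if (p84_puer <= mu_puer)
    lf_abort("degenerate_spread", sprintf(
      "negative population has no spread above its median (p84 = %g <= median = %g)",
      p84_puer, mu_puer))
  0.995 * (mu_sample - mu_puer) / (p84_puer - mu_puer)
}

#' Fold change, scheme A (Luc-negative spike)
#'
#' Each tube is spiked with Luc- (PUER) internal-control cells, which carry
#' only background staining, so within-tube background subtraction is the
#' difference between the sample and spike medians. The fold change of a
#' sample tube relative to the undifferentiated-Promoter reference tube is
#' the ratio of background-subtracted signals:
#' \deqn{L = (f_{sample2} - f_{control2}) / (f_{sample1} - f_{control1})}
#' with tube 1 the reference and tube 2 the sample. Additive per-tube
#' staining shifts cancel exactly within each difference. A sample signal
#' below its own spike yields a negative fold change that is flagged and
#' returned, never clipped (silent clipping would bias low-expression
#' estimates).
#'
#' @param f_sample1,f_control1 median Luciferase fluorescence of the CFSE-
#'   sample and CFSE+ spike populations of the reference tube.
#' @param f_sample2,f_control2 the same for the sample tube.
#' @param reference_tube_id optional provenance label for the reference.
#' @return an object of class `lucflow_fold_change`: `L_sample`, `scheme`
#'   (`"A_puer_spike"`), `b_sample` (`NA`), `negative` flag,
#'   `reference_tube_id`.
#' @export
fold_change_scheme_A <- function(f_sample1, f_control1, f_sample2, f_control2,
                                 reference_tube_id = NA_character_) {
  args <- c(f_sample1, f_control1, f_sample2, f_control2)
  if (!all(is.finite(args))) lf_contract("fold-change inputs must be finite")
  if (f_sample1 <= f_control1)
    lf_abort("reference_background", sprintf(
      "reference tube has no signal above its spike (f_sample1 = %g <= f_control1 = %g)",
      f_sample1, f_control1))
  L <- (f_sample2 - f_control2) / (f_sample1 - f_control1)
  negative <- f_sample2 < f_control2
  if (negative)
    lf_warn("negative_signal", sprintf(
      "sample signal below spike background (f_sample2 = %g < f_control2 = %g); fold change %g flagged, not clipped",
      f_sample2, f_control2, L))
  fold_change_result(L, "A_puer_spike", NA_real_, negative, reference_tube_id)
}

#' Fold change, scheme B (reporter-positive spike)
#'
#' Each tube (including a Luc- PUER background tube) is spiked with
#' undifferentiated Promoter cells, which express the reporter, so the fold
#' change relative to the Promoter reference is formed within the sample
#' tube while the background is estimated from the PUER tube. With
#' \eqn{f_{sample}} and \eqn{f^s_{sample}} the sample tube's CFSE- and
#' CFSE+ medians and \eqn{f_{PUER}}, \eqn{f^s_{PUER}} those of the PUER
#' tube, the sample-tube background is
#' \deqn{b_{sample} = f_{PUER} f^s_{sample} / f^s_{PUER}}
#' and the fold change
#' \deqn{L = (f_{sample} - b_{sample}) / (f^s_{sample} - b_{sample}).}
#' Multiplicative per-tube staining factors cancel exactly: the sample
#' tube's factor scales \eqn{f_{sample}}, \eqn{f^s_{sample}} and (through
#' \eqn{f^s_{sample}}) \eqn{b_{sample}} alike, and the PUER tube's factor
#' cancels inside \eqn{f_{PUER}/f^s_{PUER}}.
#'
#' @param f_sample,f_sample_s CFSE- sample and CFSE+ spike medians of the
#'   sample tube.
#' @param f_puer,f_puer_s CFSE- (PUER) and CFSE+ spike medians of the
#'   background tube.
#' @param reference_tube_id optional provenance label for the background
#'   tube.
#' @return an object of class `lucflow_fold_change`: `L_sample`, `scheme`
#'   (`"B_promoter_spike"`), estimated `b_sample`, `negative` flag,
#'   `reference_tube_id`.
#' @export
fold_change_scheme_B <- function(f_sample, f_sample_s, f_puer, f_puer_s,
                                 reference_tube_id = NA_character_) {
  args <- c(f_sample, f_sample_s, f_puer, f_puer_s)
  if (!all(is.finite(args))) lf_contract("fold-change inputs must be finite")
  if (f_puer_s <= 0)
    lf_contract(sprintf("PUER tube spike median must be positive (got %g)", f_puer_s))
  b_sample <- f_puer * f_sample_s / f_puer_s
  if (f_sample_s <= b_sample)
    lf_abort("degenerate_spike", sprintf(
      "spike signal does not exceed estimated background (f_sample_s = %g <= b_sample = %g)",
      f_sample_s, b_sample))
  L <- (f_sample - b_sample) / (f_sample_s - b_sample)
  negative <- f_sample < b_sample
  if (negative)
    lf_warn("negative_signal", sprintf(
      "sample signal below estimated background (f_sample = %g < b_sample = %g); fold change %g flagged, not clipped",
      f_sample, b_sample, L))
  fold_change_result(L, "B_promoter_spike", b_sample, negative, reference_tube_id)
}

fold_change_result <- function(L, scheme, b_sample, negative, reference_tube_id) {
  structure(list(L_sample = L, scheme = scheme, b_sample = b_sample,
                 negative = negative, reference_tube_id = reference_tube_id),
            class = "lucflow_fold_change")
}

#' @export
print.lucflow_fold_change <- function(x, ...) {
  cat(sprintf("<FoldChange scheme %s: L = %.4g%s%s>\n", x$scheme, x$L_sample,
              if (is.na(x$b_sample)) "" else sprintf(", b = %.4g", x$b_sample),
              if (isTRUE(x$negative)) " [negative signal flag]" else ""))
  invisible(x)
}

#' Coefficient of variation across replicates
#'
#' `100 * sd / mean` with the n-1 sample standard deviation, in percent.
#'
#' @param values numeric vector of at least two replicate values with
#'   nonzero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) lf_contract("CV needs at least two replicates")
  if (!all(is.finite(values))) lf_contract("values must be finite")
  m <- mean(values)
  if (m == 0) lf_contract("CV is undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Gate a tube and summarize its Luciferase medians
#'
#' Runs the full gating chain ([gate_tube()]) and computes, on the raw
#' Luciferase channel, the median and 84th percentile of the CFSE- sample
#' and CFSE+ spiked-control subpopulations. These are the per-tube `f`
#' statistics that the separation index and both fold-change schemes
#' consume. Counts and realized thresholds are recorded; subpopulations
#' smaller than `config$min_count` attach a low-count warning.
#'
#' @param table an [event_table()] with roles `fsc_a`, `fsc_h`, `ssc_a`,
#'   `luciferase` assigned (`viability`/`cfse` used if present).
#' @param config a [gate_config()].
#' @return an object of class `lucflow_tube_summary`: `tube_id`,
#'   `f_sample`, `f_control`, `p84_sample`, `p84_control`, `n_sample`,
#'   `n_control`, `thresholds`, `warnings`.
#' @export
analyze_tube <- function(table, config = gate_config()) {
  require_roles(table, c("fsc_a", "fsc_h", "ssc_a", "luciferase"))
  g <- gate_tube(table, config)
  luc <- channel_values(table, "luciferase")
  sample_vals <- luc[g$labels == "sample"]
  control_vals <- luc[g$labels == "control_spike"]

  warnings <- character()
  if (length(sample_vals) < config$min_count)
    warnings <- c(warnings, sprintf("low sample count: %d < %d",
                                    length(sample_vals), config$min_count))
  if (length(control_vals) > 0 && length(control_vals) < config$min_count)
    warnings <- c(warnings, sprintf("low control count: %d < %d",
                                    length(control_vals), config$min_count))
  for (w in warnings) lf_warn("low_count", sprintf("tube '%s': %s", table$tube_id, w))

  if (length(sample_vals) == 0)
    lf_contract(sprintf("tube '%s': no sample events survived gating", table$tube_id))

  structure(list(
    tube_id = table$tube_id,
    f_sample = median_fluorescence(sample_vals),
    f_control = if (length(control_vals)) median_fluorescence(control_vals) else NA_real_,
    p84_sample = if (length(sample_vals) >= 2) percentile_84(sample_vals) else NA_real_,
    p84_control = if (length(control_vals) >= 2) percentile_84(control_vals) else NA_real_,
    n_sample = length(sample_vals),
    n_control = length(control_vals),
    thresholds = g$thresholds_used,
    counts = g$counts,
    warnings = warnings
  ), class = "lucflow_tube_summary")
}

#' @export
print.lucflow_tube_summary <- function(x, ...) {
  cat(sprintf("<TubeSummary '%s': f_sample = %.4g (n = %d), f_control = %.4g (n = %d)>\n",
              x$tube_id, x$f_sample, x$n_sample, x$f_control, x$n_control))
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
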