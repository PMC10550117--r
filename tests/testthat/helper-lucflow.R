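# Independent oracles (sort/closed-form arithmetic only; no package code)
# and shared fixture builders.

oracle_median <- function(x) {
  s <- sort(x); n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_p84 <- function(x) {
  s <- sort(x); n <- length(s)
  h <- (n - 1) * 0.84 + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_cv <- function(x) {
  m <- sum(x) / length(x)
  100 * sqrt(sum((x - m)^2) / (length(x) - 1)) / m
}

oracle_r2 <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - n * mean(x) * mean(y)
  sxx <- sum(x^2) - n * mean(x)^2
  syy <- sum(y^2) - n * mean(y)^2
  sxy^2 / (sxx * syy)
}

# half-width of the 99% normal-approximation binomial interval for a
# fraction p estimated from n draws
binom_hw <- function(p, n, conf = 0.99) {
  stats::qnorm(1 - (1 - conf) / 2) * sqrt(p * (1 - p) / n)
}

tiny_event_table <- function(events, roles = NULL, tube_id = "fixture") {
  if (is.null(roles)) roles <- stats::setNames(colnames(events), colnames(events))
  event_table(events, channel_roles = roles, tube_id = tube_id)
}

# one-population table for exercising single gates with known values
scatter_table <- function(fsc_a, fsc_h = fsc_a, ssc_a = fsc_a,
                          tube_id = "fixture") {
  m <- cbind(`FSC-A` = fsc_a, `FSC-H` = fsc_h, `SSC-A` = ssc_a)
  event_table(m, channel_roles = c(fsc_a = "FSC-A", fsc_h = "FSC-H",
                                   ssc_a = "SSC-A"), tube_id = tube_id)
}

write_tmp_csv <- function(df, name = "fixture.csv") {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# scheme-A world: every tube spiked with Luc- PUER cells; per-tube additive
# staining shifts (the noise scheme A cancels)
scheme_A_specs <- function(rhos, n_events = 20000, shifts = NULL,
                           ref_expression = 1000) {
  n_tubes <- length(rhos) + 1
  if (is.null(shifts)) shifts <- rep(0, n_tubes)
  specs <- list(synthetic_tube_spec(
    n_events = n_events, expression_level = ref_expression,
    spike_expression_level = 0, tube_shift = shifts[1],
    tube_id = "Promoter_-48h", is_reference = TRUE))
  for (i in seq_along(rhos))
    specs[[i + 1]] <- synthetic_tube_spec(
      n_events = n_events, expression_level = ref_expression * rhos[i],
      spike_expression_level = 0, tube_shift = shifts[i + 1],
      tube_id = sprintf("sample_rho%g", rhos[i]))
  specs
}

# scheme-B world: every tube spiked with undifferentiated Promoter cells;
# a Luc- PUER tube provides the background estimate; per-tube multiplicative
# staining factors (the noise scheme B cancels)
scheme_B_specs <- function(rhos, n_events = 20000, scales = NULL,
                           promoter_expression = 1000) {
  n_tubes <- length(rhos) + 2
  if (is.null(scales)) scales <- rep(1, n_tubes)
  specs <- list(
    synthetic_tube_spec(
      n_events = n_events, expression_level = promoter_expression,
      spike_expression_level = promoter_expression, tube_scale = scales[1],
      tube_id = "Promoter_-48h", is_reference = TRUE),
    synthetic_tube_spec(
      n_events = n_events, expression_level = 0,
      spike_expression_level = promoter_expression, tube_scale = scales[2],
      tube_id = "PUER_bg"))
  for (i in seq_along(rhos))
    specs[[i + 2]] <- synthetic_tube_spec(
      n_events = n_events, expression_level = promoter_expression * rhos[i],
      spike_expression_level = promoter_expression, tube_scale = scales[i + 2],
      tube_id = sprintf("sample_rho%g", rhos[i]))
  specs
}

# analyze every tube of a simulated experiment, optionally routing each one
# through an FCS write/read round trip first
analyze_experiment <- function(exp, via_fcs = FALSE) {
  lapply(exp$tubes, function(tb) {
    table <- tb$table
    if (via_fcs) {
      path <- tempfile(fileext = ".fcs")
      on.exit(unlink(path))
      write_fcs(table, path)
      table <- read_fcs(path)
    }
    suppressWarnings(analyze_tube(table))
  })
}
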