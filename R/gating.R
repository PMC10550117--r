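#' Gate configuration
#'
#' Holds, per gate, the mode (`"auto"` density-valley threshold or `"manual"`
#' fixed threshold) and the numeric parameters each mode needs. The drawn
#' gate regions of a typical cytometry analysis are not portable numbers, so
#' every gate here supports both a config-driven manual threshold and an
#' automatic default, and the realized thresholds are always recorded in the
#' results for reproducibility.
#'
#' Manual thresholds: `fsc_min`/`ssc_min` are the debris floors (events below
#' either are debris); `singlet_ratio_max` is the largest admissible
#' FSC-A/FSC-H ratio; `viability_max` is the largest admissible viability-dye
#' value for a live call; `cfse_threshold` splits CFSE+ spiked controls from
#' CFSE- sample cells. They also serve as fallbacks when an auto gate finds
#' no density valley.
#'
#' Auto parameters: `bandwidth` is the kernel bandwidth rule for the
#' log-scale density (`"SJ"` Sheather-Jones plug-in, falling back to
#' `"nrd0"` when SJ is undefined); `min_separation` is the minimum distance
#' (natural-log units) between the two modes flanking a valley;
#' `min_peak_frac` discards density bumps below this fraction of the tallest
#' mode; `singlet_k` sets the auto singlet cut at
#' `median(ratio) + k * mad(ratio)`.
#'
#' @param debris_mode,singlet_mode,live_mode,spike_mode `"auto"` or
#'   `"manual"` per gate.
#' @param fsc_min,ssc_min,singlet_ratio_max,viability_max,cfse_threshold
#'   manual thresholds (all positive; `singlet_ratio_max > 1`).
#' @param singlet_k,bandwidth,min_separation,min_peak_frac auto-gate
#'   parameters (see above).
#' @param min_count minimum sample/control event count below which
#'   [analyze_tube()] attaches a low-count warning.
#' @return an object of class `lucflow_gate_config`.
#' @export
gate_config <- function(debris_mode = c("auto", "manual"),
                        singlet_mode = c("auto", "manual"),
                        live_mode = c("auto", "manual"),
                        spike_mode = c("auto", "manual"),
                        fsc_min = 15000, ssc_min = 5000,
                        singlet_ratio_max = 1.5,
                        viability_max = 800, cfse_threshold = 1000,
                        singlet_k = 3, bandwidth = "SJ",
                        min_separation = 0.5, min_peak_frac = 0.01,
                        min_count = 100) {
  cfg <- list(
    debris_mode = match.arg(debris_mode), singlet_mode = match.arg(singlet_mode),
    live_mode = match.arg(live_mode), spike_mode = match.arg(spike_mode),
    fsc_min = fsc_min, ssc_min = ssc_min,
    singlet_ratio_max = singlet_ratio_max,
    viability_max = viability_max, cfse_threshold = cfse_threshold,
    singlet_k = singlet_k, bandwidth = bandwidth,
    min_separation = min_separation, min_peak_frac = min_peak_frac,
    min_count = min_count)
  num <- c("fsc_min", "ssc_min", "singlet_ratio_max", "viability_max",
           "cfse_threshold", "singlet_k", "min_separation", "min_peak_frac",
           "min_count")
  for (f in num)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || !is.finite(cfg[[f]]) ||
        cfg[[f]] <= 0)
      lf_contract(sprintf("gate_config: '%s' must be a single positive number", f))
  if (cfg$singlet_ratio_max <= 1)
    lf_contract("gate_config: singlet_ratio_max must exceed 1")
  structure(cfg, class = "lucflow_gate_config")
}

#' Automatic density-valley threshold
#'
#' Estimates a kernel density of the natural-log values, locates the two
#' highest modes, and returns the exponentiated position of the minimum
#' density between them. Fluorescence distributions are approximately
#' log-normal per subpopulation, so valleys between subpopulations are found
#' on the log scale. Nonpositive values (possible in baseline-restored
#' exports) are clamped to the smallest positive observed value for the
#' density estimate only. Deterministic for fixed input and bandwidth rule;
#' ties between equal minima break toward the lower valley.
#'
#' @param values numeric vector, at least 100 values with positive spread.
#' @param bandwidth bandwidth rule, `"SJ"` (plug-in, default) or any rule
#'   accepted by [stats::density()]'s `bw`.
#' @param min_separation minimum log-distance between the two modes.
#' @param min_peak_frac ignore modes shorter than this fraction of the
#'   tallest mode.
#' @param side which secondary mode to threshold against: `"both"` pairs
#'   the two highest modes overall; `"below"`/`"above"` pair the tallest
#'   mode with the highest mode on that side of it. Gates pass the side
#'   their minority population is known to occupy (debris below the cells,
#'   dead and CFSE+ cells above), which keeps unrelated structure — e.g. a
#'   doublet shoulder in FSC-A — from capturing the valley.
#' @return the threshold on the linear scale (positive scalar).
#' @export
auto_threshold <- function(values, bandwidth = "SJ", min_separation = 0.5,
                           min_peak_frac = 0.01,
                           side = c("both", "below", "above")) {
  side <- match.arg(side)
  values <- values[is.finite(values)]
  if (length(values) < 100)
    lf_abort("insufficient_data",
             sprintf("auto threshold needs >= 100 values, got %d", length(values)))
  pos <- values[values > 0]
  if (length(pos) == 0)
    lf_contract("auto threshold needs at least one positive value")
  values[values <= 0] <- min(pos)
  lv <- log(values)
  if (stats::sd(lv) == 0)
    lf_abort("insufficient_data", "values have zero spread on the log scale")

  bw <- if (identical(bandwidth, "SJ")) {
    tryCatch(stats::bw.SJ(lv), error = function(e) stats::bw.nrd0(lv))
  } else bandwidth
  d <- stats::density(lv, bw = bw, n = 512)
  y <- d$y; x <- d$x
  k <- length(y)
  is_peak <- c(FALSE, y[2:(k - 1)] > y[1:(k - 2)] & y[2:(k - 1)] >= y[3:k], FALSE)
  peaks <- which(is_peak)
  peaks <- peaks[y[peaks] >= min_peak_frac * max(y)]
  if (length(peaks) < 2)
    lf_abort("no_valley", "log-scale density is unimodal; no valley to threshold at")

  main <- peaks[which.max(y[peaks])]
  others <- switch(side,
                   both = setdiff(peaks, main),
                   below = peaks[peaks < main],
                   above = peaks[peaks > main])
  # a genuine second subpopulation must sit at least min_separation away;
  # closer peaks are wiggle on the main mode's flank, not modes
  others <- others[abs(x[others] - x[main]) >= min_separation]
  if (!length(others))
    lf_abort("no_valley", sprintf(
      "no secondary mode at least %.3f log units %s the main mode",
      min_separation,
      switch(side, both = "away from", below = "below", above = "above")))
  second <- others[which.max(y[others])]
  lo <- min(main, second); hi <- max(main, second)
  between <- lo:hi
  valley <- between[which(y[between] == min(y[between]))[1]]
  exp(x[valley])
}

# run auto_threshold, falling back to `fallback` with a warning when the
# density is unimodal or the data too sparse
auto_or_fallback <- function(values, cfg, what, fallback, side = "both") {
  tryCatch(
    auto_threshold(values, bandwidth = cfg$bandwidth,
                   min_separation = cfg$min_separation,
                   min_peak_frac = cfg$min_peak_frac, side = side),
    lucflow_no_valley_error = function(e) {
      lf_warn("auto_fallback", sprintf(
        "%s: no density valley found (%s); falling back to threshold %g",
        what, conditionMessage(e), fallback))
      fallback
    },
    lucflow_insufficient_data_error = function(e) {
      lf_warn("auto_fallback", sprintf(
        "%s: insufficient data for auto threshold (%s); falling back to %g",
        what, conditionMessage(e), fallback))
      fallback
    })
}

#' Debris-exclusion gate
#'
#' Debris is excluded as events with low forward and side scatter: the keep
#' mask is true iff `FSC-A >= fsc_floor` and `SSC-A >= ssc_floor`. In auto
#' mode each floor is the density valley of the corresponding scatter
#' channel, falling back to the configured manual floor (with a warning)
#' when the scatter density is unimodal.
#'
#' @param table an [event_table()] with roles `fsc_a` and `ssc_a` assigned.
#' @param config a [gate_config()].
#' @return logical keep mask, length `n` events, with the realized floors in
#'   the `"thresholds"` attribute.
#' @export
gate_debris <- function(table, config = gate_config()) {
  require_roles(table, c("fsc_a", "ssc_a"))
  fsc <- channel_values(table, "fsc_a")
  ssc <- channel_values(table, "ssc_a")
  if (config$debris_mode == "manual") {
    thr <- c(fsc_min = config$fsc_min, ssc_min = config$ssc_min)
  } else {
    thr <- c(fsc_min = auto_or_fallback(fsc, config, "debris gate (FSC-A)",
                                        config$fsc_min, side = "below"),
             ssc_min = auto_or_fallback(ssc, config, "debris gate (SSC-A)",
                                        config$ssc_min, side = "below"))
  }
  mask <- fsc >= thr[["fsc_min"]] & ssc >= thr[["ssc_min"]]
  attr(mask, "thresholds") <- thr
  mask
}

#' Singlet-selection gate
#'
#' Cell clusters (doublets and larger) are excluded as events with high
#' FSC-A relative to FSC-H: the keep mask is true iff
#' `FSC-A / FSC-H <= r_max`. In auto mode `r_max` is the robust ratio fit
#' `median(FSC-A/FSC-H) + k * mad(FSC-A/FSC-H)` (a diagonal gate); in manual
#' mode it is `singlet_ratio_max`.
#'
#' @inheritParams gate_debris
#' @return logical keep mask with the realized `r_max` in `"thresholds"`.
#' @export
gate_singlets <- function(table, config = gate_config()) {
  require_roles(table, c("fsc_a", "fsc_h"))
  a <- channel_values(table, "fsc_a")
  h <- channel_values(table, "fsc_h")
  if (length(h) && all(h <= 0))
    lf_contract("all FSC-H values are nonpositive; ratio gate undefined")
  ratio <- ifelse(h > 0, a / h, Inf)
  if (config$singlet_mode == "manual") {
    r_max <- config$singlet_ratio_max
  } else {
    med <- stats::median(ratio[is.finite(ratio)])
    spread <- stats::mad(ratio[is.finite(ratio)])
    # tiny relative slack so a zero-spread (exactly proportional) population
    # is not split by floating-point ties at the median
    r_max <- (med + config$singlet_k * spread) * (1 + 1e-9)
  }
  mask <- ratio <= r_max
  attr(mask, "thresholds") <- c(singlet_ratio_max = r_max)
  mask
}

#' Dead-cell exclusion gate
#'
#' Dead cells are excluded as events with high viability-dye fluorescence
#' (amine-reactive dyes stain cells with compromised membranes brightly):
#' the keep mask is true iff the viability channel is at or below the
#' threshold. In auto mode the threshold is the log-scale density valley
#' between the live and dead modes; if the dye distribution is unimodal
#' (e.g. an all-live tube) the gate retains every event, records an infinite
#' threshold, and warns.
#'
#' @inheritParams gate_debris
#' @return logical keep mask with the realized cutoff in `"thresholds"`.
#' @export
gate_live <- function(table, config = gate_config()) {
  require_roles(table, "viability")
  v <- channel_values(table, "viability")
  if (config$live_mode == "manual") {
    thr <- config$viability_max
  } else {
    thr <- tryCatch(
      # live and dead are the two dominant modes on this axis (either may be
      # the taller one during differentiation), so pair the two highest modes
      auto_threshold(v, bandwidth = config$bandwidth,
                     min_separation = config$min_separation,
                     min_peak_frac = config$min_peak_frac, side = "both"),
      lucflow_no_valley_error = function(e) {
        lf_warn("auto_fallback",
                "live gate: viability density is unimodal; retaining all events")
        Inf
      },
      lucflow_insufficient_data_error = function(e) {
        lf_warn("auto_fallback",
                "live gate: too few events for auto threshold; retaining all events")
        Inf
      })
  }
  mask <- v <= thr
  attr(mask, "thresholds") <- c(viability_max = thr)
  mask
}

#' CFSE spike-in deconvolution
#'
#' Spiked control and sample cells are identified as CFSE+ and CFSE- events
#' respectively: the control mask is true iff CFSE exceeds the threshold and
#' the sample mask is its complement within the input. The input is expected
#' to be debris/doublet/dead-filtered already (use [gate_tube()] for the
#' full chain). A tube in which either side is empty cannot be normalized
#' and raises a degenerate-split error.
#'
#' @inheritParams gate_debris
#' @return list with logical `control` and `sample` masks (disjoint,
#'   covering the input) and the realized `threshold`.
#' @export
split_spike <- function(table, config = gate_config()) {
  require_roles(table, "cfse")
  cf <- channel_values(table, "cfse")
  if (config$spike_mode == "manual") {
    thr <- config$cfse_threshold
  } else {
    thr <- auto_or_fallback(cf, config, "spike split (CFSE)",
                            config$cfse_threshold, side = "above")
  }
  control <- cf > thr
  sample <- !control
  if (!any(control) || !any(sample))
    lf_abort("degenerate_split", sprintf(
      "CFSE split is degenerate (%d control / %d sample events at threshold %g); tube cannot be normalized",
      sum(control), sum(sample), thr))
  list(control = control, sample = sample, threshold = c(cfse_threshold = thr))
}

#' Full four-stage gating of one tube
#'
#' Applies the order-fixed chain debris exclusion -> singlet selection ->
#' dead-cell exclusion -> CFSE spike split, labelling every event as one of
#' `debris`, `doublet`, `dead`, `control_spike`, `sample`. Each stage only
#' removes events. When the table has no `cfse` role (an unspiked tube) the
#' live singlets are all labelled `sample`. When it has no `viability` role
#' the dead-cell stage is skipped (all retained) and this is recorded.
#'
#' @inheritParams gate_debris
#' @return an object of class `lucflow_gating_result`: `labels` (factor,
#'   one per event), `thresholds_used` (named numeric), `counts` (named
#'   integer per label, summing to the event count).
#' @export
gate_tube <- function(table, config = gate_config()) {
  n <- n_events(table)
  labels <- factor(rep("unassigned", n),
                   levels = c("debris", "doublet", "dead", "control_spike",
                              "sample", "unassigned"))
  thresholds <- numeric()

  keep <- rep(TRUE, n)
  m_debris <- gate_debris(table, config)
  thresholds <- c(thresholds, attr(m_debris, "thresholds"))
  labels[!m_debris] <- "debris"
  keep <- keep & m_debris

  m_singlet <- gate_singlets(table, config)
  thresholds <- c(thresholds, attr(m_singlet, "thresholds"))
  labels[keep & !m_singlet] <- "doublet"
  keep <- keep & m_singlet

  if ("viability" %in% names(table$channel_roles)) {
    sub <- subset_events(table, keep)
    m_live_sub <- gate_live(sub, config)
    thresholds <- c(thresholds, attr(m_live_sub, "thresholds"))
    m_live <- rep(TRUE, n)
    m_live[keep] <- m_live_sub
    labels[keep & !m_live] <- "dead"
    keep <- keep & m_live
  } else {
    thresholds <- c(thresholds, viability_max = NA_real_)
  }

  if ("cfse" %in% names(table$channel_roles)) {
    sub <- subset_events(table, keep)
    sp <- split_spike(sub, config)
    thresholds <- c(thresholds, sp$threshold)
    idx <- which(keep)
    labels[idx[sp$control]] <- "control_spike"
    labels[idx[sp$sample]] <- "sample"
  } else {
    thresholds <- c(thresholds, cfse_threshold = NA_real_)
    labels[keep] <- "sample"
  }

  counts <- table(labels)
  structure(list(labels = labels,
                 thresholds_used = thresholds,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 n = n),
            class = "lucflow_gating_result")
}

#' @export
print.lucflow_gating_result <- function(x, ...) {
  cat(sprintf("<GatingResult: %d events>\n", x$n))
  print(x$counts)
  cat("thresholds:\n")
  print(signif(x$thresholds_used, 5))
  invisible(x)
}

# internal: EventTable restricted to a mask (roles preserved)
subset_events <- function(table, mask) {
  event_table(table$events[mask, , drop = FALSE],
              channel_names = table$channel_names,
              channel_roles = table$channel_roles,
              tube_id = table$tube_id)
}
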