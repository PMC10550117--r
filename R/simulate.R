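# Ground-truth generator for reporter tubes. Each tube is a multinomial
# mixture of debris / doublets / dead cells / spiked controls / live sample
# cells with log-normal channel intensities per subpopulation. The key
# structural assumptions it encodes:
#   * dead cells show the Luciferase channel at the autofluorescence level
#     with its own spread, INDEPENDENT of reporter expression, and a
#     viability-dye level ~30-fold above live cells;
#   * spiked controls are CFSE-bright (~100-fold above unlabeled cells);
#   * doublets double FSC-A at matched FSC-H;
#   * debris sits low in both scatter channels;
#   * per-tube staining effects (multiplicative factor, additive shift)
#     apply to the fluorescence channels only, never to scatter.

#' Specification of one synthetic tube
#'
#' Generative parameters for [simulate_tube()]. The realized Luciferase
#' median of live sample cells is `autofluorescence_level +
#' expression_level` (and likewise for the spike), so `expression_level` is
#' the functional reporter signal that background subtraction recovers: a
#' Luc- (PUER) population is simply `expression_level = 0`. All
#' fluorescence levels are linear acquisition units.
#'
#' @param n_events number of events to draw.
#' @param frac_debris,frac_doublet,frac_dead,frac_spike subpopulation
#'   fractions, each in `[0, 1]`, summing to at most 1; the remainder is
#'   live sample cells. The default spike fraction (0.2) sits inside the
#'   10--25% range typical of spike-in protocols.
#' @param expression_level true reporter signal of live sample cells.
#' @param spike_expression_level true reporter signal of the spiked
#'   controls (0 for a Luc- spike).
#' @param autofluorescence_level Luciferase-channel level of dead and
#'   unstained cells (and the additive staining background of live cells).
#' @param log_sd named list of log-scale SDs per channel group:
#'   `scatter` (FSC), `ssc`, `viability`, `cfse`, `luciferase`.
#' @param tube_scale,tube_shift per-tube multiplicative factor and additive
#'   shift applied to all fluorescence channels (viability, CFSE,
#'   Luciferase) after the draws; scatter is unaffected.
#' @param seed integer seed; identical spec + seed reproduce the tube
#'   exactly.
#' @param tube_id tube label.
#' @param is_reference marks the reference tube inside
#'   [simulate_experiment()].
#' @param base named list of linear median levels: `fsc_h`, `ssc`,
#'   `viability` (live cells), `cfse` (unlabeled cells).
#' @param dead_dye_fold viability-dye fold elevation of dead over live
#'   cells.
#' @param spike_cfse_fold CFSE fold elevation of spiked over unlabeled
#'   cells.
#' @param singlet_slope,ratio_sd median and log-SD of the FSC-A/FSC-H
#'   singlet ratio.
#' @param debris_scatter_frac scatter attenuation of debris relative to
#'   cells.
#' @return an object of class `lucflow_tube_spec`.
#' @export
synthetic_tube_spec <- function(n_events = 20000,
                                frac_debris = 0.05, frac_doublet = 0.05,
                                frac_dead = 0.15, frac_spike = 0.2,
                                expression_level = 1000,
                                spike_expression_level = 0,
                                autofluorescence_level = 100,
                                log_sd = list(scatter = 0.18, ssc = 0.3,
                                              viability = 0.4, cfse = 0.45,
                                              luciferase = 0.5),
                                tube_scale = 1, tube_shift = 0,
                                seed = 1L, tube_id = "tube",
                                is_reference = FALSE,
                                base = list(fsc_h = 6e4, ssc = 3e4,
                                            viability = 80, cfse = 60),
                                dead_dye_fold = 30, spike_cfse_fold = 100,
                                singlet_slope = 1.05, ratio_sd = 0.03,
                                debris_scatter_frac = 0.08) {
  fr <- c(debris = frac_debris, doublet = frac_doublet, dead = frac_dead,
          spike = frac_spike)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    lf_contract("fractions must each lie in [0,1] and sum to at most 1")
  if (n_events < 1 || n_events != round(n_events))
    lf_contract("n_events must be a positive integer")
  if (autofluorescence_level <= 0)
    lf_contract("autofluorescence_level must be positive")
  if (expression_level < 0 || spike_expression_level < 0)
    lf_contract("expression levels must be non-negative")
  if (tube_scale <= 0) lf_contract("tube_scale must be positive")
  structure(list(
    n_events = as.integer(n_events), fractions = fr,
    expression_level = expression_level,
    spike_expression_level = spike_expression_level,
    autofluorescence_level = autofluorescence_level,
    log_sd = log_sd, tube_scale = tube_scale, tube_shift = tube_shift,
    seed = as.integer(seed), tube_id = tube_id, is_reference = is_reference,
    base = base, dead_dye_fold = dead_dye_fold,
    spike_cfse_fold = spike_cfse_fold, singlet_slope = singlet_slope,
    ratio_sd = ratio_sd, debris_scatter_frac = debris_scatter_frac
  ), class = "lucflow_tube_spec")
}

# evaluate `code` under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sim_channel_names <- c("FSC-A", "FSC-H", "SSC-A", "LiveDead-Violet-A",
                       "CFSE-A", "Luciferase-AF647-A")
sim_channel_roles <- c(fsc_a = "FSC-A", fsc_h = "FSC-H", ssc_a = "SSC-A",
                       viability = "LiveDead-Violet-A", cfse = "CFSE-A",
                       luciferase = "Luciferase-AF647-A")

#' Simulate one stained tube
#'
#' Draws subpopulation membership multinomially and per-channel log-normal
#' intensities as described in [synthetic_tube_spec()], applies the tube's
#' staining effect to the fluorescence channels, and returns the events
#' together with the realized ground truth. The per-channel noise draws are
#' shared across parameter settings at a fixed seed, so changing
#' `expression_level` changes only the populations that actually express
#' the reporter — dead-cell Luciferase values are bit-identical across
#' expression levels, encoding that dead cells carry no functional
#' reporter.
#'
#' @param spec a [synthetic_tube_spec()].
#' @return list with `table` (an [event_table()]) and `truth` (realized
#'   `counts` per subpopulation, per-event `labels`, sample-cell
#'   `viability` = live / (live + dead), and the spec's expression levels).
#' @export
simulate_tube <- function(spec) {
  stopifnot(inherits(spec, "lucflow_tube_spec"))
  with_seed(spec$seed, {
    n <- spec$n_events
    fr <- spec$fractions
    probs <- c(fr, live = 1 - sum(fr))
    counts <- stats::setNames(as.integer(drop(
      stats::rmultinom(1, n, probs))), names(probs))
    labels <- sample(rep(names(probs), counts))

    is_debris <- labels == "debris"
    is_doublet <- labels == "doublet"
    is_dead <- labels == "dead"
    is_spike <- labels == "spike"

    fsc_h_med <- rep(spec$base$fsc_h, n)
    fsc_h_med[is_debris] <- spec$base$fsc_h * spec$debris_scatter_frac
    fsc_h <- fsc_h_med * exp(stats::rnorm(n, 0, spec$log_sd$scatter))

    ratio <- spec$singlet_slope * exp(stats::rnorm(n, 0, spec$ratio_sd))
    ratio[is_doublet] <- 2 * ratio[is_doublet]
    fsc_a <- fsc_h * ratio

    ssc_med <- rep(spec$base$ssc, n)
    ssc_med[is_debris] <- spec$base$ssc * spec$debris_scatter_frac
    ssc <- ssc_med * exp(stats::rnorm(n, 0, spec$log_sd$ssc))

    via_med <- rep(spec$base$viability, n)
    via_med[is_dead] <- spec$base$viability * spec$dead_dye_fold
    viability <- via_med * exp(stats::rnorm(n, 0, spec$log_sd$viability))

    cfse_med <- rep(spec$base$cfse, n)
    cfse_med[is_spike] <- spec$base$cfse * spec$spike_cfse_fold
    cfse <- cfse_med * exp(stats::rnorm(n, 0, spec$log_sd$cfse))

    a <- spec$autofluorescence_level
    luc_med <- rep(a + spec$expression_level, n)
    luc_med[is_spike] <- a + spec$spike_expression_level
    luc_med[is_dead] <- a                 # decoupled from expression
    luc_med[is_debris] <- a
    luc_med[is_doublet] <- 2 * (a + spec$expression_level)
    luciferase <- luc_med * exp(stats::rnorm(n, 0, spec$log_sd$luciferase))

    stain <- function(v) v * spec$tube_scale + spec$tube_shift
    events <- cbind(fsc_a, fsc_h, ssc, stain(viability), stain(cfse),
                    stain(luciferase))
    colnames(events) <- sim_channel_names

    table <- event_table(events, channel_roles = sim_channel_roles,
                         tube_id = spec$tube_id)
    truth <- list(
      counts = counts, labels = labels,
      viability = counts[["live"]] / (counts[["live"]] + counts[["dead"]]),
      expression_level = spec$expression_level,
      spike_expression_level = spec$spike_expression_level)
    list(table = table, truth = truth)
  })
}

#' Simulate an experiment of several tubes with a designated reference
#'
#' Generates each tube independently with a per-tube seed derived
#' deterministically from `master_seed` (substream `i` uses
#' `(master_seed * 10007 + i * 7919) mod (2^31 - 1)`), and records the true
#' fold change of every tube as the ratio of its `expression_level` to the
#' reference tube's. Exactly one spec must have `is_reference = TRUE`, and
#' the reference must express the reporter (otherwise the fold change is
#' undefined).
#'
#' @param specs list of [synthetic_tube_spec()] objects.
#' @param master_seed integer; when given, overrides the per-spec seeds
#'   with derived substream seeds so the whole experiment is reproducible
#'   from one number.
#' @return list with `tubes` (per tube: `table`, `truth`),
#'   `rho` (named true fold changes), `reference` (tube id).
#' @export
simulate_experiment <- function(specs, master_seed = NULL) {
  if (!length(specs) || !all(vapply(specs, inherits, logical(1), "lucflow_tube_spec")))
    lf_contract("specs must be a non-empty list of synthetic_tube_spec objects")
  ref_idx <- which(vapply(specs, function(s) isTRUE(s$is_reference), logical(1)))
  if (length(ref_idx) != 1)
    lf_contract(sprintf("exactly one reference tube required, found %d",
                        length(ref_idx)))
  if (specs[[ref_idx]]$expression_level <= 0)
    lf_contract("the reference tube must have positive expression_level")

  if (!is.null(master_seed)) {
    master_seed <- as.numeric(master_seed)
    for (i in seq_along(specs))
      specs[[i]]$seed <- as.integer((master_seed * 10007 + i * 7919) %% 2147483647)
  }
  tubes <- lapply(specs, simulate_tube)
  ids <- vapply(specs, `[[`, character(1), "tube_id")
  if (anyDuplicated(ids)) lf_contract("tube_ids must be unique")
  names(tubes) <- ids
  rho <- vapply(specs, function(s)
    s$expression_level / specs[[ref_idx]]$expression_level, numeric(1))
  names(rho) <- ids
  list(tubes = tubes, rho = rho, reference = ids[ref_idx])
}

#' Simulate a bulk luminescence measurement
#'
#' Only live cells contribute functional Luciferase to the lysate, so
#' luminescence is `expression_level * viability * n_cells` up to
#' multiplicative log-normal noise of the given CV (mean 1). The
#' protein-normalized readout divides by total cells — dead cells still
#' contribute protein — so the normalized bulk signal scales with
#' viability, which is exactly the bias a live-gated single-cell
#' measurement avoids.
#'
#' @param expression_level per-live-cell signal (positive).
#' @param viability live fraction, in `(0, 1]`.
#' @param n_cells total cells lysed (positive).
#' @param noise_cv CV of the multiplicative measurement noise (0 for the
#'   noise-free expectation).
#' @param seed optional seed for the noise draw.
#' @return list with `luminescence` and `protein_normalized`
#'   (= luminescence / n_cells).
#' @export
simulate_bulk <- function(expression_level, viability, n_cells,
                          noise_cv = 0, seed = NULL) {
  if (!is.finite(viability) || viability <= 0 || viability > 1)
    lf_contract("viability must lie in (0, 1]")
  if (expression_level <= 0 || n_cells <= 0 || noise_cv < 0)
    lf_contract("expression_level and n_cells must be positive, noise_cv >= 0")
  draw <- function() {
    if (noise_cv == 0) return(1)
    sdlog <- sqrt(log(1 + noise_cv^2))
    exp(stats::rnorm(1, -sdlog^2 / 2, sdlog))
  }
  eps <- if (is.null(seed)) draw() else with_seed(seed, draw())
  lum <- expression_level * viability * n_cells * eps
  list(luminescence = lum, protein_normalized = lum / n_cells)
}
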