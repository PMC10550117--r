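---
title: "Quantifying single-cell Luciferase reporter expression with lucflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell Luciferase reporter expression with lucflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Reporter assays read out the activity of promoters and enhancers (cis-regulatory
modules, CRMs) through the expression of an inert reporter — here firefly
Luciferase, detected per cell by intracellular immunostaining and flow
cytometry. Two systematic problems dominate the error budget of such assays:

1. **Dead cells.** Dying cells autofluoresce in the reporter channel but carry
   no functional Luciferase protein. A bulk luminescence assay lyses everything,
   so its signal scales with the live fraction: at viability $v$ the
   protein-normalized bulk estimate of a fold change $\rho$ is approximately
   $v\rho$. A single-cell assay that excludes dead cells with a fixable
   viability dye is unbiased in $v$. During myeloid differentiation viability
   can drop to ~50%, making this a 2-fold error.
2. **Tube-to-tube staining variation.** Fixation, permeabilization, blocking,
   antibody staining and instrument drift make the raw median fluorescence
   intensity (MFI) of a tube highly variable across biological replicates
   (CVs of 30% or far more are typical). Spiking every tube with internal
   control cells — labeled with CFSE so they can be separated during
   acquisition — exposes sample and control to identical conditions, so
   statistics formed as within-tube contrasts cancel tube-level effects.

`lucflow` implements the full computational chain: FCS 3.0/3.1 I/O, the
four-stage gating scheme, the summary statistics, replicate-precision and
bulk-agreement reports, and a ground-truth simulator used to validate every
stage.

## Gating

Gates are applied in a fixed order, each stage only removing events:

1. **Debris**: events with low FSC-A *and* low SSC-A are removed
   (two independent floors, i.e. a rectangle gate; the lower-left corner of a
   drawn polygon would differ only marginally for well-separated debris).
2. **Singlets**: events with high FSC-A relative to FSC-H are removed via the
   ratio cut $\mathrm{FSC\text{-}A}/\mathrm{FSC\text{-}H} \le r_{\max}$.
3. **Live cells**: events with high LIVE/DEAD-dye fluorescence are removed.
4. **Spike split**: CFSE$^+$ events are the spiked internal control, CFSE$^-$
   events the sample.

Numeric gate positions are instrument- and day-specific and are not portable,
so every gate supports a manual threshold *and* an automatic default, and the
realized thresholds are always recorded in the output.

**Automatic thresholds** use a kernel density estimate of the natural-log
values (fluorescence is approximately log-normal per subpopulation) with the
Sheather–Jones plug-in bandwidth (falling back to Silverman's rule when SJ is
undefined). The threshold is the density minimum between the main mode and the
tallest *admissible* secondary mode, where admissible means: height at least
`min_peak_frac` (default 1%) of the tallest mode, and at least `min_separation`
(default 0.5 log units) away from it — closer bumps are kernel wiggle on a
mode's flank, not subpopulations. Each gate also declares which side of the
main mode its minority population can occupy: debris lies *below* the cell
mode, CFSE$^+$ spikes (≤ 25% of events) lie *above* the CFSE$^-$ mode, while
live and dead cells may each be the majority during differentiation, so the
viability gate pairs the two highest modes regardless of side. This side
constraint is what keeps, e.g., the doublet shoulder in FSC-A from capturing
the debris valley. Non-positive values (possible in baseline-restored exports)
are clamped to the smallest positive observed value *inside the density
estimate only*; raw values are never altered. Failure to find a valley is
never fatal at the gate level: the debris and spike gates fall back to the
configured manual threshold with a warning, and the live gate retains all
events (threshold $+\infty$, recorded).

The automatic singlet cut is $r_{\max} = \tilde r + k\,\mathrm{mad}(r)$ with
$\tilde r$ the median ratio and $k = 3$, times $(1 + 10^{-9})$ so an exactly
proportional population is not split by floating-point ties.

No spillover compensation is applied anywhere; medians are computed on raw
linear channel values.

## Statistics

With $f$ denoting the median Luciferase fluorescence of a gated subpopulation:

* **MFI** — the raw sample median; sensitive to all tube effects.
* **Separation index** against a Luc$^-$ negative population:
  $\mathrm{SI} = 0.995\,(\mu_{\text{sample}} - \mu_{\text{neg}}) /
  (p84_{\text{neg}} - \mu_{\text{neg}})$. The denominator is a robust
  one-sigma spread of the negative population (for a Gaussian,
  $p84 - \text{median} \approx \sigma$, and $0.995$ is the matching
  calibration constant), which is why the 84th percentile uses linear
  interpolation between order statistics (type-7): any other interpolation
  rule would silently recalibrate the constant. SI is invariant to scaling
  (and shifting) all three arguments.
* **Fold change, scheme A** (Luc$^-$ PUER spike in every tube):
  $L = (f_{s2} - f_{c2}) / (f_{s1} - f_{c1})$, tube 1 being the
  undifferentiated-Promoter reference. Additive per-tube shifts cancel
  exactly inside each difference.
* **Fold change, scheme B** (undifferentiated-Promoter spike in every tube,
  plus one Luc$^-$ PUER tube to estimate background):
  $b_s = f_{\mathrm{PUER}} f^s_{\text{sample}} / f^s_{\mathrm{PUER}}$ and
  $L = (f_{\text{sample}} - b_s)/(f^s_{\text{sample}} - b_s)$.
  Multiplicative per-tube factors cancel exactly in both tubes.

Negative background-subtracted signals are *flagged and returned*, never
clipped to zero — clipping would bias low-expression fold changes upward.
Replicate precision is summarized as $\mathrm{CV} = 100\,s/\bar x$ with the
$n-1$ sample SD (the denominator convention is a documented choice). Bulk
agreement is the squared Pearson correlation between per-(construct, time)
mean fold changes of the two methods; a replicate-level pairing is available
as an option, mean-level is the default and is logged.

## The simulator and what a green test establishes

`simulate_tube()` draws a multinomial mixture
(debris / doublets / dead / spike / live sample) with log-normal channel
intensities per subpopulation. Defaults (chosen once, as plausible values for
a myeloid line on a BD-style analyzer, and not revisited): 5% debris, 5%
doublets, 15% dead, 20% spike (inside the 10–25% protocol range), FSC-H
median $6\times10^4$ (log-SD 0.18), SSC $3\times10^4$ (0.3), viability dye 80
for live cells with a 30-fold elevation in dead cells (0.4), CFSE 60 with a
100-fold elevation in spiked cells (0.45), Luciferase log-SD 0.5, singlet
ratio 1.05 (log-SD 0.03), debris scatter attenuation 0.08.

Three structural decisions matter:

* The realized Luciferase median of live cells is
  `autofluorescence_level + expression_level` (default background 100). This
  makes `expression_level` exactly the functional signal that background
  subtraction recovers, so the ground-truth fold change
  $\rho = E_{\text{sample}}/E_{\text{ref}}$ is what both schemes estimate,
  and a Luc$^-$ population is simply `expression_level = 0`. (A stricter
  reading of the generator contract would require all levels strictly
  positive; that would make a PUER tube unrepresentable, so zero expression
  is allowed and only the autofluorescence floor must be positive.)
* Dead cells get the autofluorescence level with its own spread,
  *independent* of `expression_level` — the same RNG draws are used for every
  expression level at a fixed seed, so dead-cell values are bit-identical
  across expression settings. This encodes the observed phenomenon (dead
  cells carry no functional reporter) directly rather than modelling epitope
  loss mechanistically.
* Per-tube staining effects (`tube_scale`, `tube_shift`) apply to the
  fluorescence channels only; scatter is unaffected.

`simulate_bulk()` models lysate luminescence as
$E \cdot v \cdot n_{\text{cells}}$ with optional multiplicative log-normal
noise (mean 1), and a protein-normalized readout dividing by *total* cells —
dead cells contribute protein but no signal, so the normalized bulk value
scales with viability.

The simulator does **not** emulate spectral spillover, photon statistics,
CFSE dilution through division, cell-cycle structure, or correlated
scatter–fluorescence effects. A green recovery test therefore establishes the
correctness of the gating/normalization algebra under the stated mixture
model, not robustness to every instrument artifact.

## Validation worlds (what the acceptance tests run)

* **Formula oracles**: every statistic is checked against an independent
  sort-based or closed-form computation on ≥ 1000 randomized inputs, and the
  scheme A/B invariances (additive / multiplicative tube effects) are checked
  as exact identities.
* **Parameter recovery**: experiments with $\rho \in \{0.5, 1, 2, 5, 10\}$ at
  20,000 events/tube over 10 master seeds, each tube routed through an FCS
  write/read round trip, with additive tube shifts (log-normal, median 150)
  for scheme A and multiplicative factors (log-normal, CV 40%) for scheme B;
  the median recovered $L$ must land within 5% of $\rho$.
* **Dead-cell bias**: at $\rho = 4$ and viabilities 0.3–1.0, the flow
  estimate stays within 5% of $\rho$ while the noise-free bulk fold change
  equals $v\rho$ exactly.
* **Precision ordering**: four constructs × six replicates under
  multiplicative tube noise (CV 40%). Per replicate, a PUER-spiked tube
  yields MFI (raw, suffers the full tube factor) and the internal-control SI
  (tube factor cancels; residual CV is dominated by the sampling noise of the
  spike population's $p84 - \mu$ spread estimate), and a Promoter-spiked tube
  plus a PUER background tube yield the scheme-B fold change (all tube
  factors cancel; residual CV is median sampling noise only). The test
  asserts the resulting ordering of per-statistic mean CVs,
  $\mathrm{CV}(L) < \mathrm{CV}(\mathrm{SI}) < \mathrm{CV}(\mathrm{MFI})$.
  Both spiking schemes are simulated side by side because the SI needs a
  Luc$^-$ internal control while scheme B needs a reporter-positive spike;
  running both per replicate mirrors practice, where the two schemes perform
  equally well and either can be chosen per tube.
* **Supplementary-style recomputation**: the replicate-CSV dialects and the
  two report entry points are exercised on synthetic stand-in tables
  (hand-computable CVs; a paired flow/bulk time course with depressed
  viability at the dying timepoints, where the flow/bulk ratio must exceed 1
  at every such point and the two methods still correlate). The deposited
  supplementary files themselves are not redistributable with the package,
  so no numeric claim about them is made here.

## Numerical choices and degenerate inputs

* 84th percentile: type-7 linear interpolation, fixed (see above); requires
  ≥ 2 values.
* Median: mean of the central order statistics for even counts.
* CV: requires ≥ 2 replicates and nonzero mean; groups violating this are
  skipped with a warning, never silently dropped.
* Density thresholds: deterministic for fixed input; ties between equal
  valley minima break toward the lower value.
* Degenerate inputs raise classed conditions (`lucflow_*_error`) rather than
  returning sentinel values: empty CFSE side (`degenerate_split`), negative
  population spread (`degenerate_spread`), reference without signal
  (`reference_background`), spike at or below estimated background
  (`degenerate_spike`), zero-variance correlation (`undefined_correlation`).
* Batch runs (`run_timeseries()`) isolate per-tube failures as `failed` rows
  with messages; only a missing reference/background tube aborts the batch.
* FCS: versions 3.0/3.1, list mode, float/double/uniform-integer data, both
  byte orders; no analysis-segment interpretation, no FCS 2.0/3.2, no
  gating-ML. Values are stored as 32-bit floats on write (~7 significant
  digits preserved).

## Known limitations

* Automatic thresholds assume roughly log-normal, well-separated
  subpopulations; heavily skewed or overlapping mixtures should use manual
  thresholds (and the realized-threshold log makes any run auditable).
* The bulk model has no protein-assay dynamic-range saturation; it is the
  idealized linear model against which the viability bias is defined.
* The CSV dialects tolerate and surface unknown columns but never interpret
  them; a dialect whose mandatory columns are renamed beyond
  case/punctuation variants must be mapped by the caller.
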