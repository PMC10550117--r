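# lucflow

Single-cell quantification of Luciferase reporter expression from flow
cytometry, for labs measuring promoter/enhancer (CRM) activity with
immunostained Luciferase reporters instead of — or alongside — bulk
luminescence assays.

## Why

Two systematic errors dominate reporter quantification:

* **Dead cells** autofluoresce in the reporter channel but carry no
  functional Luciferase, so a bulk lysate assay underestimates expression in
  proportion to viability (at viability *v*, the protein-normalized bulk
  estimate of a true fold change ρ is ≈ *v*·ρ). Gating dead cells out with a
  fixable viability dye removes the bias.
* **Tube-to-tube staining variation** makes raw median fluorescence (MFI)
  highly variable across replicates. Spiking each tube with CFSE-labeled
  internal-control cells lets statistics be formed as within-tube contrasts
  that cancel tube effects.

`lucflow` implements the computational chain:

* FCS 3.0/3.1 list-mode read/write (float/double/integer, both byte orders),
  with pattern-based channel-role resolution;
* the four-stage gating scheme — debris (low FSC-A/SSC-A), singlets
  (FSC-A/FSC-H ratio), live cells (viability dye), CFSE⁺/CFSE⁻ spike split —
  each gate with a manual threshold and an automatic log-density-valley
  default, realized thresholds always recorded;
* the statistics: MFI; separation index
  `SI = 0.995 (μ_sample − μ_neg) / (p84_neg − μ_neg)`; fold change under
  **scheme A** (Luc⁻ spike): `L = (f_s2 − f_c2)/(f_s1 − f_c1)` — exact under
  additive tube shifts; and **scheme B** (reporter⁺ spike):
  `b = f_PUER · f^s_sample / f^s_PUER`, `L = (f_sample − b)/(f^s_sample − b)`
  — exact under multiplicative tube factors;
* replicate CV reports, flow-vs-bulk agreement (r²), batch time-series runs;
* a ground-truth simulator (mixture of debris/doublets/dead/spike/live with
  log-normal channels, reporter-independent dead-cell autofluorescence,
  per-tube staining effects) plus a matched bulk-luminescence model.

## Worked example

Simulate a reference tube (undifferentiated Promoter, expression 1000) and a
sample tube (CRM18, expression 5000 = true fold change 5, plus an additive
staining shift of 150), round-trip the sample through an FCS file, gate, and
quantify:

```r
library(lucflow)
specs <- list(
  synthetic_tube_spec(n_events = 20000, expression_level = 1000,
                      spike_expression_level = 0,
                      tube_id = "Promoter_-48h", is_reference = TRUE),
  synthetic_tube_spec(n_events = 20000, expression_level = 5000,
                      spike_expression_level = 0, tube_shift = 150,
                      tube_id = "CRM18_0h"))
exp <- simulate_experiment(specs, master_seed = 1)

path <- file.path(tempdir(), "CRM18_0h.fcs")
write_fcs(exp$tubes$CRM18_0h$table, path)
tube <- read_fcs(path)

gate_tube(tube)
#> <GatingResult: 20000 events>
#>        debris       doublet          dead control_spike        sample
#>           999          1043          3023          3914         11021
#>    unassigned
#>             0
#> thresholds:
#>           fsc_min           ssc_min singlet_ratio_max     viability_max
#>        11259.0000         7688.6000            1.1531          589.7400
#>    cfse_threshold
#>          630.8800

s_ref <- analyze_tube(exp$tubes[["Promoter_-48h"]]$table)
s_smp <- analyze_tube(tube)
s_smp
#> <TubeSummary 'CRM18_0h': f_sample = 5227 (n = 11021), f_control = 248.1 (n = 3914)>

fold_change_scheme_A(s_ref$f_sample, s_ref$f_control,
                     s_smp$f_sample, s_smp$f_control,
                     reference_tube_id = "Promoter_-48h")
#> <FoldChange scheme A_puer_spike: L = 5.014>

separation_index(s_smp$f_sample, s_smp$f_control, s_smp$p84_control)
#> [1] 73.37
```

Reading the numbers: the gate recovered the simulated mixture (5% debris, 5%
doublets, 15% dead, 20% spike), the sample median 5227 is the expression
level 5000 plus the 100 autofluorescence baseline scaled/shifted by the tube
effect, and the background-subtracted fold change 5.014 recovers the true
ρ = 5 within 0.3% *despite* the additive shift, because scheme A cancels it
exactly. The separation index says sample and Luc⁻ control are ~73 robust
SDs apart.

Replicate reports and bulk comparison work from CSV summaries in three
dialects (`read_replicate_csv(path, dialect = "s11" | "s12" | "s13")`):
`reproduce_fig4()` computes per-construct CVs of MFI/SI/fold change and
their ranges; `reproduce_fig5()` computes bulk and flow fold changes, their
per-point ratio, and r².

A command-line front end is installed at `exec/lucflow`
(`simulate`, `gate`, `quantify`, `cv-report`, `compare-bulk`), e.g.
`lucflow simulate --out-dir tubes --seed 5` then
`lucflow quantify tubes/*.fcs --reference Promoter_-48h --out quant.csv`.

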