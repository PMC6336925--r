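# nirsfilt

Filter design and evaluation for GLM analysis of functional near-infrared
spectroscopy (fNIRS) time series.

## Why

fNIRS concentration signals (ΔHbO₂, ΔHbR) carry a task-evoked hemodynamic
response of a few tenths of a micromolar buried in physiological noise —
cardiac (~1 Hz), respiratory (~0.3 Hz), Mayer waves (~0.1 Hz),
very-low-frequency activity and slow drifts. Band-pass or low-pass digital
filtering is the standard cleanup before fitting the general linear model

&nbsp;&nbsp;&nbsp;&nbsp;*y = X β + ε*,&nbsp;&nbsp; *X = [ boxcar ⊛ HRF , 1 ]*,

but the filter family (Butterworth, FIR, moving average), order, and
cut-off frequencies [f_c,low, f_c,high] determine whether the estimated β
recovers the true response or a distorted one — and high-order IIR designs
can be outright unstable in their realized coefficients.

`nirsfilt` makes the filter choice testable. It simulates multi-subject,
multi-channel resting fNIRS data with realistic noise spectra and injects a
known task component (a double-gamma HRF, peak 6 s / undershoot 16 s,
convolved with a 14-block 20 s-on/20 s-off boxcar; stimulation frequency
0.025 Hz), so the generating amplitude *is* the ground-truth β (presets
0.8/−0.27, 0.5/−0.17, 0.3/−0.1 µM for HbO₂/HbR). It then runs any grid of
filter specifications through the full pipeline — modified Beer–Lambert
conversions between optical density and concentration, optional targeted-PCA
motion correction, zero-net-phase filtering, GLM estimation under three
serial-correlation treatments (none, 1 Hz spline down-sampling,
HRF precoloring) — and scores every specification by group-level recovery
of the reference β: subject medians over channels, Shapiro–Wilk normality,
IQR outlier flags, and one-sample t-tests against the reference
(df = n_subjects − 1).

For whom: fNIRS researchers choosing preprocessing parameters, and method
developers who need a seeded, fully synthetic benchmark where the right
answer is known.

## Worked example

Screen two Butterworth band-pass designs for stability, then compare a
5th- and a 1000th-order FIR band-pass on a small simulated study:

```r
library(nirsfilt)

check_stability(design_filter(filter_spec("BP", "BW", 5, 0.01, 0.2)))
#> <stability_report> stable  max|pole|=0.997234671071909
check_stability(design_filter(filter_spec("BP", "BW", 20, 0.01, 0.2)))
#> <stability_report> UNSTABLE  max|pole|=2.19893404121214

ds <- assemble_dataset(n_subjects = 6, n_channels = 8,
                       amplitudes = amplitude_presets()["Amplitude1"],
                       master_seed = 42)
grid <- list(filter_spec("BP", "FIR", 1000, 0.01, 0.09),
             filter_spec("BP", "FIR", 5, 0.01, 0.09))
names(grid) <- vapply(grid, spec_id, character(1))
sw <- run_sweep(ds, grid, corrections = "precolor", domains = "conc")
sw$records[, c("spec", "chromophore", "mean_beta", "bias", "t_stat", "t_p")]
#>                       spec chromophore mean_beta      bias t_stat    t_p
#> 1 BP_FIR_o1000_fc0.01-0.09        HbO2  7.76e-07 -2.37e-08  -3.24 0.0229
#> 2 BP_FIR_o1000_fc0.01-0.09         HbR -2.64e-07  5.64e-09   2.69 0.0435
#> 3    BP_FIR_o5_fc0.01-0.09        HbO2  8.45e-07  4.48e-08   1.89 0.1173
#> 4    BP_FIR_o5_fc0.01-0.09         HbR -2.81e-07 -1.05e-08  -1.13 0.3114
```

Reading the output: the reference β is 8×10⁻⁷ Molar for ΔHbO₂ and
−2.7×10⁻⁷ for ΔHbR. The order-5 FIR barely attenuates the slow drifts, so
its group mean β overshoots the reference (8.45×10⁻⁷, bias +4.5×10⁻⁸ M);
the order-1000 design removes them and lands closer with less spread, at
the cost of a small systematic attenuation bias (−2.4×10⁻⁸ M) from task
harmonics above its 0.09 Hz edge. Unstable IIR cells are recorded as
skipped, mirroring the dashed cells of stability-screened reports.
`rank_filters(sw, "abs_bias")` orders specifications by recovery;
`export_group_table(sw, ...)` lays a statistic out as orders × cut-offs.

The methods vignette (`vignettes/filter-evaluation.Rmd`) documents the
noise model, the filter design conventions, the three serial-correlation
treatments, and the known limitations of each ranking criterion.

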