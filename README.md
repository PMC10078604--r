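# relaxoplan

Relaxometry fitting and SNR-efficiency protocol planning for ex vivo MRI.

Ex vivo MRI of fixed brain tissue fights short relaxation times: fixation
shortens T1 and T2, and the long echo times needed for diffusion weighting
then cost most of the signal. Three preparation factors can be tuned
against this — fixative concentration, rehydration (soaking in PBS, which
recovers T2), and a gadolinium contrast agent introduced by active
staining, which shortens T1 so a short repetition time can be used without
saturation, but also shortens T2. `relaxoplan` models each factor and
combines them to plan acquisitions, for preclinical MRI groups preparing
fixed rodent brains for high-resolution imaging.

The models at the core:

- **Relaxivity**: 1/Tᵢ(c) = 1/Tᵢ₀ + rᵢ·c for contrast-agent concentration
  c (mM), fitted per tissue/fixative/agent (`fit_relaxivity()`); nine
  fitted ex vivo rat-brain records ship with the package
  (`load_relaxivity_records()`).
- **Spin-echo signal**: S ∝ (1 − 2e^{−(TR−TE/2)/T1} + e^{−TR/T1})·e^{−TE/T2}
  (with the simpler (1 − e^{−TR/T1})·e^{−TE/T2} selectable), and
  **SNR efficiency** S/√TR, maximized over TR and concentration
  (`optimal_tr()`, `optimal_concentration()`, `efficiency_surface()`).
- **Rehydration kinetics**: T2(t) = a − b·e^{−t/τ} with the derived time
  to 95% of plateau (`fit_rehydration()`, `time_to_fraction()`).
- **T1/T2 mapping**: voxelwise saturation-recovery and multi-echo fits
  from NIfTI series (`fit_map()`, `roi_stats()`).
- **SNR estimation**: background-noise SNR with the Rician magnitude
  correction √(2 − π/2) ≈ 0.655 (`estimate_snr()`, `measure_rois()`).
- **Phantoms**: seeded synthetic relaxometry series (Rician noise) and
  cohort tables for every fitting stage (`phantom_spec()`,
  `make_relaxometry_series()`, …).

## Worked example

Plan the contrast-agent concentration for cortical grey matter fixed with
2% PFA, at the timing of a high-resolution diffusion-weighted spin echo
(TE = 27 ms, TR = 250 ms):

```r
library(relaxoplan)
rec <- load_relaxivity_records()
cortex <- get_relaxivity_pair(rec, "cortex", 2, "Gd-DTPA")
plan_protocol(cortex$t1, cortex$t2, te = 27, tr = 250)
#> Acquisition plan
#>   tissue: cortex, 2% PFA, Gd-DTPA
#> Optimal [CA] at TE = 27 ms, TR = 250 ms (full variant):
#>   argmax = 20.2 mM (efficiency 0.0145)
#>   95%-of-max interval: [12.3, 30.3] mM
#>   predicted tissue at 20.2 mM: T1 = 222.5 ms, T2 = 26.6 ms
```

The argmax is the concentration maximizing SNR per unit scan time; any
concentration in the interval costs at most 5% of the attainable SNR, so
15 mM — comfortably inside — is a practical choice.

How does an optimized preparation (2% PFA corpus callosum at 15 mM
Gd-DTPA) compare with a standard one (4% PFA, no contrast agent,
T1 = 1705 ms, T2 = 52 ms)?

```r
cc <- get_relaxivity_pair(rec, "CC", 2, "Gd-DTPA")
opt <- tissue_relaxation(relaxation_time(cc$t1, 15),
                         relaxation_time(cc$t2, 15))
opt
#> Tissue relaxation: T1 = 360.2 ms, T2 = 34.6 ms
std <- tissue_relaxation(1705, 52)
matched_tr(opt, sequence_params(te = 26.78, tr = 250), std)
#> [1] 780.3603
predict_snr(12, opt, std, sequence_params(te = 26.78, tr = 250))
#> [1] 4.123386
scale_scan_time(91.35, tr_ratio = 3)
#> [1] 274.05
```

The standard preparation would need TR ≈ 780 ms (vs 250 ms) to match the
optimized tissue's per-excitation signal — roughly tripling a 91.35 h scan
to 274 h — and, run at the optimized protocol's own timing, its predicted
SNR drops from the measured 12 to about 4.1, below the ≈ 5 usually
considered acceptable for diffusion modelling.

A command-line wrapper (`exec/relaxoplan`) exposes the stages as
subcommands (`simulate`, `fit-t1`, `fit-t2`, `roi-stats`, `relaxivity`,
`rehydration`, `plan`, `matched-tr`, `snr`); see `?run_command`.

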