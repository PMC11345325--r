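# vfimix

Synthetic end-to-end reimplementation of a bench-top ultrasound **vector
flow imaging (VFI)** study of the thoracic aorta under **VA-ECMO**
(veno-arterial extracorporeal membrane oxygenation). Under VA-ECMO,
retrograde pump flow returned via the femoral artery meets the native
anterograde cardiac output at the aortic *mixing zone*; its location
(ascending aorta / arch / descending aorta) governs cerebral oxygenation
and cardiac afterload, and high-frame-rate VFI is a candidate bedside
monitor for it.

The package is aimed at researchers in ultrasound flow imaging and ECMO
hemodynamics who want a fully synthetic, deterministic testbed for the
whole computational chain:

1. **`synthetic_flow`** — ground-truth 2D velocity scenes: a pulsatile
   parabolic cardiac jet (30 mL x 90 bpm = 2.7 L/min, 40/60
   systole/diastole) against a steady retrograde 12 mm ECMO jet (0.35 or
   1.0 L/min), blended at an interface that follows the momentum balance
   `m = L Qc² / (Qc² + Qe²)`, plus Lamb–Oseen diastolic vortices and a
   bi-modal 81/57 mmHg pump pressure waveform.
2. **`acquire`** — dual-angle (±10°) plane-wave Doppler at 10 kHz PRF:
   per-angle frequency maps `f_d = (f0/c)(v_x sin a + v_z (1 + cos a))`,
   Nyquist wrapping with aliasing flags, frequency noise, optional IQ
   ensembles with a Kasai lag-one estimator. 2 angles x 4 pairs = 800 µs
   frames (1250 fps).
3. **`solve_vectors`** — per-pixel least squares `argmin ‖A v − f‖₂` with
   validity masking.
4. **`segment_phases` / `detect_systole_onset` / `synchronize_cineloops`**
   — late diastole `[0, 0.1)`, systole `[0.1, 0.4)`, early diastole
   `[0.4, cycle)`; onset from the first anterograde vectors in the
   proximal ascending aorta; loop alignment by circular cross-correlation
   of the pressure waveforms.
5. **`categorize_vectors` / `group_ratios` / `phase_summary` /
   `welch_t_test` / `localize_mixing_zone`** — the five flow groups
   (fast/slow anterograde, fast/slow retrograde, other; ±30° cones,
   0.25 m/s threshold), per-frame area ratios, per-phase mean ± SD, Welch
   comparisons between ECMO conditions, and the crossing of the
   anterograde/retrograde ratio profiles along the aortic path.
6. **`render_cineloop` / `compose_video`** — vector-projectile style
   arrows advected through the field, synchronized multi-panel PNG
   sequences with the pressure trace and cursor metadata.

## Worked example

The numbered scripts under `analysis/` run the study workflow; they are
thin drivers over the package functions:

```sh
Rscript analysis/01_simulate_scenes.R
Rscript analysis/02_run_pipelines.R
Rscript analysis/03_compare_conditions.R
Rscript analysis/04_render_cineloops.R
```

`02_run_pipelines.R` executes the full chain for both ECMO conditions
(three probe positions each, 1.5 s at 1250 fps) and prints:

```
low_ecmo: systole onset 0.1112 s, mixing zone 217.4 mm
high_ecmo: systole onset 0.1240 s, mixing zone 142.9 mm
```

The detected onset sits just after the generator's 0.1 s gate opening (the
smooth gate must first exceed the 0.02 m/s flow floor), and the mixing-zone
estimate moves from the distal descending aorta (217 mm along the aortic
path) to proximal of it (143 mm) when the ECMO rate rises from 0.35 to
1.0 L/min. `03_compare_conditions.R` prints the phase-resolved contrast:

```
arch late-diastole retrograde ratio: high 99.9% vs low 69.0% (min p = 0)
descending systole anterograde ratio: high 76.6% vs low 86.8% (min p = 0.000729)
mixing zone: high 142.9 mm (proximal) vs low 217.4 mm (distal)
```

i.e. the retrograde ECMO stream dominates the arch in late diastole under
high flow, and the systolic cardiac stream in the mid descending aorta is
suppressed by it — the directional signature of the mixing zone moving
rootward. Full tables land in `results/` (`ratios.csv`,
`phase_summary.csv`, `condition_comparison.csv`).

Equivalent interactive use:

```r
library(vfimix)
run_low  <- run_pipeline(default_run_config("low_ecmo",  seed = 1))
run_high <- run_pipeline(default_run_config("high_ecmo", seed = 1))
cmp <- compare_conditions(run_high, run_low)
head(cmp$table)
```

Bundled study-default configurations (YAML) are in `inst/extdata/` and
round-trip through `read_run_config()` / `write_run_config()`.

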