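# motorcargo

Tools for quantifying how molecular motors sit on the vesicles they move.
In two-colour live-cell imaging of intracellular transport — e.g. a
Rab6-labelled secretory vesicle (cargo channel) carrying a GFP-tagged
kinesin (motor channel) — the motor's position relative to the vesicle
centre reports whether the motor is pulling (front), resisting (back) or
disengaged (no shift). `motorcargo` implements the full computation from
per-frame sub-pixel detections to that statistic:

* **Synthetic data**: a ground-truthed simulator of vesicles alternating
  diffusive "jiggling" and processive, microtubule-guided runs
  (0.065 µm/px, 0.1 s/frame defaults), with a motor channel offset along
  the instantaneous velocity, chromatic-aberration fields, calibration
  grids, and a 2D-Gaussian + Poisson image renderer.
* **Localization**: spot detection by 2D Gaussian least-squares fitting;
  red-onto-green channel registration as an affine map plus a thin-plate
  residual field fitted to calibration-grid detections.
* **Tracking**: per-frame one-to-one colocalization pairing
  (0.52 µm threshold) and nearest-neighbour track linking with gap closing
  (0.65 µm, up to 5 missing frames).
* **Runs**: segmentation of trajectories into directional runs where the
  cosine between consecutive velocity vectors stays above 0.6, in both the
  single-channel variant (>6 frames, pause splitting) and the colocalized
  variant (>0.3 s and >0.5 µm); run metrics and per-cell run-fraction
  statistics.
* **Motor geometry**: the signed projected distance
  `d = (v · l)/|v|` of the cargo→motor vector `l` onto the cargo velocity
  `v`, the angle `α = arccos(d/|l|)`, experiment-averaged histograms, and
  the opposite-polarity run-pair analysis (cosine < −0.6, centres of mass
  < 1 µm apart, forward = larger average `d`) that contrasts motor position
  during plus-end- versus minus-end-directed motion.
* **Speed statistics**: per-cell and pooled run speeds, 1- vs 2-component
  Gaussian fits to the binned speed distribution (`fit_speed_mixture()`,
  a classed model object with `print`/`coef`/`predict`/`plot` methods)
  compared by the extra sum-of-squares F test, and speed-vs-distance
  binning.
* **Photometry**: background-corrected aperture intensities (7 px circles),
  motor copy-number estimates against a single-motor standard, and FRAP
  trace normalization.

## Worked example

Simulate 100 vesicles whose motor sits a median 76 nm ahead of the cargo
centre along the direction of motion, corrupt both channels with 25 nm
localization noise, and recover the offset through the full pipeline:

```r
library(motorcargo)

cfg <- pipeline_config(
  simulation = simulation_config(n_vesicles = 100, n_frames = 500,
                                 motor_offset_mean = 0.076, seed = 11),
  stages = c("simulate", "pair", "link", "segment", "geometry"))
rep <- run_pipeline(cfg)
rep
#> <pipeline_report>
#>  counts:
#>    detections_green       50000
#>    detections_red         50000
#>    pairs                  50000
#>    tracks                 100
#>    runs                   938
#>    geometry_timepoints    12166
#>  stats:
#>    median_d_nm            74.83
#>    median_d_run_avg_nm    75.52
#>    median_alpha_deg       25.63
```

`median_d_nm` is the median instantaneous projected distance over all
~12,000 run timepoints: the simulated 76 nm front offset is recovered to
within a couple of nanometres despite the noise (the residual shortfall is
the expected attenuation from projecting onto a noisy velocity direction).
`median_alpha_deg` far below 90° says the motor clusters at the vesicle
front; a marker with no directional preference gives a symmetric `d`
distribution around zero and a roughly uniform `α`.

Fitting the run-speed distribution and asking whether two speed
populations are present:

```r
f1 <- fit_speed_mixture(rep$runs$speed_um_s, k = 1)
f2 <- fit_speed_mixture(rep$runs$speed_um_s, k = 2)
f2
#> <speed_mixture_fit> 2 component(s), 938 speeds, bin width 0.1 um/s
#>   component 1: mean 1.307 um/s, sd 0.216, weight 0.470
#>   component 2: mean 1.662 um/s, sd 0.471, weight 0.530
#>   SSE 366.8 on 20 df
extra_ss_ftest(f1, f2)
#> extra sum-of-squares F = 35.85 on (3, 20) df, p = 3.08e-08
#>   preferred model: 2 component(s)
```

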