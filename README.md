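# dcmflow

Quantitative analysis for colonic-motility biopharmaceutics: the wall
kinematics, fluid rheology, tracer-particle tracking and mixing analyses
used with a ten-unit **dynamic colon model** (DCM) — a 200 mm tube of
20 mm haustral units whose membranes contract, hold and relax under
program control, half-filled with carboxymethyl-cellulose media of low
(L), medium (M) and high (H) viscosity. It is written for researchers in
gastrointestinal biopharmaceutics and motility biophysics who need to
turn cine-MRI haustral series, Lagrangian particle tracks and programmed
wall protocols into the field's standard metrics.

The core quantities:

* **Herschel–Bulkley rheology** τ = τ_y + K·γ̇ⁿ, apparent viscosity
  μ_A = τ/γ̇ (quoted at γ̇ = 10 s⁻¹), particle relaxation time
  t_o = ρ_d d_d²/(18 μ_A), Reynolds number Re = d_h ū ρ/μ_A.
* **Motility index** (segment·s): over 20 s bins,
  Σ D_r·N_seg, where D_r is the contraction-active time in the bin and
  N_seg the number of active colon segments.
* **Haustral event metrics**: occlusion degree (% reduction from
  baseline), occlusion velocity (cm/s), contraction/relaxation durations,
  propagating-wave direction, travel distance and velocity.
* **Trajectory metrics**: propulsive displacements (axial excursions
  ≥ 10 mm) with velocity U_x = Δx/Δt, per-unit residence times,
  cross-sectional occupancy, distance-at-velocity histograms.

A seeded synthetic-data module emulates every input (wall-driven 1-D
flow, PEPT-like tracks, compartmental tracer mixing, in vivo-like
haustral series), so the full pipeline is testable without the original
recordings. The methods vignette
(`vignettes/dcm-motility-and-transport.Rmd`) documents the models and
their assumptions.

## Worked example

Physics of the tracer particles — the magnetic pill used for in vivo
comparisons (ø 5.5 mm, 1.8 g/cm³) in the thin and thick media:

```r
library(dcmflow)
pill <- particle_presets()$magnetic_pill
relaxation_time(pill, fluid_presets()$L)   # 0.378125 s
relaxation_time(pill, fluid_presets()$H)   # 0.015125 s
```

0.378 s vs 0.015 s: the pill responds to flow changes twenty-five times
faster in the thick medium — in thin fluids it is a poor flow tracer.

Recover a programmed contraction wave from a synthetic haustral
recording (10 haustra, 1 Hz, 120 s; one antegrade wave at 2 cm/s with
40 % occlusion):

```r
hs <- simulate_haustral_series(
  data.frame(direction = "antegrade", velocity_cm_s = 2,
             occlusion_pct = 40, onset = 10), seed = 1)
ev <- detect_contraction_events(hs)
head(ev[, c("haustrum", "onset", "occlusion_degree", "t_c", "t_r")], 3)
#>   haustrum onset occlusion_degree t_c t_r
#> 1        1     9         41.50945   9  17
#> 2        2    10         39.55506   9  20
#> 3        3    11         41.02615   8  22

link_waves(ev, hs)$waves[, 1:4]
#>   direction travel_distance travel_velocity n_events
#> 1 antegrade            22.5        1.931818        9

in_vivo_motility_index(ev, hs)   # 199 segment*s
```

The detector recovers the occlusion degree within ~1.5 points, the wave
direction exactly and the travel velocity within 4 %; the motility index
scores the recording's activity in segment-seconds.

## Analysis workflow

The numbered drivers under `analysis/` reproduce the study's analyses
over synthetic data and write delimited tables under `results/`:

| script | what it computes |
|---|---|
| `01_physics_table.R` | rheology / relaxation-time / Reynolds table for L/M/H × particle presets |
| `02_wall_protocol.R` | the programmed wave (10 s traversal) and its motility index |
| `03_motility_analysis.R` | event detection, wave linking, timing ratios, fold changes |
| `04_track_analysis.R` | displacements, distance–velocity histograms, residence times, occupancy |
| `05_tracer_mixing.R` | tracer mixing and the viscosity–heterogeneity ordering |

Run any of them from the repository root, e.g.
`Rscript analysis/04_track_analysis.R`.

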