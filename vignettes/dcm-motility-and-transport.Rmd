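---
title: "Wall kinematics, rheology and particle transport in a dynamic colon model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wall kinematics, rheology and particle transport in a dynamic colon model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmflow)
```

## The system

`dcmflow` provides the quantitative machinery for biorelevant colonic
motility experiments in a ten-unit dynamic colon model (DCM): a 200 mm
tube of ten 20 mm haustral units whose membranes inflate and deflate
under program control, half-filled (100 mL) with sodium-carboxymethyl-
cellulose media of low, medium or high viscosity. Four strands of
analysis live in the package:

1. **Rheology and particle physics** — Herschel–Bulkley constitutive law,
   apparent viscosity, particle relaxation times, Reynolds numbers.
2. **Wall kinematics** — the programmed contraction–hold–relaxation cycle
   propagated as an antegrade or retrograde wave, and the segment-based
   colonic motility index.
3. **Motility time-series analysis** — detection of haustral contraction
   events in per-haustrum length/area series extracted from cine-MRI,
   occlusion metrics, linking of events into propagating waves, motility
   indices and condition fold changes.
4. **Trajectory analysis** — Savitzky–Golay smoothing, registration into
   tube coordinates, pass segmentation, propulsive-displacement detection
   (≥ 10 mm rule), residence times, occupancy and distance–velocity
   histograms for Lagrangian particle tracks.

A fifth component, the synthetic-data generator, emulates every input the
analyses consume so that the whole pipeline is testable end to end
without the original recordings.

## Rheology and particle physics

Shear stress follows the Herschel–Bulkley law
$\tau = \tau_y + K\dot\gamma^n$; the apparent viscosity at shear rate
$\dot\gamma$ is $\mu_A = \tau/\dot\gamma$, conventionally quoted at
$\dot\gamma = 10\,\mathrm{s^{-1}}$. The particle relaxation time
$t_o = \rho_d d_d^2 / (18\mu_A)$ measures how quickly a particle of
density $\rho_d$ and diameter $d_d$ adapts to the surrounding flow, and
the tube Reynolds number is $\mathrm{Re} = d_h \bar u \rho / \mu_A$.

```{r physics}
physics_table()[, 1:6]
```

Design notes:

* The preset fluids L/M/H carry **both** the printed apparent viscosities
  (8, 106, 200 mPa s) and the measured consistency/flow indices as
  independent fields. The two are mutually consistent only for fluid M at
  10 s⁻¹; for L and H the shear rate behind the printed viscosity is not
  recoverable, so the package never derives one preset field from the
  other.
* Internally everything is strict SI; `physics_table()` is the reporting
  layer (mPa s, cm/s).
* Herschel–Bulkley fitting is a constrained nonlinear least-squares
  problem that is non-convex in $n$; `fit_herschel_bulkley()` multi-starts
  at $n \in \{0.3, 0.6, 0.9\}$ and breaks ties by residual norm, then by
  the lower $n$.
* The relaxation-time diameter of a cylindrical 3 × 3 mm tracer is taken
  as 3 mm; the 21 × 8 mm capsule preset uses its 8 mm transverse diameter.
  The hydraulic diameter behind the default Reynolds number (31 mm,
  partially filled tube) is a modelling choice, and the reported Re should
  be read as order-of-magnitude.

## The wall-motion protocol

Each unit's actuation cycle is piecewise linear in membrane displacement:
inflation at 1.6 cm/s to a programmed occlusion degree (default 40 % of
the 12 mm maximum travel, i.e. a 0.30 s ramp), a 1 s hold, and deflation
at 0.35 cm/s (1.37 s), mimicking the slower active relaxation of the
colonic wall. Contraction onsets stagger along the tube at the wave speed
(2 cm/s default), so the front crosses the 20 cm tube in 10 s.

```{r wave}
field <- propagate_wave(wave_protocol())
wave_traversal_time(field)
```

With paired expansion (the "law of the intestine"), the unit downstream
of each contracting unit deflates below its neutral position at the same
speed. A membrane cannot be deflating and inflating simultaneously, so an
expanded unit starts its own cycle by re-inflating from below neutral at
the contraction speed; its contraction proper is delayed by one ramp time
(0.30 s). The final unit faces the rigid siphon and receives no
expansion.

The **motility index** divides the recording into 20 s bins; in each bin
$D_r$ is the union of time during which any contraction activity occurs
(capped at the bin width) and $N_{o,seg}$ the number of segments active at
any instant, giving $\sum_i D_r N_{o,seg}$ in segment-seconds. The
canonical example — the whole five-segment colon active for one bin plus
one segment active for the next — scores $20\times5 + 20\times1 = 120$.
Applying the same accounting to the programmed protocol of four waves per
two minutes yields ≈ 239 segment·s (`analysis/02_wall_protocol.R`).

## Motility time-series analysis

Inputs are per-haustrum series at 1 Hz over ~120 s: straight-line lengths
(cm) under baseline conditions, ROI areas (cm²) under stimulated
conditions. A contraction is any sustained drop of at least 10 % (default,
configurable) below baseline.

* **Detection** runs on a centred moving-median (window 5) copy; all
  metrics are then measured on the raw series, so metric values are not
  distorted by the smoother. The per-event baseline is the median of the
  10 samples preceding the onset. Onset and end are refined on the raw
  series with a 5 % recovery band, each extended along its monotone limb
  so the full contraction and relaxation are attributed symmetrically
  (mirror-reversing a series swaps $t_c$ and $t_r$ exactly).
* **Occlusion velocity** is reported in cm/s for both modes; area series
  are converted to an equivalent diameter $\sqrt{4A/\pi}$ before
  differencing, and the conversion is flagged by the mode field.
* **Wave linking** chains events on adjacent haustra with positive onset
  lags of at most 15 s, allowing a one-haustrum gap when the skipped
  haustrum shows a sub-threshold dip. Direction follows the
  position-versus-time order (antegrade = towards the hepatic flexure).
  Travel velocity is the inverse least-squares slope of onset against
  position: identical to span-over-lag for collinear onsets and robust to
  the ±0.5 s onset quantisation of 1 Hz sampling (the quantisation error
  of the endpoint formula alone can exceed 10 % over a 22 cm span).
* The in vivo motility index maps haustra onto five equal spans of the
  position range and reuses the same binned accounting as the protocol
  side, so both are tested against one brute-force integral oracle.

## Trajectory analysis

Tracks are time-ordered Cartesian positions of a single tracer particle,
sampled several times per second with sub-millimetre localisation noise.
The pipeline is: Savitzky–Golay smoothing (order 2, window 11 at the
default 4 Hz — the window is a package default, the source experiments do
not state theirs), registration of the initial dwell onto the first-unit
centre (floating particles map to the free surface in z, neutrally
buoyant ones 5 mm below), segmentation into passes (complete when the
particle reaches within 10 mm of the distal end), and then per-pass
statistics.

**Propulsive displacements** are maximal monotone axial excursions,
tolerating counter-movements up to 3 mm (the particle's own size), that
span at least 10 mm. Each carries $U_x = \Delta x / \Delta t$ over the
excursion; the sign gives antegrade/retrograde. The detector is a linear
zigzag state machine and is verified against an independent
drawdown-scan oracle on hundreds of random tracks.

**Residence times** attribute each inter-sample interval to the half-open
20 mm unit containing its left sample, so per-unit times sum to the pass
duration exactly. Occupancy maps are normalised 2-D histograms of the
cross-sectional (y, z) samples pooled over passes; distance–velocity
histograms sum distance covered per signed velocity bin (0.1 cm/s).

## The synthetic-data generator

The generator emulates the study conditions: 1 Hz, 120 s haustral series
with propagating trapezoidal contractions; particle tracks at 4 Hz with
0.5 mm Gaussian localisation noise in the 200 mm ten-unit tube; and a
ten-compartment tracer for the imaging experiments. All generators are
pure functions of (configuration, seed).

### Flow model

The wall-driven flow is deliberately reduced to a 1-D compartment model
with exact volume bookkeeping — an emulator, not CFD. Each unit has a
time-varying lumen capacity and a fluid volume; both tube ends are
closed. Two mechanisms exchange fluid between neighbours:

* **Piston displacement.** The membrane rises from the tube floor where
  the half-fill fluid lies, so a shrinking positive-occlusion capacity
  displaces fluid one-to-one until the unit is drained. The displaced
  volume leaves through the two neighbouring interfaces in proportion to
  a constriction gate (the squared minimum neighbouring lumen fraction):
  a contracted neighbour throttles its share — the peristaltic valve
  action. Only the membrane rising *into* the lumen acts as a piston; an
  expanded pouch returning to neutral merely removes empty headroom.
* **Free-surface levelling.** Differences in fill fraction relax by a
  gravity-driven flux $G_0 \cdot \mathrm{gate}^2 \cdot
  \sqrt{\mu_{ref}/\mu_A} \cdot \Delta f$. Thin media level quickly
  (sloshing, strong backflow after the wave has passed); thick media
  level slowly (plug flow). $G_0$ defaults to
  $6\times10^{-6}\,\mathrm{m^3 s^{-1}}$, a levelling time of roughly two
  seconds for adjacent half-filled units in the reference fluid M — fast
  enough that the fluid is effectively static within the 10 s inter-wave
  delay the protocol prescribes.

The occlusion fraction maps to lumen area proportionally by default (a
40 % occlusion removes 40 % of the cross-section, matching how luminal
occlusion is quoted for the device); a displaced-wall chord-geometry map
is available as an option but maps 40 % membrane travel to only ~7 % area
loss, which is too weak to move anything. With the reported area taken as
the *wetted* cross-section, discrete continuity
$\partial A/\partial t + \partial Q/\partial x = 0$ holds exactly and
both end fluxes are zero.

### Particle advection

A purely volume-conserving 1-D velocity field returns every parcel it
displaces, so a point particle would ratchet nowhere (verified
numerically). Physically the two flux components have different
cross-sectional structure: the piston expulsion is a focused jet through
the constriction which the particle rides in full, whereas the levelling
return runs as a bottom-concentrated gravity current of which a particle
in the upper bulk samples only a fraction. The particle is therefore
advected with $u_{forced} + c\,u_{level}$, with coherence $c = 0.3$ by
default (calibrated within a physically plausible 0.1–0.5 to reproduce
the qualitative residence-time gradient of the tracking experiments;
levelling velocities are evaluated with the resting wetted area as a
floor, since the return current never exceeds its section-mean speed in
the bulk). On top of this the particle takes a random-walk axial
dispersion $D = D_0\,\mu_{ref}/\mu_A$ ($D_0 = 2\times10^{-6}\,
\mathrm{m^2 s^{-1}}$, so the thin medium disperses ~25× more than the
thick one), floating particles stay on the free surface with an optional
surface-transport factor (a named 1.15 preset reproduces surface
transport slightly faster than the wave), and neutrally buoyant particles
diffuse transversally within the lumen.

### Tracer mixing

The dissolved tracer evolves on the ten compartments by upwind advective
exchange with the interface fluxes plus diffusive exchange
$k_{mix} = k_{mix,0}\,\mu_{ref}/\mu_A$. Transfers are antisymmetric, so
total mass is conserved to machine precision. At fixed seeds the final
axial-profile heterogeneity (CV across compartments) is non-decreasing
from L to M to H: the thin medium spreads the tracer along the tube while
the thick media leave concentrated spots.

### What the emulator does and does not show

Passing tests demonstrate that the *analysis* code recovers known ground
truth (occlusion degrees within 5 points, wave velocities within 10 %,
directions exactly, over seeded replicates) and that the emulator
reproduces the study's qualitative physics: bounded propulsive velocities
(no propulsive velocity above the 2 cm/s wave speed plus 10 % for a neutrally
buoyant particle in the thick medium), viscosity-ordered mixing, net
antegrade transport with short proximal dwell and the longest dwells
distally. They do not validate 3-D hydrodynamics: sloshing, free-surface
shape, haustral pocketing and the exact per-unit residence ranking are
outside a section-averaged model. In particular "first unit strictly
shortest" — observed in the physical experiments — is only marginally
reproduced here (proximal recapture by backflow competes with it), so the
end-to-end test asserts the robust pattern (proximal dwell below the
pooled mean, maximum dwell in the distal half) rather than a strict
ranking.

## Numerical choices

* Time grid 0.01 s (resolves the 0.30 s inflation ramp); the heavy
  end-to-end test uses 0.02 s, which leaves all ramps ≥ 15 samples.
* Problem sizes in tests: haustral recovery over 20 seeds; displacement
  oracle over 100 random tracks of ≤ 200 samples; velocity-bound check
  over 5 seeded tracks of 20 waves; end-to-end residence over 4 seeded
  tracks of 70 waves. These sizes give stable pooled statistics for the
  properties asserted.
* Event detection drops events whose raw-series depth falls below the
  threshold even when the smoothed series crossed it (the smoother is for
  localisation only).
* Degenerate inputs: zero shear rate returns the yield stress; apparent
  viscosity at zero shear rate, empty event lists, zero baselines and
  empty pass sets raise errors rather than NaNs; full lumen occlusion is
  rejected by the flow model.
* Ties in Herschel–Bulkley multi-start resolve to the lowest residual,
  then the lowest flow index.

## Known limitations

* The 1-D emulator cannot express torque-free sloshing or the
  cross-sectional position dependence the tracking experiments report;
  transverse coordinates of simulated tracks are diffusive placeholders.
* Pass completion for the thick medium takes over a thousand simulated
  seconds (tens of waves), consistent with the long measured residence
  times, so default test horizons analyse long incomplete passes and flag
  them as such.
* Reynolds numbers depend on an inferred hydraulic diameter; the printed
  values for the two thicker media are not reproducible from any single
  geometry and are treated as indicative only.
* Area-mode occlusion velocities assume an equivalent-circular haustrum;
  real haustra are not circular, so cross-mode velocity comparisons carry
  that geometric assumption.
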