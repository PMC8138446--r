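---
title: "Methods: transport, cardiac metrics and coupled DDI modelling in a liver-heart MPS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transport, cardiac metrics and coupled DDI modelling in a liver-heart MPS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpsddi)
```

This vignette is the package's own account of its science: the models it
implements, the assumptions and numerical choices behind them, where each
parameter comes from, which design decisions were genuinely open, and what
the synthetic-data tests do and do not establish.

## 1. The device and its transport model

The liver chip is a membrane-bilayer device: a cell chamber
(5,560 × 560 × 100 µm) holding ~10⁴ hepatocyte-like cells under an
isoporous membrane (15 µm thick, 5.6 % porosity, 3 µm pores), with a media
channel of the same footprint above it, all cast in a gas-permeable PDMS
slab (3.5 mm to the ambient above the channel) on a glass base. Media is
perfused at Q = 20 µL/h.

### Hydraulics are analytic

At these scales the Reynolds number is ≪ 1 and the channel flow is fully
developed plane Poiseuille flow, so no numerical flow solve is needed:

- mean velocity `Q/(w·h)` ≈ 9.9 × 10⁻⁵ m/s,
- wall shear `6µQ/(w·h²)` ≈ 0.046 dyn/cm² (channel Peclet ≈ 3),
- channel residence time ≈ 56 s.

Flow across the membrane and inside the cell chamber is neglected: the
membrane's open area and pore size make its flow resistance orders of
magnitude larger than the channel's, so the chamber is a dead-end,
diffusion-only compartment. `Q = 0` is a legal no-flow state, reported as
such rather than as an error.

### Species transport

`discretize_device()` builds a 2-D x–z finite-volume mesh (width-averaged;
the y direction enters only through volumes, the discrete flow-rate
normalization and the wall-exchange term below). Concentrations obey an
advection–diffusion equation with a Michaelis–Menten oxygen sink in the
cell-chamber cells:

    R(c) = -VO2max * rho_cell * c / (Km*S_cell + c)

with VO2max = 1.04e-16 mol/s/cell (0.104 nmol/s per 10⁶ cells, matching
the Seahorse-measured OCR of 0.1), Km = 5.6 mmHg and
S_cell = 1.049 mM/atm, i.e. a half-saturation concentration
Km·S_cell ≈ 7.7 × 10⁻³ mol/m³ (`km_in_concentration_units()`).

Two constitutive choices:

- **Membrane as effective medium.** Straight cylindrical pores give an
  effective diffusivity `porosity × D` and a storage capacity equal to the
  porosity (tortuosity 1).
- **PDMS in media-equivalent units.** The dissolved-gas jump at the
  media–PDMS interface follows Henry's law with partition coefficient
  `k = c_sat,PDMS / c_sat,media = 1.11/0.173 ≈ 6.42`. The solver works in
  media-equivalent concentration u = c_PDMS/k, giving PDMS nodes an
  effective diffusivity `k·D_PDMS` and capacity `k`; partial-pressure and
  flux continuity at the interface then hold automatically, with no
  explicit jump condition.

### Ambient oxygen supply: roof *and* walls

The one place where this package deviates from the obvious 2-D reduction
is the ambient O₂ supply path, and the reason is quantitative. The
chambers are flanked on both sides by PDMS open to the incubator. A 2-D
x–z model that feeds O₂ only through the resolved slab above the channel
under-supplies the tissue badly, for two compounding reasons: (i) in 2-D
the slab has the same width as the channel, whereas in 3-D the slab is
laterally much wider than the 0.56 mm channel and spreads the ambient
supply over a far larger access area; and (ii) every roof-path molecule
must still cross the 5.6 %-porosity membrane to reach the cells. With the
printed uptake parameters, a top-only model settles near 0.04 mol/m³ —
hypoxic, and inconsistent with the device's observed performance.

The side walls bypass the membrane and feed the chambers directly. Width
averaging a lateral boundary flux turns it into a volumetric exchange
term, and the ambient-to-wall access conductance per unit channel length
follows from the classical buried-strip spreading-resistance formula (a
strip of height h at depth t below a fixed-concentration plane, treated as
a cylinder of equivalent radius h/4):

    G' = 2*pi*D_pdms*k / ln(8 t / h)

Each chamber row gains an exchange term `gamma (c_amb - c)` with
`gamma = 2 G'/(W h)` (two walls). The formula contains geometry only — no
fitted constant. With it, the steady cell chamber sits at ≈ 0.166 mol/m³,
periportal-like and within 4 % of the design simulation's 0.16; the
top-only mode is retained as `side_walls = FALSE` for comparison.

### Numerics

First-order upwind advection, central (harmonic-mean) diffusion, implicit
Euler in time with the Michaelis–Menten sink linearized at the previous
state (`s = Vρ/(Km S + c_old)` enters the diagonal). The resulting system
matrix is an M-matrix, so the scheme is unconditionally stable and
positivity-preserving at any dt — oxygen never goes negative, without
clipping. Steady states use Picard iteration on the nonlinearity with a
sparse direct solve per pass (convergence: max relative change < 10⁻⁸,
iteration cap with an informative error). Default mesh: 60 cells along the
channel; 6/3/6/8 cells for chamber/membrane/channel/slab. The steady
cell-chamber mean changes by < 2 % when the mesh is doubled in both
directions (tested).

Mass conservation is checked per time step as the node-summed residual of
the implicit system: interior face fluxes cancel exactly in that sum, so
it equals accumulation minus (boundary flux − uptake) and sits at machine
precision (tested < 10⁻⁸). The steady solver is additionally verified
against an independently written dense direct-solve oracle and, in the
no-flow no-uptake limit, against the exact layered-slab solution.

### The three design simulations

1. **Steady O₂ with gas exchange**: inlet and initial media at
   0.173 mol/m³ (saturation against 18.7 % O₂ incubator gas), PDMS
   surfaces at their saturation (1.11 mM); the cell chamber settles at
   ≈ 0.17 mol/m³.
2. **Hypoxia without gas exchange**: with all PDMS supply removed, the
   ~10⁴ cells exhaust the chamber within minutes; the run reports the
   first time the cell-chamber minimum crosses a hypoxia threshold. The
   threshold is not prescribed anywhere authoritative; the package
   defaults to the Michaelis constant in concentration units
   (≈ 7.7 × 10⁻³ mol/m³), the concentration at which uptake has fallen to
   half-maximal — configurable.
3. **Tracer wash-in**: an inert molecule (D = 10⁻⁹ m²/s) infused at
   20 µL/h into an empty device with impermeable walls; the time to bring
   the cell-chamber minimum to 95 % of the inlet value (≈ 290 s at the
   default mesh, consistent with the ~300 s design figure).

Because the model is width-averaged and the simulations that motivated the
device were 3-D, the steady-oxygen acceptance band is ±15 %.

## 2. Cardiac action-potential metrics

`segment_beats()` detrends with a rolling-percentile baseline (10th
percentile, 1.5 s window; a window larger than the trace degrades to a
constant global baseline), detects upstrokes as threshold crossings at
50 % of the robust amplitude with a 0.25 s refractory period, and takes
the **maximum-derivative point as the activation reference** (the
50 %-upstroke alternative is selectable). The diastolic baseline of each
beat is the median of the last 10 % of the preceding diastolic interval —
robust to drift.

`apd(level)` measures from activation to the first crossing of
`amplitude × (1 − level/100)` on the repolarizing flank, with linear
interpolation between samples — at a 100 Hz optical sampling rate the
10 ms frame period would otherwise quantize every duration. A beat that
never repolarizes to the requested level inside its window yields a
flagged `NA`, not an error.

The rate correction is Fridericia's cube-root law with RR in seconds,
`cAPD = APD / RR^(1/3)`, so 60 BPM is the identity — the exponent and
units follow the QTc convention, the natural reading for an in vitro QTc
surrogate. Triangulation is `(cAPD80 − cAPD30)/cAPD80`; `capd30 > capd80`
is rejected as a segmentation failure rather than silently producing a
negative metric.

**Hill fits.** "Three parameters" is read as EC₅₀ plus the two asymptotes
with the slope fixed at 1; `slope = "free"` gives the four-parameter form.
For a fixed slope the model is linear in the asymptotes, so the fit
profiles them out by a linear solve and optimizes only log₁₀(EC₅₀) — a
1-D, derivative-free, start-value-free search that cannot diverge. Flat
response ranges return a `no_fit` flag. The margin of safety is
EC₅₀/ETPC: 9.63/2.6 ≈ 3.7-fold at the lower ETPC bound (1.97-fold at the
upper).

## 3. Contraction motion tracking

`block_match()` is the definitional exhaustive search: every integer
displacement within the search radius is scored (SAD by default, SSD
selectable) and the global minimum is returned, ties broken by smaller
displacement magnitude then lexicographically. The recording convention
this supports compares 8 × 8 px macroblocks at frame i with frame i+5 —
50 ms at the 100 Hz default, though neither is hard-coded. The search
radius is not documented in the source material; the default is ±7 px,
configurable. Blocks are tiled without overlap by default (stride =
block size); low-texture blocks (variance below threshold) emit invalid
vectors rather than noise. A true shift beyond the radius clamps at the
window edge and is flagged. The kernel is compiled (Rcpp); a brute-force
R implementation in the test helpers serves as its oracle, including
tie-break order.

Beat rate: each beat contributes two motion strokes (contraction and
relaxation). Because displacements are whole pixels, one stroke can
arrive as several short speed bumps; `beat_rate_from_motion()` therefore
clusters above-threshold episodes separated by < 0.3 s into strokes,
pairs successive strokes into beats, and returns 60 / median inter-beat
interval. Fewer than two strokes (a static video) gives `NA` with a
warning.

## 4. PDMS dose correction

PDMS absorbs small lipophilic molecules; the measured dose-escalation
table (percent remaining 35.52/30.54/30.95/34.55/39.79 % at
10–1000 nM) and the fixed 64 % absorbed fraction used for the
dose-response analyses are both exposed and never mixed silently.
Interpolation is linear in log-dose (the table spans two decades), with a
nearest-key mode for exact reproduction. Note a deliberate rounding
mismatch kept visible: 50 nM × 0.36 = 18 nM, while the coupled
experiments describe the same arm as "17 nM" — the exact fraction behind
that figure is not recoverable, so both printed numbers are preserved and
the tests accept the ±1.5 nM discrepancy.

## 5. Liver metabolism stage

The measured conversion series (2.66/6.19/9.33 % at 3/6/24 h) is visibly
sub-first-order — no single rate constant fits it — so the stage uses a
saturating-exponential fraction metabolized scaled by a competitive
inhibition factor (ketoconazole is a competitive CYP3A4 inhibitor; no
kinetic law is prescribed by the source data):

    f(t) = A * (1 - exp(-t/tau)) / (1 + I/Ki)

`calibrate_metabolism()` fits (A, τ, Ki) by bounded least squares with A
profiled out analytically and a deterministic multi-start over (τ, Ki);
an independent refining grid search agrees with the optimizer to < 1 % on
the observed series (tested). At the fitted Ki (≈ 3.7 µM) the competitive
factor at 10 µM ketoconazole is ≈ 0.27, consistent within ±0.10 with the
~0.35 relative clearance seen in the 30-min assays, and with the
printed 68 % reduction of 3-h conversion. (Arithmetic on the printed 6-h
means gives an 84 % reduction where 85 % is quoted; the tests pin the 3-h
value only.) Mass balance — parent out plus metabolized equals dose in —
holds by construction and is asserted.

## 6. The coupled DDI pipeline

`run_ddi()` evaluates three arms from one configuration: the
PDMS-corrected dose applied directly to the cardiac stage; the same dose
passed through the liver stage; and the liver stage with 10 µM
ketoconazole. Each effective dose maps through a Hill curve for the
normalized cAPD₉₀, and an arm is flagged when the predicted increase over
vehicle exceeds a threshold (default 10 % — a threshold on predicted
effect, because the model arms carry no biological replicates; when real
trace sets are available, `compare_to_vehicle()` applies the standard
two-sample test instead).

Two parameter choices here were genuinely open and are the package's own:

- **Liver-stage kinetics** (`mps_liver_kinetics()`). The dish-calibrated
  kinetics (§5) describe static 2-D cultures with a large media excess and
  do not transfer to the perfused chip, which holds its ~10⁴ cells against
  a 0.32 µL channel — a first-pass organ in miniature. Its defaults are
  set once, from chip-level evidence: extraction plateau 95 % with a 2 h
  time constant (≈ 93 % of parent cleared over the 8-h perfusion,
  consistent with the observed complete loss of the cardiac signal in the
  uninhibited coupled arm and with cisapride's extensive first-pass
  N-dealkylation in vivo), and Ki from the chip's own CYP3A4 luminescence
  assay: the seven-fold drop under 10 µM ketoconazole gives an inhibition
  factor 361/2640 ≈ 0.137, i.e. Ki ≈ 1.58 µM. Nothing here is fitted to
  the cardiac outcome the pipeline predicts.
- **Cardiac Emax.** The saturating normalized cAPD₉₀ is set to 1.5 — a
  ~50 % prolongation at saturating dose, typical of strong hERG-mediated
  responses in engineered cardiac tissue. The flags are robust to this
  choice: they are driven by effective doses on opposite sides of the
  EC₅₀ (18 and 15.7 nM versus 1.2 nM).

Configurations never default kinetics silently — omitting `metabolism` or
`hill` is a configuration error. Reports carry the provenance of each
parameter so constants of different origins (the 64 % absorption constant
versus the measured table; dish- versus chip-level kinetics) cannot be
mixed unnoticed.

## 7. Synthetic data: the stated world

Every analysis input has a generator with exact ground truth:

- `make_ap_trace()` — a half-cosine upstroke (maximum derivative at its
  midpoint, the activation reference) and a repolarizing flank built as a
  monotone cubic through the three specified crossing points, so
  APD₃₀/₈₀/₉₀ are exact by construction, plus linear drift and Gaussian
  noise. Defaults: 30 BPM, 200/350/400 ms, 100 Hz.
- `make_contraction_video()` — a smoothed random texture rigidly
  translated by `amplitude · sin²(πt/period)`, rounded to whole pixels per
  frame; the truth series is returned. Defaults: 64 × 64 px, 3 px
  amplitude, 2 s period (30 BPM).
- `make_dose_response()` — Hill means with multiplicative Gaussian noise
  (5 % CV, 6 doses, 4 replicates by default).

All generators are pure functions of (spec, seed): byte-identical reruns,
no global RNG state disturbed. What a green round-trip test establishes
is that the metrics recover *constructed* truth within the documented
tolerances (one sample period for APDs, ±1 BPM for rates, 10 % for a
noisy EC₅₀ median). What it does not establish: robustness to motion
artifacts, photobleaching beyond linear drift, non-rigid deformation,
optical blur, or arrhythmic beat-to-beat variability — none of which the
generators emulate.

## 8. Known limitations

- The transport model is width-averaged; the wall-exchange conductance is
  a spreading-resistance estimate, not a resolved 3-D solve. The ±15 %
  band on the steady-oxygen benchmark reflects this.
- The printed cell density (6.44 × 10¹³ m⁻³) and the counted cell number
  (9,812) disagree by about a factor 2 for the stated chamber volume; the
  package takes both as given and uses the density in the sink term, the
  count for whole-chip budgets.
- The printed media-channel fill volume (0.32 µL) exceeds
  length × width × height (0.311 µL); the geometry reproduces the
  dimensions, not the rounded volume.
- The liver stage is a single well-mixed compartment: no transporter
  kinetics, no conjugation, no intra-chip concentration gradients.
- The motion tracker reports whole-pixel vectors (no sub-pixel
  refinement, no strain mapping), matching its exhaustive-search
  definition.
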