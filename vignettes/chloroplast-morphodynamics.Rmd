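---
title: "Modeling and measuring light-driven chloroplast morphodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and measuring light-driven chloroplast morphodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidyn)
```

The dinoflagellate *Pyrocystis lunula* carries a single reticulated
chloroplast — a net of cytoplasmic strands with junctions — that retracts
toward the cytoplasmic core under strong light (photoavoidance) and
re-expands under dim light (photoaccumulation), all inside a rigid cell
wall. `plastidyn` implements both halves of the quantitative story: a
dynamical model of the projected-area response to light, and the image
pipeline that extracts area, network structure, topology and node
kinematics from brightfield and confocal time series. A seeded synthetic
generator reproduces every data modality with known ground truth, so each
stage of the pipeline is testable end to end.

## The two-sensor viscoelastic model

The relative projected chloroplast area is `A(t)/A0 = 1 - x(t)`, where
`x` is the relative contraction. `x` relaxes like a Kelvin–Voigt element
toward an enforced position `p(t)`:

    tau * dx/dt + x = p(t),

with an asymmetric timescale: `tau = tau_kv` while contracting
(`p > x`) and `tau = tau_kv_star` while expanding (`p < x`). The branch
is chosen from the sign of `p - x` at each integration step; no
hysteresis is modeled, because the sign of `dx/dt` is exactly the sign
of `p - x`.

The enforced position integrates two photosensory signals, each a
first-order process `tau_i * dc_i/dt + c_i = s_i(I)`:

* an **avoidance sensor**, `s1 = alpha1 * I`, active at all irradiances;
* a **repressor**, `s2 = alpha2 * H(i_th - I)`, active only below the
  threshold irradiance `i_th` (`H(I >= i_th) = 0`, `H(I < i_th) = 1`).

The net drive is `p = beta * (c1 - c2)`, clipped below at zero (the
chloroplast cannot contract "negatively") and capped at `x_max` — the
fraction of the projected area outside the cytoplasmic core, which the
chloroplast cannot vacate. Both bounds are physical, not numerical.

### Parameters, units and defaults

| parameter | meaning | default | unit |
|---|---|---|---|
| `tau_kv` | contraction response time | 2.25 | min |
| `tau_kv_star` | expansion response time | 7.2 | min |
| `tau1` | avoidance-sensor signaling time | 1.74 | min |
| `tau2` | repressor signaling time | 1.76 | min |
| `alpha1` | avoidance gain | 1/30 | (mW/cm²)⁻¹ |
| `alpha2` | repressor amplitude | 0.08 | – |
| `beta` | extension per unit net signal | 1 | – |
| `i_th` | repressor threshold | 2.8 | mW/cm² |
| `x_max` | contraction cap (core bound) | 0.4 | – |

The four time constants are population-mean estimates from dynamic
light-stimulation experiments on *P. lunula* ([`lunula_params()`], with
per-cell spreads in [`lunula_param_spread()`]). The sensory gains are not printed anywhere,
so they are calibrated once from the reported steady-state behavior and
then frozen:

* `beta * alpha1 = 1/30`, so the steady state `x_ss = I/30` reaches the
  `x_max = 0.4` cap exactly at 12 mW/cm² — the irradiance beyond which
  the maximal area reduction saturates at ≈40%, and below which it grows
  gradually (the dose–response regime).
* `i_th = 2.8` mW/cm², the upper end of the bracketed threshold range,
  so that a 2.8 mW/cm² stimulus is unrepressed, as observed.
* `alpha2 = 0.08`, large enough that sub-threshold traces carry usable
  information about `tau2` while keeping the repressed steady state at
  full expansion (`beta*(alpha1*I - alpha2) < 0` for dim light).

Initial conditions default to the dark-adapted rest state `x = 0`,
`c1 = 0`, `c2 = alpha2` (cultures are kept under very dim light, which
is below threshold, so the repressor sits at its saturated level). Two
analyses need a different start and say so explicitly: the relaxation
design starts from a strong-light-adapted state, and the sub-threshold
transient uses a repressor-naive cell (`c2_0 = 0`, as after strong-light
pre-exposure where `s2 = 0`). With the default dark-adapted start and
`tau1 ≈ tau2`, no visible sub-threshold transient exists — an honest
limitation of the fitted parameter set rather than of the solver; the
transient property is therefore exercised with `tau2 > tau1`, the regime
in which the two-sensor mechanism produces it.

### Numerics

`simulate_response()` integrates the single mechanical ODE with
classical RK4 at `dt = min(all time constants)/50` (a warning fires
beyond `min(tau)/10`); the sensor signals are piecewise-exponential and
evaluated exactly on the half-step grid, so signaling accuracy does not
depend on `dt`. `constant_light_solution()` solves the same equations
in closed form, propagating analytically between events (clip-state
crossings of the unimodal bi-exponential drive, contraction/expansion
switches) located by bracketed root-finding; coincident time constants
use the degenerate `t*exp(-t/tau)` form. The two routes agree to below
1e-5 over random parameter draws, which is the package's primary solver
check.

### Filtering, fitting and derived statistics

Above threshold the light-to-area chain is two first-order stages in
series, so the DC-normalized gain is
`|H(w)| = [(1 + w^2 tau1^2)(1 + w^2 tau_kv^2)]^(-1/2)`
(`transfer_magnitude()`), and `cutoff_frequency()` solves
`|H|^2 = 1/2` by bisection — about 0.32 min⁻¹ at the default
parameters, the scale separating surface-wave flicker (ignored) from
cloud-cover changes (followed). The asymmetric element makes the true
periodic response mildly nonlinear; the gain formula describes the
symmetric linearization, which is how it is tested.

`fit_trace()` minimizes the unweighted sum of squared residuals between
the simulated and measured `A(t)/A0` (Levenberg–Marquardt on
log-transformed time constants, box bounds 0.3–60 min). Uncertainty
comes from an optional residual bootstrap (200 resamples by default in
the orchestration layer; 0 in direct calls, where the caller decides).
A trace whose range does not exceed 1.5 times its first-difference noise
floor is flagged degenerate and returns `NA` rather than a spurious
estimate. `recovery_study()` packages the four standard simulation
designs (strong-light contraction for `tau_kv`/`tau1`, dim-light
relaxation for `tau_kv_star`, just-sub-threshold transient for `tau2`)
with 5% multiplicative noise. At the fitted `tau1 ≈ tau2` the `tau2`
design is intrinsically weakly identified: the sub-threshold signal
amplitude is capped by `beta*alpha1*i_th ≈ 0.09`, and the Fisher
information bounds the scatter of a 6-trace mean at roughly ±0.5 min
regardless of design choices; the 42-trace variant narrows this to
about ±0.2 min.

`dose_response()` computes per-trace maximal contraction and its
Pearson correlation with irradiance; `estimate_signal_diffusion()` is
the order-of-magnitude estimate `D = L^2/tau` for the fast internal
signal implied by whole-cell responses to local stimulation.

## The synthetic generator

The generator is first-class, tested code; everything downstream is
validated against it.

* `make_cell_geometry()` builds the crescent cell as the difference of
  two equal discs (closed-form area available for testing) with an
  embedded convex core ellipse grown by bisection to a requested area
  fraction; the default `core_fraction = 0.6` leaves exactly the
  observed 40% of vacatable area. Fractions beyond what an inscribed
  ellipse can reach in a concave crescent (≈0.8) switch to peeling the
  outline, trading convexity for the fraction contract.
* `sample_reticulum()` draws well-separated nodes outside the core
  interior and connects k-nearest neighbors under a metric that shrinks
  the major-axis coordinate by `1 + axis_bias`, plus a spanning tree —
  long edges along the cell axis, cycles from the extra neighbors.
* `motion_field()`/`advect_network()` implement the kinematic
  contraction: exact affine flow `pos -> center + (pos-center)e^(-k dt)`
  (speed = strain rate × distance) with Brownian jitter applied only
  inside the core, reproducing the ballistic-rim/diffusive-core
  dichotomy. The default `strain_rate = 0.35 min^-1` puts peripheral
  node speeds near 30 µm/min on a default-size cell, matching the
  reported maximum. The graph never rewires, so `beta1` is constant by
  construction.
* `render_confocal_series()` rasterizes tubes around the edges,
  attenuates slices by the Beer–Lambert factor `exp(-z/lambda)` and adds
  detector background plus Gaussian noise. `render_brightfield_series()`
  shrinks the absorbing region concentrically toward the core so its
  pixel count tracks a driving `A(t)/A0` trace exactly.
* `simulate_area_trace()` adds multiplicative Gaussian noise to model
  output — segmentation noise scales with the measured area, unlike the
  additive detector noise of the confocal render.

What the generator does **not** emulate: strand thickening and material
flow along tubes, optics (no PSF), bleaching, multi-cell fields, and
any mechanical coupling between strands (contraction is kinematic, not
force-based). Passing tests therefore validate the pipeline's
measurement logic, not biological mechanics.

## The measurement pipelines

**Brightfield.** `generate_roi()` (Gaussian smoothing, triangle
threshold, disk closing, largest component), `background_threshold()`
(background mean − 1 SD), `area_trace()` (dark-pixel count per frame,
threshold fixed at t = 0 so a drifting threshold cannot confound the
dynamics), `loss_trace()` (`(Ibg − I)/(Ibg − I(0))`, with `I` the ROI
*mean*, making the loss ratio ROI-size independent). The published
kernel sizes (21 px smoothing, 51 px disk) correspond to the original
acquisition pixel pitch; both are arguments, and the tests use the
equivalents at the generator's 0.5 µm/px raster. One structural caveat
worth knowing: with a Gaussian background, the mean − 1 SD rule counts
Φ(−1) ≈ 16% of vacated ROI pixels as chloroplast, inflating late-time
areas by up to `0.16 (1 − A/A0)`; the round-trip test pins the exact
bookkeeping on a clean background and bounds the noisy case by that
envelope.

**Confocal.** `fit_depth_attenuation()` fits the plane-mean profile to
`b + I0 exp(-z/lambda)` — the constant absorbs detector background,
which does not attenuate — and flags non-decaying profiles
(`lambda = Inf` sentinel, identity correction). The fit is exact on
clean exponential data and assumes depth-uniform structure occupancy;
profiles dominated by where the specimen sits in z, not by attenuation,
will bias it, so the orchestration fits the first frame only and reuses
the result. `segment_volume()` applies the fixed stage order: per-slice
1 px Gaussian blur → white top-hat with a (2.8, 2.8, 1) µm half-extent
ellipsoid → triangle threshold → (1, 1, 1) µm binary closing →
26-connectivity labeling → size filter. "1 px" is read as the Gaussian
SD, the µm triplets as per-axis half-extents converted to voxels, and
the <20,000 px label filter counts voxels of the acquired grid; all are
arguments (down-sampled synthetic volumes use proportionally smaller
`min_voxels`). `mask_topology()` counts the Euler characteristic on the
cubical complex of closed voxels (foreground 26-adjacency, complement
6-adjacency) and reports the printed convention `g = 1 - chi/2`; the
alternative `g = 1 - chi` sits behind a flag because the two printed
genus routes (mask χ and graph `beta1/2`) disagree by a factor on
simple phantoms — a filled annulus gives `g = 1` from χ but 0.5 from
its skeleton's cycle rank. The discrepancy is surfaced, not resolved.

**Graph.** `skeletonize_to_graph()` thins the mask by sequential
simple-point removal (a voxel is deletable iff it has exactly one
26-connected foreground component in its 26-neighborhood and one
6-connected background component touching it face-wise), peeling
shallowest-first and preserving curve endpoints — topology is preserved
by construction. Junction/end voxels cluster into nodes; degree-2 paths
become edges with geodesic lengths; an isolated cycle becomes one node
with a self-loop so its `beta1` survives. `simplify_graph()` merges the
globally closest node pair under 5 px to its midpoint, recomputing
distances after every merge (the published rule does not fix an order;
closest-pair-first makes the fixpoint deterministic, and clusters of
more than two mutually close nodes resolve by repeated pairwise
merging), prunes end nodes on sub-9 px edges in a single pass, then
dissolves pass-through nodes. Pixel rules use xy-pixel units with z
scaled by the voxel anisotropy. Merging two *adjacent* nodes, pruning
and dissolving all preserve the cycle rank; merging two nodes that are
close in space but connected only through a longer path necessarily
creates a cycle — the same identification ambiguity the original
analysis attributes to strand contact during compaction.

**Dynamics.** `track_nodes()` links frame to frame around
constant-velocity-extrapolated positions inside an anisotropic
(6, 6, 2) µm window, persists unmatched tracks for up to 4 frames, and
resolves conflicts by shrinking the window geometrically to 10% (per
conflict, which is the deterministic reading) before an exhaustive
minimal-total-squared-displacement matching — chosen so the linker is
exactly comparable to a brute-force assignment oracle on small scenes.
`trajectory_velocities()` takes the analytic derivative of local
second-order Savitzky–Golay fits over the odd window nearest 37.5 s
(midpoint of the 30–45 s recipe); it is exact on polynomial paths.
`msd_curve()` implements the standard time-averaged MSD with lags up to
half the trajectory duration; the printed expression omits the
difference-and-square, but only the standard form yields the reported
slopes of 1 (diffusive) and 2 (ballistic). `distance_map()` is a
geodesic (within-mask) distance by converged chamfer sweeps — strands
move along material paths, so Euclidean distance would understate
central distances in curved cells; Euclidean is available by passing no
map. `speed_distance_analysis()` joins speeds with distances into the
strain-rate table, a through-origin regression slope, and a plateau
statistic (relative SD of `v/D` over the upper half of distances).

## Orchestration and reproducibility

`run_synthetic()`, `run_confocal()` and `run_fit()` chain the stages,
log per-stage parameters and object counts, and write a fully resolved
YAML configuration snapshot next to every output, sufficient to
reproduce the run exactly. Configuration is YAML (`load_config()`
merges user values over `default_config()`); all randomness flows from
one top-level seed through fixed per-stage offsets. Volumes travel as
multi-page 16-bit TIFFs with a JSON sidecar for voxel size, frame times
and intensity scale; graphs, traces, trajectories and topology tables
are CSV with documented schemas.

## Problem sizes used in the tests

The suite renders volumes of roughly 100–220 × 50–140 × 12–16 voxels,
tracks 8–25 nodes over 6–13 frames, fits 6–42 simulated traces per
recovery design, and uses 80–100 random walks for MSD statistics —
sizes chosen so the full suite exercises every stage, including two
complete render→segment→graph→track chains, in about a minute on one
CPU. The round-trip topology checks use well-separated tube networks
(radius ≥ 2 voxels, gaps well above the closing kernel), which is the
regime where skeleton-graph recovery is reliable; densely contracted
networks genuinely fuse, and their genus dips during compaction — as in
the source observations — so no test asserts topology recovery there.

## Known limitations

* The solver pair (RK4 + event-driven closed form) assumes
  piecewise-constant light; arbitrary waveforms must be staircased
  (`light_protocol()` takes any segment list, and the sinusoidal tests
  do exactly this).
* `tau2` is weakly identified at realistic noise with the fitted
  parameter set (see above); population means over few traces scatter
  accordingly.
* The attenuation fit conflates depth attenuation with axial occupancy
  if the specimen does not span the fitted z-range uniformly.
* The brightfield area threshold inherits the Φ(−1) background
  misclassification of the published rule.
* Tracking is greedy frame-to-frame with local conflict resolution, not
  a global multi-frame optimization; it matches exhaustive assignment
  on unambiguous scenes and is not designed for dense crossing traffic.
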