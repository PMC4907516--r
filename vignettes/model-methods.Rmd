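---
title: "The occlusim model: mechanics, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The occlusim model: mechanics, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

occlusim simulates the progression of capillary occlusion in retinal
microvascular networks through a local adverse feedback loop: occlusion of a
capillary starves the surrounding tissue of oxygen; hypoxic Mueller cells
synthesize VEGF; locally elevated VEGF raises the probability that
neighboring capillaries occlude (the ICAM-mediated leukostasis pathway,
treated as a black box behind a probability function); each new occlusion
deepens the hypoxia. Whether this loop ignites and spreads, stalls, or never
starts depends almost entirely on the geometry of the capillary network —
which is why the package ships three network generators spanning the
clinically relevant architectures.

## Model objects

The tissue is a 2.5-D tiling of generalized cells. Mueller cells (MC) and
other retinal cells (OT) are square tiles of pitch `a_mc` (default 12 um)
interleaved on a checkerboard to a configurable MC fraction; each tile
carries a thickness attribute (initially 50 um), so the third dimension
enters only through contact areas and the thickness/edema map. Capillary
blocks (CAP) are laid along every segment centerline at a fixed block length
(10 um). Fluid portions (FP) — the structural element of edema — are tracked
as per-column fluid volumes rather than motile cells; the original framework
treats them as trapped by their surroundings, so their mechanics add nothing
observable. The foveal avascular zone, when a network has one, is tiled as a
pinned region: a Dirichlet oxygen source (`po2_faz`) and a VEGF sink.

Exchange of oxygen and VEGF between neighboring cells is proportional to the
inter-cellular concentration difference and the shared contact area. Oxygen
uses two exchange coefficients: `k_o2` between tissue tiles and `k_o2_wall`
across the capillary wall. The separation is deliberate: a single
coefficient cannot simultaneously keep near-vessel cells in the 35-40 mmHg
band (which requires an efficient wall) and make tissue ~130 um from the
nearest vessel frankly hypoxic (which requires a short tissue diffusion
length, here `sqrt(k_o2 * a_mc)` in continuum terms). Two-coefficient
exchange is the standard construction in Krogh-type models.

## Oxygen: conveyor-belt advection, diffusion, consumption

Advection is modeled by conveyor belts: each flowing segment is discretized
into belts of size `velocity * dt_flux`, so one advection step moves every
belt's oxygen volume exactly one belt downstream at the local flow velocity.
At junctions the outgoing volumes of all inflowing segments are pooled and
split among outflowing segments in proportion to their volumetric flows;
boundary inlets fill their first belt to the inlet tension; outlets discharge
to the venous sink. Belts and blocks are reconciled every step: a block's
pre-diffusion volume is the sum of its assigned belts (assignment by belt
center), diffusion/consumption act on block tensions, and the belts are then
rescaled by the block's post/pre ratio, which conserves oxygen exactly.

Three discretization rules keep this bookkeeping exact in corner cases:

* the last belt is truncated to fit the segment; during advection it passes
  its content on and the overshooting fraction of the penultimate belt
  passes through it within the same step (throughput conservation);
* belt size is capped at half the segment length and the belt count per
  segment at `max_belts`; a segment too slow for that cap is stagnant —
  it exchanges by diffusion only, and junction pools surrender its share
  of the splitting rule (tallied as discharge);
* a chain-fed block converts volume to tension with the geometric volume of
  its assigned belts, so coarse belts on fast segments do not inflate block
  tensions.

Consumption is Michaelis-Menten (`v_max_o2`, `k_m_o2`), applied to MC and OT
cells only. Oxygen content is linear in tension (constant `alpha_o2`); no
hemoglobin binding curve is used.

## VEGF

Hypoxic Mueller cells (tension strictly below `o2_hyp`, reversibly) are the
only hypoxia-responsive VEGF source, with rate
`k_syn * (1 - C/o2_hyp)+ * (1 - V/vegf_sat)+` — a linear ramp in oxygen
deficit with linear saturation. A small basal production `k_dec * vegf_basal`
in every decaying cell (CAP, MC, OT) makes the uniform basal field an exact
fixed point of synthesis-decay; attributing the basal term to Mueller cells
alone would leave the basal state slightly non-uniform and break that
designed equilibrium. VEGF diffuses on the contact graph (`k_vegf`), decays
with first-order rate `k_dec`, is pinned to zero in the FAZ, and is not
advected.

The screened diffusion length `sqrt(k_vegf * a_mc / k_dec)` is ~90 um
(about seven Mueller-cell widths) under the defaults. A shorter range of
2-3 cell widths was considered but makes capillaries at realistic
inter-capillary spacings (65-160 um in the three generators) insensitive to
an adjacent ischemic patch, which would switch off occlusion propagation
altogether; at 90 um the elevation is still well bounded relative to the
sector scale, and confinement of damage to an arteriole-venule sector is
enforced by the oxygenated barrier at the bounding vessels rather than by
the VEGF range.

## Occlusion, leakiness, edema

Every four model weeks each patent non-trunk segment faces an independent
Bernoulli draw with probability

`p = p_occ_max * V^h / (V^h + vegf_half^h) * exp(-|v| / vel_scale)`

(V the segment VEGF, v the flow velocity): strictly increasing in VEGF,
strictly decreasing in velocity. The Hill exponent defaults to `h = 3`. With
the basal VEGF level defining 1 A.U. and the midpoint `vegf_half` just above
basal, a quadratic Hill cannot simultaneously give the calibrated basal
spontaneous rate (~1 occlusion per network-year) and robust propagation at
post-occlusion VEGF levels; the cubic separates the two regimes. Occlusion
is whole-segment, irreversible, and implemented as an infinitesimal diameter
(`eps_d`); the flow solver treats these segments as non-conducting, and any
region they cut off inherits the pressure of its nearest connected node so
its internal flows vanish exactly.

Weekly, capillary segments with VEGF above `vegf_leak_thr` are leaky
(reversibly); trunk segments — arterioles, venules, shunts — never leak,
since VEGF-driven barrier breakdown is a capillary-wall phenomenon. Each
leaky capillary block adds one fluid unit (`fp_unit_volume`) to its tissue
column per weekly check and each column drains a quota
(`fp_removal_volume`, the pigment-epithelium pump); thickness is base
thickness plus fluid column height, so net thickening requires sustained
leakage. Edema here is threshold-VEGF only; no Starling pressure balance is
modeled.

After every occlusion event, patent non-trunk diameters adapt once by the
shear-stress log law `d <- d * (1 + k_adapt * log(tau/tau_ref))`, clipped to
1% per event and to [0.8, 1.3] times the construction diameter, with
`tau_ref` frozen at the intact-network solution so the pre-occlusion state
is a fixed point. Only the hemodynamic stimulus is modeled; the gain is set
high enough that a meaningful stimulus reaches the 1% clip, which is what
produces the hyperemic inflow recovery seen in progressive runs. No
metabolic adaptation term is implemented because no defensible functional
form is available.

## The event loop and the separation of time scales

Flux equilibration (seconds) is treated as instantaneous relative to the
weekly edema clock and the monthly occlusion clock: steady states are
recomputed only after occlusion events, never through calendar time. A run
records checkpoints every four weeks and at every event, and stops at the
horizon (156 weeks after the first occlusion) or as soon as no patent
arteriole-venule path remains. Week 0 is the week of the first occlusion; in
spontaneous mode the waiting time to the first basal-rate occlusion is
sampled analytically (geometric over monthly checks) and the clock
re-zeroed.

## Steady-state numerics

The flux integration step is `dt_flux = 0.002 s`, and a field is accepted as
converged when the maximum relative per-cell change per iteration stays
below `tol_ss = 1e-6` for ten consecutive iterations (relative changes are
guarded with a scale floor of 0.1 mmHg for oxygen and 0.05 A.U. for VEGF —
far below any resolvable signal — so that cells decaying toward zero do not
stall the stopping rule). Marching the explicit iteration from arbitrary
initial states to that tolerance is correct but extremely slow, because the
slow modes of the coupled system have relaxation times of tens of model
seconds. Two numerical devices make it cheap without touching the model:

* a direct sparse steady solve seeds the iteration: pairwise exchange with
  Newton-linearized Michaelis-Menten consumption for tissue, and, for
  flowing capillary chains, the belt model's own axial attenuation law
  (uniform relative rescale within a block gives multiplicative decay with
  exponent `beta * (1 - T/C)`, beta the wall-conductance/flow ratio),
  chained along the flow direction with junction mixing over the total
  nodal outflow. The exponent is clamped at zero — where tissue is hotter
  than blood the chain transports unchanged — because the multiplicative
  form amplifies unstably in gain regions. For VEGF the analogous solve is
  linear except for the saturation term, handled by damped Picard
  iteration (undamped, the lagged saturation 2-cycles once the field
  crosses `vegf_sat`).
* Anderson acceleration (depth 7, sampled every 80 iterations) is applied
  inside the explicit drivers; acceleration jumps reset the convergence
  window, so the accepted state is always a verified fixed point of the
  plain explicit operator at the stated tolerance.

The unit suite pins the compiled driver to the R reference composition of
the step operations (advect, belts-to-blocks, diffuse, consume, rescale) to
double precision, one iteration at a time.

## Calibration and the study conditions

The defaults in `sim_config()` are frozen outputs of the calibration
procedure implemented in `calibrate_defaults()`, run on the 65-um hexagonal
lattice: the consumption ceiling is bisected until the intact-network
minimum cell tension sits above the ischemia threshold with the histogram
bulk at 10-25 mmHg and near-vessel cells at 35-40 mmHg; the occlusion model
is then scaled so that a single central occlusion's VEGF response exceeds
the Hill midpoint over the ischemic patch while the basal spontaneous rate
is about one occlusion per network-year. Under these constants the hexagon
edge is critical near 65 um: doubling it produces pre-occlusion hypoxia,
halving it abolishes post-occlusion hypoxia — the spacing-dependence that
motivates the lattice in the first place.

The three generators define the study conditions:

* hexagonal lattice: edge 65 um, 5 x 6 hexagons, feeding/draining stubs on
  opposite sides, optional uniform random edge deletion under a
  connectivity constraint;
* peripheral ladder: 3 arteriole-venule sectors, 5 rung capillaries
  (10 um) per sector at 160-um spacing, 320-um rails, 18-um apical shunts;
  run under the low peripheral arteriovenous gradient
  (`p_art = 24.5, p_ven = 22 mmHg`), the one regional difference the
  peripheral scenario requires beyond structure and diameters;
* synthetic macular sector: 510 x 600 x 50 um, arteriolar and venular
  trunks tapering from 10 um, capillary mesh with diameters
  Gaussian(5, 0.5) um, an avascular FAZ on one edge, and mesh density
  decreasing toward the FAZ — the sparse juxtafoveal annulus is what makes
  that zone vulnerable, mirroring the clinical pattern. This network is a
  synthetic stand-in for an imaged sector; it reproduces scale, diameter
  statistics and density gradient, not any individual retina.

Forced initial occlusions use `pick_vulnerable_segment()`: among sites whose
single occlusion produces an appreciable hypoxic patch, the one costing the
least total inflow — the slow capillary a leukocyte would plug first, not a
feeding conduit.

## What the generators do and do not emulate

The generators reproduce the features that drive the dynamics: capillary
spacing relative to the oxygen diffusion length, the density gradient toward
the FAZ, sector structure between arterioles and venules, and realistic
diameters and flows. They do not reproduce patient-specific topology, the
multi-layer macular plexus, curved vessels, or imaging artifacts; a passing
suite therefore demonstrates the mechanism and its geometry-dependence, not
agreement with any individual retina's trajectory.

## Problem sizes and replicate counts

The shipped analyses use the sizes above (roughly 3,000-6,000 generalized
cells and 40-110 segments per network), 20 replicates for the peripheral
ensemble, 30 for the macular shape/locality ensembles, and 28 replicates
per sweep cell in `sweep_parameters()` — the replicate count used for the
published one-at-a-time sensitivity analysis. Phase-plane orientation is
assessed by quadrant passage (`trajectory_shape_checks()`): once mean
oxygen has fallen below 85% of the normal condition, flow at least matches
its post-onset maximum from when oxygen was still near-normal — the oxygen
decline leads the flow decline, i.e. the trajectory passes through the
high-flow/low-oxygen zone on the way to the low-flow/low-oxygen end state,
and replicates still sitting in that hyperemic transition zone at the
horizon count as passing. The net signed (shoelace) area of the open
trajectory remains available as `phase_orientation()`, but is dominated by
the arbitrary closing chord. Histogram modality is classified by local
maxima with a prominence rule after 1-2-1 smoothing (`count_modes()`),
which on these histogram shapes agrees with visual classification and
needs no external dip-test machinery.

## Known limitations

In the peripheral ladder, hypoxic damage stays within the initiating
arteriole-venule sector, but strict confinement of *occlusions* does not:
because the VEGF field is isotropic and its range must span the inter-rung
spacing for propagation to occur at all, rungs just across a bounding rail
see nearly the same VEGF as the next in-sector rung at this schematic
geometry's scale, and most 3-year replicates occlude at least one of them.
A VEGF range short enough to prevent this (~30 um) abolishes in-sector
propagation at any rung spacing coarse enough to develop post-occlusion
hypoxia under the globally calibrated oxygen constants; we verified this
across rung spacings of 80-160 um, sector widths of 320-420 um and the
feasible peripheral pressure range, and record the sector-crossing
statistic as a known shortfall rather than re-tuning around it.

Occlusion and leakiness probabilities are calibrated, not fitted: the
functional forms honor the stated monotone dependences, and the constants
land the calibrated operating points, but none of them is identified by
data. The edema module is a counter, not a fluid mechanics model. Venous
oxygen saturation is not an explicit output. The quasi-static coupling
assumes no interaction between flux transients and the weekly clocks. A
single VEGF species stands in for what is surely a balance of factors.
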