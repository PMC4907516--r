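# occlusim

Mechanistic simulation of progressive capillary occlusion in retinal
microvascular networks.

Contiguous areas of capillary loss are a hallmark of diabetic retinopathy,
in the macula (with edema) and in the retinal periphery (without). Purely
random capillary occlusion cannot produce contiguous ischemic fields, so the
occlusion of one capillary must raise the odds that its neighbors occlude.
`occlusim` implements that adverse feedback loop as an event-driven network
simulator for researchers studying ischemia propagation, and reproduces the
regional phenotypes from nothing but network geometry:

* **Hemodynamics** — Poiseuille flow on the vessel graph, conductance
  g = pi d^4 / (128 mu L), sparse direct solve, shear-log diameter
  adaptation after every occlusion.
* **Oxygen** — "conveyor-belt" advection (belt size = v dt, one belt
  shift per step, flow-proportional splitting at junctions), pairwise
  contact-area diffusion on the generalized-cell tiling, Michaelis-Menten
  consumption in Mueller (MC) and other retinal (OT) cells.
* **VEGF** — synthesized by hypoxic Mueller cells at rate
  k_syn (1 - C/C_hyp)+ (1 - V/V_sat)+, diffusing with first-order decay,
  FAZ as sink.
* **Pathology** — monthly per-segment occlusion draws with
  p = p_max V^h / (V^h + V_half^h) exp(-|v|/v_scale) (VEGF raises, flow
  protects); weekly VEGF-threshold leakiness driving an edema/thickness
  map; occlusion irreversible.

Three built-in generators emulate the canonical architectures: a 65-um
hexagonal lattice with random deletions (the spacing-criticality testbed), a
far-peripheral arteriole-venule "ladder" with 18-um shunts and 10-um rung
capillaries, and a synthetic 510 x 600 um juxtafoveal sector with an
avascular FAZ and capillary density decreasing toward it.

## Worked example

A progressive macular run: forced initial occlusion at the most vulnerable
juxtafoveal capillary, 156 model weeks.

```r
library(occlusim)
sc <- macular_scenario(network_seed = 1)
cfg <- sc$config; cfg$seed <- 4L
tr <- run_simulation(sc$network, cfg, first_occlusion = sc$forced_site)
print(tr)
#> <trajectory> 41 checkpoints, 20 occlusions
#>   final week 156: inflow 2.81e+05 (78% of baseline), hypoxic MC 12.8%

round(100 * tr$checkpoints$total_inflow / tr$checkpoints$total_inflow[1])
#>  [1] 100  95  94  94  94  94  94  94  94  94  87  87  87  87  88  88  90
#> [18]  91  91  92  76  76  76  76  76  76  77  77  77  77  78  75  76  77
#> [35]  77  77  77  77  77  78  78

trajectory_shape_checks(tr)
#>     rise_then_fall      dmin_monotone bimodal_transition          clockwise
#>               TRUE               TRUE               TRUE              FALSE
```

Reading the output: total inflow first falls with the initial occlusion,
recovers through capillary dilation (the hyperemic phase), then collapses
below 90% of baseline as the cascade severs flow paths; the mean
Mueller-cell distance to the nearest patent vessel rises monotonically; the
cellular oxygen histogram goes from unimodal (all cells around 10-40 mmHg)
to bimodal (an ischemic mass near zero beside the surviving peak), with
mean retinal thickness up 4.1% from edema at the lesion margin. The fourth
signature — clockwise flow-oxygen phase passage, oxygen decline leading the
flow decline — varies replicate to replicate (this seed collapses flow and
oxygen together); across a 30-replicate ensemble the majority of
progressive runs shows it.
`run_ensemble()` repeats this over replicate RNG streams and summarizes
per-segment patency frequencies (the patency map), progressive
classification by the 75% rule, and the phase-diagram table;
`sweep_parameters()` adds the one-at-a-time sensitivity harness
(28 replicates per grid cell by default).

A command-line front end with `generate`, `run`, `ensemble` and `sweep`
subcommands is installed at `inst/cli/occlusim.R`.

See the vignette (`vignettes/model-methods.Rmd`) for the model description,
the calibration procedure behind the defaults, and numerical choices.

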