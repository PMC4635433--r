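# carbotrace

Traceable decomposition of terrestrial carbon storage capacity for a
13-pool compartmental carbon-cycle model.

## The problem

Terrestrial biosphere models disagree widely on how much carbon land
ecosystems can store, and much of that disagreement traces to carbon
*residence time* rather than to productivity. `carbotrace` implements a
traceability framework that factors the equilibrium carbon stock of an
ecosystem into three independently inspectable components:

```
C_st = NPP × τ_E          with   τ_E = τ'_E / ξ ,   ξ = ξ_t · ξ_w
```

* **NPP** — net primary productivity, the carbon influx *U* (gC m⁻² yr⁻¹);
* **τ′_E** — the *baseline* residence time (yr), set purely by carbon
  allocation (vector **B**), the transfer topology between pools
  (matrix **A**) and the potential turnover rates (diagonal matrix **C**);
* **ξ** — the environmental scalar in [0, 1], the product of a
  soil-temperature scalar ξ_t and a soil-moisture scalar ξ_w, which slows
  decomposition of litter and soil pools (vegetation pools are unscaled).

The pool model is the linear compartmental system

```
dX/dt = B·U − A·ξ·C·X
```

with 13 pools: 4 vegetation (leaf, woody, fine root, coarse root), 5
litter (surface/soil metabolic and structural, coarse detritus) and 4
soil (surface/soil microbe, slow, passive). The steady state is solved
semi-analytically, `X = (A·ξ·C)⁻¹·B·U`, instead of integrating for
millennia; an explicit-Euler forward integrator is included as an
independent oracle. Litter routing follows the CENTURY lineage: the
lignin:nitrogen ratio splits fresh litter into metabolic and structural
pools, tissue lignin fractions split structural decay between microbial
and slow soil carbon, and clay/silt content modifies soil-pool routing.

On top of the core decomposition the package provides

* a registry of the temperature/moisture scalar schemes used by major
  terrestrial biosphere models (Lloyd–Taylor and Q10 temperature
  responses; piecewise-with-floor, parabolic and linear moisture
  responses), and a **scheme-swap experiment** that quantifies how much
  structural uncertainty in the scalars propagates into residence time
  and storage;
* an elasticity-style **parameter sensitivity analysis** with the
  |S| > 0.2 sensitivity classification;
* a seeded **synthetic grid generator** (biome map, soil texture, daily
  soil temperature and moisture, annual NPP) with per-biome climate
  envelopes, so the whole pipeline runs with no external data.

## Worked example

Decompose storage for a tropical evergreen broadleaf forest (EBF) cell
with the shipped defaults, temperature scalar 0.69 and moisture scalar
0.53:

```r
library(carbotrace)
sys <- transfer_system(default_parameter_table()[["EBF"]],
                       default_soil_texture())
trace_cell(sys, xi_t = 0.69, xi_w = 0.53, npp = 1325.7)
#> <traceability_result>
#>  NPP 1325.7 gC/m2/yr x tau_E 26.13 yr = 34637.8 gC/m2 (34.64 kgC/m2)
#>  tau_E = tau_baseline 16.40 yr / xi; xi product 0.366, implied ratio 0.628
```

Read: of the 26.1-year residence time, 16.4 years are structural
(allocation/turnover) and the rest is environmental limitation
(ξ = 0.69 × 0.53 ≈ 0.37 on litter and soil pools). The *implied* ratio
τ′/τ (0.628) is larger than the product because the four vegetation
pools carry no environmental limitation.

A full synthetic-grid run and a moisture-scheme swap:

```r
g  <- generate_grid(shape = c(10, 10), seed = 42)
tr <- trace_grid(g)
tr
#> <trace_result 100 cells; schemes T=beps W=beps>
#>  mean NPP 528.5 gC/m2/yr, mean tau_E 20.3 yr, mean storage 13.0 kgC/m2

run_swap(g, swap = "moisture")
#> <swap_experiment swap=moisture: T beps->beps, W beps->cable>
#>  global mean |d xi_t| 0.000, |d xi_w| 0.214
#>  global mean storage change 14.3%; 0.0% of cells changed > 100%
```

Swapping only the moisture scalar changes the mean moisture limitation
by 0.214 and mean storage by 14.3% on this small synthetic grid — the
moisture scheme, not the temperature scheme, is where scalar structure
matters (a temperature-only swap moves ξ_t by an order of magnitude
less; try `swap = "temperature"`).

Command-line interface (same functionality):

```sh
Rscript inst/cli/carbotrace synth --seed 1 --rows 20 --cols 20 --out grid/
Rscript inst/cli/carbotrace run --grid grid/ --out run/
Rscript inst/cli/carbotrace compare-scalars --grid grid/ --swap moisture --out cmp/
Rscript inst/cli/carbotrace sensitivity --out sens/
```

Each run echoes its configuration to `config.json` and a `run.log` into
the output directory; identical config + seed reproduces byte-identical
CSVs.

## Documentation

The methods vignette (`vignettes/traceability.Rmd`) documents the model
assumptions, all tunable constants and their defaults, what the
synthetic generator does and does not emulate, and the numerical and
design choices.
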