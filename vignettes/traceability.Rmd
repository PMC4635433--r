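---
title: "Tracing carbon storage capacity: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing carbon storage capacity: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbotrace)
```

## The model and its assumptions

`carbotrace` treats an ecosystem's carbon cycle as a linear compartmental
system of 13 pools,

$$\frac{dX}{dt} = B\,U - A\,\xi\,C\,X,$$

where $X$ is the vector of pool stocks (gC m⁻²), $U$ is the carbon influx
(NPP, gC m⁻² yr⁻¹), $B$ allocates influx to the four vegetation pools, $A$
routes carbon between pools (with respiration as the unrouted remainder of
each donor column), $C$ holds potential turnover rates (yr⁻¹) and $\xi$ is
the diagonal environmental scalar. At equilibrium
$X = (A\xi C)^{-1} B U$, so the total stock factors exactly as

$$C_{st} = \mathrm{NPP} \times \tau_E, \qquad
  \tau_E = \mathbf{1}^\top (A\xi C)^{-1} B,$$

and $\tau_E$ further decomposes into the baseline residence time
$\tau'_E$ (the same sum with $\xi = I$) and the environmental limitation.

Assumptions worth stating explicitly:

* **Linearity.** Turnover is first-order in pool size; there is no
  microbial saturation, priming or nutrient feedback. This is what makes
  the semi-analytical steady state and the clean three-way factorisation
  possible.
* **Equilibrium ("spin-up") hypothesis.** All reported stocks and
  residence times are steady-state quantities under a repeating climate
  year. Transient attribution is out of scope.
* **Diagnostic-model stance.** NPP is an *input*, as in models driven by
  satellite canopy state; the package does not simulate photosynthesis,
  phenology or mortality, and vegetation-pool turnover is prescribed, not
  climate-limited. Consequently the $\xi$ diagonal is
  $(1, 1, 1, 1, \xi_5, \dots, \xi_{13})$: only litter and soil pools feel
  temperature and moisture.
* **No CO₂ fertilisation or nitrogen-deposition effects.**

## Pool structure and the transfer matrix

Pools 1–4 are vegetation (leaf, woody, fine root, coarse root), 5–9
litter (surface metabolic, surface structural, soil metabolic, soil
structural, coarse detritus), 10–13 soil organic matter (surface
microbe, soil microbe, slow, passive). Routing follows the CENTURY
lineage:

* Fresh leaf and fine-root litter splits metabolic/structural by the
  lignin:nitrogen ratio, $f_{met} = \mathrm{clamp}(0.85 - 0.018\,L/N,\,
  0,\,1)$. Woody and coarse-root turnover routes entirely to coarse
  detritus.
* Structural and coarse-detritus decay splits a lignin share (fraction
  $0.7 \cdot L_{tissue}$, to the slow pool) from a non-lignin share
  (0.45–0.55 of the non-lignin flux, to the microbial pools);
  metabolic litter transfers 0.45 to microbes.
* Soil-microbe routing carries the texture modifiers: respired fraction
  $0.85 - 0.68\,(clay+silt)$, passive stabilisation $0.003 + 0.032\,clay$
  (from the slow pool, $0.003 + 0.009\,clay$); the slow pool transfers
  0.45 onward; the passive pool transfers 0.45 of its (tiny) outflux back
  to microbes.

The equations behind these coefficients are standard CENTURY-family
values; where the primary sources leave a choice (exact coefficients of
the clay/silt modifiers, whether surface-structural litter also feeds the
slow pool directly) we fixed one defensible form and verify its
invariants — unit diagonal, non-positive off-diagonals, routed column
sums ≤ 1, carbon conservation per donor — by property tests rather than
trusting the constants. $A$ depends only on chemistry and texture, $C$
only on the biome: all climate dependence is in $\xi$.

## Environmental scalar schemes

Temperature:

* **Lloyd–Taylor** (default): $\exp[E_0(1/(T_{ref}-T_0) - 1/(T-T_0))]$
  with the published constants $E_0 = 308.56$ K, $T_0 = 227.13$ K,
  normalised to 1 at $T_{ref} = 10$ °C and clamped to [0, 1]. Below the
  $-46$ °C singularity the scalar is 0 (with a warning).
* **Q10**: $Q_{10}^{(T - T_{ref})/10}$, default $Q_{10} = 2$,
  $T_{ref} = 10$ °C, clamped to [0, 1].

Both being normalised at the same reference, their disagreement is
largest in the cold and shrinks as soil warms — the property tests assert
this convergence over 0–30 °C.

Moisture:

* **Piecewise with floor** (default; the scheme of porosity-normalising
  models): a function of relative water content $k = \theta/\phi$, rising
  linearly from a floor of 0.25 at $k = 0$ to 1 at the optimum
  $k_{opt} = 0.75$, then declining linearly to 0.5 at saturation. The
  paper-stated elements are the variable $k$, the piecewise ("subsection")
  structure and the 0.25 floor; the optimum and the saturated value are
  package defaults, configurable per call.
* **Parabolic** (single smooth function of saturation fraction):
  $1 - ((\theta_1 - 0.6)/1.2)^2$. The optimum 0.6 is a conventional
  aeration optimum; the half-width 1.2 was chosen so the curve's slope
  stays below 1, which a 0.001-step continuity sweep then bounds at a
  jump of $10^{-3}$ — a deliberately gentle parabola, normalised to peak
  at 1, with both the dry end (0.75) and saturation (0.889) below the
  optimum.
* **Linear**: $0.25 + 0.75\,W_1$ — this formula is printed in the source
  material and is asserted exactly.

The registry also carries reconstructed stand-ins for the other model
families' scheme pairs (CASA, inTEC, IBIS, ORCHIDEE, DLEM,
CENTURY/daycent), each flagged `provenance = "reconstructed"`: their
published formulas are not reproduced in our source text, so these
entries are shape-faithful placeholders (linear, parabolic or
saturating forms on the declared moisture variable), good enough for
scheme-swap plumbing but not for quantitative claims about those models.
On the synthetic grid, every moisture variable — including the
water-budget ratios — is proxied by relative saturation
$\theta/\phi$, since the grid carries no precipitation or
evapotranspiration.

## Aggregation choices

* **Time.** Daily scalars are averaged to annual means before the single
  steady-state solve, consistent with the equilibrium hypothesis
  (`xi_aggregation = "annual"`). The alternative — twelve monthly solves
  whose residence times are averaged — is available
  (`xi_aggregation = "monthly"`); because $\tau$ is convex in $\xi$, the
  monthly route gives systematically longer residence times.
* **Aggregate scalar.** Two definitions are exposed rather than
  conflated: the cell product $\xi_t \xi_w$ (what is applied to litter
  and soil pools) and the implied ratio $\tau'_E/\tau_E$. They differ
  because vegetation pools carry $\xi = 1$; reported biome tables that
  mix the two will look internally inconsistent, which is why both are
  returned.
* **Space.** Biome summaries are equal-area cell means. Since
  $\overline{\mathrm{NPP} \cdot \tau} \ne \overline{\mathrm{NPP}} \cdot
  \overline{\tau}$, `biome_summary()` reports both the mean of the
  per-cell product and the product of the means.

## The synthetic grid: what it does and does not emulate

`generate_grid()` draws, per cell: a biome (every configured biome
appears at least once), clay/silt/sand and porosity from uniform ranges,
annual NPP log-normally around a per-biome mean, and a daily year of
soil temperature (sinusoidal season plus Gaussian noise) and soil water
(seasonal anticorrelation with temperature, clamped into
$[0.02\,\phi, \phi]$). The per-biome NPP means use reported global biome
means where available (EBF 1325.7, DBF 789.3, ENF 402.4, DNF 275.8,
crop 231.3, crop/natural 412.5 gC m⁻² yr⁻¹); the remaining biomes use
field-plausible values. The tundra mean is set to 80 gC m⁻² yr⁻¹ — the
2.5 gC m⁻² yr⁻¹ figure that circulates for tundra NPP is inconsistent
with any plausible stock at a 146-yr residence time and is treated as a
typo, not emulated.

The generator reproduces *ordering* structure (tropical biomes warm,
wet, productive; boreal cold; barren dry and unproductive) and
reproducibility under a seed. It does **not** emulate spatial
autocorrelation, realistic texture–biome covariance, interannual
variability, or the formats of real forcing archives. A green test on
this grid therefore establishes correctness of the pipeline's
*mechanics* (assembly, solve, decomposition identities, swap isolation)
and the plausibility bands of the shipped parameters — not agreement
with any real-world global mean.

## The shipped parameter table

No per-biome parameter supplement is reproduced in our source text, so
the 13-biome table in `inst/extdata/biome_parameters.csv` is an
*editable default*, calibrated once at design time to the documented
constraint that baseline residence times land near 12–54 yr for forest
biomes (wood allocation 0.3–0.5 against woody turnover of
0.013–0.04 yr⁻¹) and 4–6 yr for non-forest biomes. Band membership is
asserted at the biome level (grid means); individual cells with extreme
random textures can sit a few tenths of a year outside. The turnover
ordering invariants — woody and coarse-root slowest among vegetation,
coarse detritus slowest among litter — hold for every row and are
tested.

## Sensitivity analysis

The index is the symmetric relative (elasticity-style) form

$$S = \frac{[O(p(1+\delta)) - O(p(1-\delta))]\,/\,O(p)}{2\delta},$$

with $\delta = 0.10$ by default and the |S| > 0.2 sensitivity threshold.
Allocation-fraction perturbations are renormalised on the simplex;
texture perturbations absorb their complement into sand. $S$ converges
to the logarithmic derivative as $\delta \to 0$ and is invariant to
output rescaling (both tested). With the shipped defaults, forest
baseline residence time is dominated by woody allocation and turnover,
so the litter-chemistry elasticities (L/N, lignins) fall below 0.2; the
often-reported ranking "lignin contents first" is a statement about a
particular parameterisation, not a structural property, and is
deliberately not asserted.

## Numerical choices

* Steady states use a dense direct solve (13×13) guarded by an estimated
  condition number threshold of $10^{12}$; failures name the
  slowest-turnover pools.
* The forward-integration oracle is explicit Euler. Its fixed point
  equals the analytic steady state for any stable step
  ($dt \cdot \max \xi_i c_i < 1$), so oracle agreement checks the matrix
  assembly and the solve, not the integrator's accuracy.
* Randomised oracle-equivalence tests draw turnover rates in
  [0.05, 15] yr⁻¹ and litter/soil scalars in [0.3, 1], keeping the
  slowest eigenmode above 0.015 yr⁻¹ so a 1000-year integration is
  within $10^{-3}$ of equilibrium. With a realistic passive pool
  (0.0045 yr⁻¹) under strong limitation this would require tens of
  millennia — which is precisely the case for the semi-analytical solve.
* The CLI is deterministic end to end: identical configuration and seed
  give byte-identical CSV outputs, and every run echoes its
  configuration for provenance.

## Known limitations

* Steady state only: no transient storage attribution.
* One soil moisture representation on the synthetic grid (relative
  saturation) proxies all schemes' moisture variables.
* Reconstructed scheme entries are placeholders (flagged as such), and
  the piecewise/parabolic moisture constants are conventions, not fits.
* CSV is the only gridded output format (no NetCDF dependency available
  offline); coordinates are abstract row/column indices.
* The parameter table is calibratable, not calibrated to data: biome
  contrasts are illustrative.
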