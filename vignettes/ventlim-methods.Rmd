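---
title: "Linear inverse modelling of vent-sediment carbon flows: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear inverse modelling of vent-sediment carbon flows: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventlim)
```

## The problem and the model

Sedimented hydrothermal vents mix two carbon sources — sinking
photosynthetic detritus and in-situ chemosynthetic fixation — in a
soft-sediment food web whose exchange rates cannot be measured
directly. `ventlim` reconstructs those exchanges with a linear inverse
model (LIM): the unknowns are the flows $x_j \ge 0$ (mmol C m$^{-2}$
d$^{-1}$) between compartments, and the data enter as linear
constraints

$$E\,x = f \qquad G\,x \ge h.$$

The equalities are steady-state mass balances, one per internal
compartment: inflows minus outflows equal zero. Steady state is an
assumption, not an observation — stocks are treated as constraints on
rates, never as state variables, and no transient term exists in the
model. The inequalities encode everything else that is known:

* **Physiology** (dimensionless ratio rules): assimilation efficiency
  (0.20–0.75 of ingestion), faecal production (0.25–0.80 of
  ingestion), net growth efficiency (0.30–0.70 of assimilation for
  macrofauna, 0.50–0.70 for megafauna), bacterial growth efficiency
  (0.05–0.45 of uptake), viral lysis returning 0.30–0.80 of bacterial
  production to detritus, and chemosynthetic fixation efficiency
  (0.10–0.50 of DIC uptake). The ratio rules hold at any temperature.
* **Biomass- and temperature-scaled rates**: secondary production
  within growth-coefficient bounds times `Tlim` times biomass;
  respiration at least the maintenance coefficient (0.01 d$^{-1}$
  macrofauna, 0.001 d$^{-1}$ megafauna) times `Tlim` times biomass and
  within 0.5–1.5 times the biomass-specific rate (default 0.01
  d$^{-1}$, configurable — the literature constant is not printed in
  our sources) times `Tlim` times biomass. `Tlim = Q10^((T-20)/10)`
  with Q10 = 2 is used exactly; `temperature_limitation(..., rounded =
  TRUE)` reproduces the two-decimal constants sometimes quoted (0.20 /
  1.30&ndash;1.32 / 6.96&ndash;7.00 at &minus;1 / 24 / 48 &deg;C).
  Bacterial rates carry no biomass term: microbial biomass is a poor
  proxy for activity, so bacterial respiration is bounded only through
  community oxygen consumption and growth efficiency.
* **Stable-isotope diet mixing**: for each feeding consumer $j$ with
  sources $i$, the flow-weighted mean source signature plus a single
  trophic discrimination factor $\Delta$ (default 1.0 &permil; for
  carbon) must lie within $k$ = 2 consumer standard deviations of the
  consumer's mean $\delta^{13}$C. This is linear in the flows:
  $\left|\sum_i x_{ij}(\delta_i + \Delta - \delta_j)\right| \le k\,
  \mathrm{sd}_j \sum_i x_{ij}$. No functional form beyond "averaged
  signatures constrain diet" is given in our sources; linear mixing
  with a configurable $\Delta$ and $k$ is this package's choice.
  Compartments fed by symbiont or chemoautotrophic fixation take their
  signature from fixation, not diet, and contribute no mixing rows.
* **Site bounds**: particulate deposition within the regional POC-flux
  window (0.70–27.17); total respiration within the measured sediment
  community oxygen consumption window (0.81–2.86 off-vent, 1.62–2.86
  at the vents, in carbon units); DOC efflux at most 10% of total
  respiration; burial 1–3% of the gross organic-matter input (all
  imports: deposition, suspension capture, DIC fixation — this base
  quantity reproduces burial magnitudes of a few percent of
  gross inputs).

Every row carries a provenance tag (`mass_balance:Det`,
`physiology:nge:MacDF`, `isotope:MacPS`, `scoc`, ...), so
infeasibility certificates and sensitivity checks can name the
biological rule responsible.

## Topology

Ten internal compartments (detritus, DOC, heterotrophic and
chemosynthetic bacteria, endosymbiont-bearing macrofauna, macrofaunal
deposit/suspension feeders and predator/scavengers, megafaunal
deposit/suspension feeders) and five externals (buried detritus,
external predation, DIC, water-column DOC, water-column detritus).
Endosymbiont-bearing fauna lack feeding organs: their only carbon
input is symbiont fixation.

The shipped per-site flow lists reconstruct a web whose per-site edge
counts are pinned at 31 (off-vent), 38 (low-activity) and 37
(high-activity): a 30-flow core in which bacteria take up dissolved
organic carbon, every faunal group respires, egests and has a
production outlet; an endosymbiont block present off-vent and at the
low-activity site; a chemosynthetic-mat block at both vent sites; and
three high-activity-specific links (mat grazing by
predator/scavengers and by megafaunal deposit feeders, detritus
scavenging). The exact published edge list is not available to this
build, so these lists are a documented reconstruction consistent with
the compartments' feeding modes and reported diets; each faunal
compartment must keep respiration, faeces and one production outlet,
otherwise the growth and faecal rows above are unsatisfiable. When no
explicit list is given, `build_topology()` falls back to a generic
feeding-mode rule set (`default_edge_rules()`).

## Solving and sampling

The compiled system is underdetermined: the feasible set is a convex
polytope, and no single solution is "the" answer. The package
characterises the whole polytope:

* `check_feasibility()` finds a feasible point by minimum-norm
  quadratic programming (`quadprog`), and on failure reports an
  irreducible set of conflicting row provenances by a deletion filter.
* `flow_ranges()` computes each flow's attainable minimum and maximum
  with two linear programs per flow. These run on an in-package dense
  two-phase simplex (Dantzig pricing with a Bland anti-cycling
  fallback, row equilibration, a 1e-7 pivot floor, and a phase-1 basis
  shared across all objectives); the site LPs are small but highly
  degenerate, and the implementation is validated against closed-form
  toys, quadratic-programming feasibility and rejection sampling.
* `sample_polytope()` draws the ensemble with a mirror (reflective)
  random walk in the null space of the equalities: an isotropic
  Gaussian step is folded across every inequality hyperplane it meets,
  which leaves the uniform distribution invariant. The walk runs in a
  width-scaled parameterisation $x = x_0 + \mathrm{diag}(w)\,Z\,q$
  ($w$ proportional to the per-flow range widths, $Z$ orthonormal):
  the map is linear with constant Jacobian, so uniformity is
  preserved, while steps move each flow in proportion to its
  range — without this, flows spanning two orders of magnitude force
  thousands of reflections per step. The hot loop is C++ (Rcpp) on
  R's RNG, so ensembles are bit-reproducible under a seed.

Defaults: jump length 0.3 times the mean range width (no value is
prescribed by our sources; this mixes well across all shipped
models), burn-in 1000 steps (`burn_in = 0` reproduces a protocol that
retains from the common start point onwards), production ensembles of
100 000 iterations, and constraint tolerance 1e-8 throughout (flows
are O(0.01–10), so this is far below any biological signal).

`convergence_diagnostic()` implements the run-length ladder protocol:
chains of 300 / 3 000 / 30 000 / 200 000 iterations (the package's
heavy jobs scale the top rung to 100 000) begun from the same start
point; the minimum adequate run length is the first rung at which the
mean and SD of five tracked flows of varying magnitude are within 2%
of the longest run.

## Ensemble reductions

* `ensemble_summary()`: per-flow mean, SD ($n-1$), coefficient of
  variation, and the CoV bins (&ge; 1 flags considerable residual
  uncertainty; &lt; 0.5 and &lt; 0.2 are reported as quality
  descriptors). A zero-mean flow gets an undefined CoV, not an
  infinity.
* `om_budget()`: the site carbon budget per solution, then averaged.
  "Net" inputs subtract only the mediating compartments' respiration
  (suspension feeders for the suspension route; chemoautotrophs and
  symbiont hosts for fixation) — their egesta stay in-system as
  detritus and are tracked separately, which keeps net &le; gross and
  lets whole-system conservation (gross inputs = respiration + burial
  + DOC efflux + external predation) hold to numerical precision in
  every sampled solution. Percentage shares use net inputs as the
  denominator.
* `diet_composition()`: mean share of each feeding inflow in total
  intake; fixation inflows are not diet.
* `fraction_greater()`: the distribution-free comparison used instead
  of null-hypothesis tests (with $10^5$ solutions per ensemble,
  p-values saturate at negligible effect sizes): the fraction of
  cross pairs $(a, b)$ with $a > b$, ties counting zero; &gt; 0.95 is
  significant, &gt; 0.98 highly significant. Cross-pairing (rather
  than index-pairing) is used because ensembles are unordered samples;
  the fraction is computed exactly at any size by a sorted scan, which
  equals exhaustive enumeration.

## Network indices

`to_flow_matrix()` maps a solution onto the compartment flow matrix
plus import, export and respiration vectors (respiration is kept
separate so throughflows balance; DIC fixation counts as an import).
On that container:

* **TST** — total system throughflow, the sum of compartment
  throughflows.
* **FCI** — Finn cycling index from the output-fraction matrix
  $g_{ij} = T_{ij}/T_i$ and $N = (I-g)^{-1}$: cycled throughflow
  $T_c = \sum_i \frac{n_{ii}-1}{n_{ii}} T_i$ over TST. The corrected
  variant relates cycled to straight-through throughflow,
  $T_c/(\mathrm{TST}-T_c)$; both are emitted because published
  "corrected FCI" values do not state their convention.
* **AMI** — average mutual information in bits over the extended
  matrix (imports as an external source row; exports and respiration
  as external sink columns); the bit scale matches reported values
  near 2 for webs of this size.
* **Compartmentalisation** — mean Jaccard overlap of undirected
  interaction neighbourhoods over compartment pairs, the focal node
  included; 1 for a complete web, 0 for an edgeless one.

`ensemble_indices()` computes indices per solution and reports mean
&plusmn; SD (indices are reported with SDs in the field, implying
per-solution evaluation); `per_solution = FALSE` evaluates them once
on the mean flow network instead.

## The synthetic-site generator

The real biomass stocks and isotope signatures for the Bransfield
sites live in unpublished cruise datasets, so the shipped fixtures
carry clearly labelled synthetic placeholders, and quantitative
validation runs on synthetic sites with known truth
(`generate_site()`):

1. build the template's topology (off-vent / low-activity /
   high-activity, with their compartment absences, temperatures and
   rule set);
2. draw a ground-truth flow vector uniformly from a broadly
   constrained polytope: the structural ratio rules, wide deposition
   and oxygen-consumption windows (0.5–15 and 0.3–12 mmol C m$^{-2}$
   d$^{-1}$), import caps of 5 (15 for deposition), small metabolic
   floors so every population is alive, and a
   production/respiration compatibility band per faunal class;
3. derive the observations from the truth: faunal biomass drawn
   log-uniformly inside the interval jointly admitted by the
   maintenance, respiration-band and growth rows at the truth's rates
   (a naive "respiration/(rate × Tlim) times noise" recipe can
   violate the maintenance row, making the emitted dataset
   inconsistent with its own truth, so the interval construction is
   used instead); compartment $\delta^{13}$C from the truth-weighted
   mixing system with photosynthetic detritus at &minus;25 &permil;
   and chemosynthetic carbon at &minus;35 &permil; (round conventional
   end-members, configurable), SD 1 &permil;; deposition and
   oxygen-consumption windows of &plusmn;20% around the truth;
4. assert that the truth satisfies the compiled system at 1e-8 before
   returning.

`recovery_test()` then compiles, samples and asks per flow whether the
truth lies in the central 95% interval. Across 20 seeds per template
at 20 000 iterations, mean coverage is ~96% (the acceptance script
recomputes this). What passing shows: compiler, sampler and interval
machinery jointly invert observations that were generated by the
model's own assumptions. What it does not show: robustness to real
data whose noise violates those assumptions — field stocks are not
lognormal around physiological bands, real discrimination factors
vary by tissue and taxon, and detritus lability is not resolved.

## Numerical choices and degenerate inputs

Tolerance 1e-8 for constraint satisfaction everywhere; LP pivots below
1e-7 (after row equilibration) are treated as zero; reflections
exceeding 100 000 per step reject the move (the state simply stays,
preserving the chain's invariant distribution); a move that ends
outside the polytope by more than 1e-10 through rounding is likewise
rejected. Flows fixed by the equalities sample as constants and count
as converged (relative deviation defined 0) and as covered when the
pinned value equals the truth. Unbounded coordinates are a reportable
state from `flow_ranges()` but an error from the sampler, which cannot
mix over an infinite polytope. Ties in `fraction_greater()` count
zero, so mutual fractions sum to at most one.

## Problem sizes used by the shipped analyses

The numbered scripts under `analysis/` use 100 000-iteration
production ensembles, 10 000-row subsamples for per-solution index
computation, and ten synthetic recovery runs per template at 20 000
iterations; the acceptance script runs twenty per template. These
sizes put Monte-Carlo error well below the ensemble SDs they
accompany.

## Known limitations

* The per-site flow lists are a reconstruction pinned to the
  published counts, not the published edge list itself.
* Meiofauna are absent (no data), so bacterial and faunal respiration
  absorb their share; detritus is one pool with no lability classes.
* The fixtures' stocks and signatures are synthetic: fixture budgets
  and indices characterise the pipeline, not the Bransfield sites.
  With real stocks supplied as a CSV (`apply_stocks_csv()`), the same
  pipeline applies unchanged.
* Whether predators consume megafauna directly, and which bacterial
  compartment feeds predators at each site, is under-determined by the
  available descriptions; the shipped lists route mat carbon to
  predator/scavengers only at the high-activity site.
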