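---
title: "Models and methods behind h2sink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind h2sink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h2sink)
```

## The problem

After closure of a deep geological repository (DGR) for radioactive waste,
anoxic corrosion of steel canisters produces hydrogen gas on a scale that
threatens the integrity of the clay host rock. The access galleries will be
backfilled with a porous sand-bentonite mixture saturated with sulfate-rich
Opalinus Clay porewater (about 15 mM sulfate), and indigenous
hydrogenotrophic microorganisms - sulfate-reducing bacteria (SRB) and, where
sulfate runs out, methanogens - can consume that hydrogen:

$$4\,\mathrm{H_2} + \mathrm{SO_4^{2-}} + \mathrm{H^+} \rightarrow
  \mathrm{HS^-} + 4\,\mathrm{H_2O}$$

$$4\,\mathrm{H_2} + \mathrm{CO_2} \rightarrow \mathrm{CH_4} +
  2\,\mathrm{H_2O}$$

`h2sink` implements the quantitative chain from monitored flow-through
reactor experiments to a repository-scale capacity statement: a forward
reactor simulator that stands in for the monitored reactors and provides
ground truth, two sulfate-reduction rate estimators, electron
donor/acceptor budgets with stoichiometric conversion and scale-up, and the
kitome-corrected spatial microbiome statistics used to locate the
hydrogenotrophs on the post-mortem sampling grid.

Units are fixed package-wide: concentrations in mM (numerically equal to
umol/cm^3), volumes in cm^3 internally, flow logs in uL/min converted on
read (1 uL/min = 1.44 cm^3/day), rates in umol/(day cm^3 of *void*
volume). The void (porewater-filled) volume is the normalising volume
throughout, because the mass balance divides by it; conversion to bulk
backfill volume is a separate, explicit step scaled by porosity.

## The reactor model

`simulate_reactor()` evolves a well-mixed dissolved state (sulfate,
sulfide, ferrous iron over the void volume `v_voids`) plus a gypsum
inventory and cumulative ledgers:

- **Transport**: first-order exchange at dilution rate $Q/V_v$ against the
  inflow composition; the outflow leaves at the instantaneous reactor
  concentration. There is no spatial structure - preferential flow paths
  and unconnected porosity, both present in real columns, are outside the
  model.
- **Sulfate reduction**: $R_{sr} = v_{max}\, f(\mathrm{H_2})\,
  [\mathrm{SO_4}]/(k_{SO_4} + [\mathrm{SO_4}])$, consuming 4 H2 per
  sulfate. With sulfate well above $k_{SO_4}$ and H2 limiting, this
  reduces to the zero-order (constant-rate) behaviour the linear estimator
  assumes.
- **H2 availability**: the experiment delivers H2 as one computer-driven
  pulse per day and no dissolved-H2 measurements exist, so dissolved H2 is
  not a state variable. Instead each day has a budget of `k_h2` times that
  day's pulse; consumption proceeds at full rate while budget remains and
  stops when it is spent. Numerically the availability factor is clamped
  per step, $f = \min(1, \mathrm{remaining}/\mathrm{demand})$, so the
  day's total use matches the budget to $O(\Delta t^2)$ rather than
  overshooting by one step's demand. Gas-phase partitioning (Henry's law)
  is deliberately not modelled.
- **Gypsum**: first-order relaxation of sulfate toward a single saturation
  concentration (`c_sat`, default 20 mM) while inventory remains; full
  ion-activity-product chemistry is out of scope. Dissolution stops
  exactly when the inventory is exhausted (any within-step overshoot is
  returned to solution so the ledger closes).
- **FeS precipitation**: treated as instantaneous; after each chemistry
  step the lesser of dissolved ferrous iron and sulfide is removed
  (operator splitting) and booked as FeS.
- **Methanogenesis**: switched on below the sulfate gate `so4_gate`
  (default 1 mM), encoding the competitive exclusion of methanogens by
  SRB at the H2 level; it draws on the same daily H2 budget (4 H2 + 1 CO2
  per CH4).

### Integration and conservation

The integrator is a fixed-step explicit fourth-order Runge-Kutta scheme,
default step 0.01 day (0.02 day in the validation sweeps; both divide one
day evenly so pulse budgets reset cleanly). The discrete switches (H2
budget, gypsum indicator, sulfate gate) are frozen within a step, which
keeps the scheme smooth inside each step. Because the sulfur and iron
totals are *linear* invariants of the continuous system and Runge-Kutta
methods preserve linear invariants exactly, the element ledgers close to
machine precision - the 0.1 % conservation requirement is met with twelve
orders of magnitude to spare, and `conservation_check()` exposes the
closure error for any run.

### Default study conditions

The defaults of `reactor_config()` and `kinetic_params()` emulate the
monitored experiment: 420 cm^3 of voids in a 942 cm^3 vessel, 15 mM
sulfate inflow and initial condition, 120 uM initial ferrous iron, 8.2
mmol gypsum sulfate, ~2 uL/min inflow, a 0.45 mmol/day H2 pulse, 108
days. Under these conditions the H2 pulse, not the sulfate pool, limits
consumption (demand at full rate is ~0.8 mmol H2/day against a 0.45
mmol budget), the outlet sulfate declines roughly linearly from 15 mM
toward a few mM, and the time-averaged consumption rate is ~0.27
umol/(day cm^3) - the same order as the mass-balance estimates of the
monitored reactors. Values not stated for the experiment (inflow iron 30
uM, `k_so4` 0.3 mM, `k_gyp` 0.01/day, `vmax_meth` 0.05 umol/(day cm^3))
were chosen once as plausible for this system and are documented here
rather than tuned.

One deliberate mismatch with the observations: with FeS precipitation
limited to *dissolved* ferrous iron (initial pool plus inflow), simulated
dissolved sulfide accumulates beyond the sub-millimolar levels observed
in the monitored reactors, which evidently lose sulfide to iron sources
(e.g. clay-bound iron) the model does not track. The simulator is a
ground-truth generator for the estimators, not a calibrated geochemical
model; its sulfide trajectory overstates what a real outflow record
shows.

### Observation model

`sample_observations()` emulates weekly triplicate sampling: per day and
analyte, `n_reps` independent draws of latent value plus Gaussian noise,
censored at zero, summarised as mean, sample SD (n-1 denominator; 0 by
convention for a single replicate) and n. Censoring introduces no
measurable bias at the default noise levels (sulfate SD 0.5 mM against
latent values of several mM); near-zero latent values would bias the mean
upward, which is the realistic behaviour of a non-negative assay.

## Rate estimators

**Linear regression** (`linear_rate()`): ordinary least squares of mean
outlet sulfate (mM) on time (day); the rate is the negative slope. Since
1 mM = 1 umol/cm^3 of porewater, the slope is numerically the volumetric
rate per cm^3 of void. The fit is unweighted - replicate SDs are ignored,
matching the plain adjusted-R^2 reporting convention - with an
inverse-variance option available. The slope standard error is reported
as the rate's uncertainty. A rising series gives a negative rate, which
is information (resupply outpacing consumption), not an error.

**Global mass balance** (`mass_balance_rate()`): all sulfate supplied
(injected water at the inflow concentration plus gypsum) minus all
sulfate accounted for (weekly outflow export plus the final dissolved
pool), divided by duration and void volume. Two conventions matter:

- The injected volume includes the *initial saturation fill* of the
  voids: the reactors start dry and are saturated with the same
  porewater, so a closed system has $V_{in}^{tot} = V_{voids}$ at the
  initial concentration. Without this term the balance of a sealed,
  fully-depleted reactor would be zero.
- `mass_balance_inputs_from_sim()` uses an inflow-weighted effective
  inflow concentration so the identity holds exactly even when the
  initial and inflow concentrations differ, and uses the gypsum actually
  dissolved (from the simulator ledger) rather than the total inventory.
  On simulator output with exact bookkeeping the estimator reproduces the
  true time-averaged rate to rounding error; the published application
  instead inserts the *total* gypsum figure (10 mmol in the equation
  annotation; 8.2 mmol by inventory), one reason the monitored
  mass-balance rates scatter more than the regression rates.

The two estimators answer different questions: the regression reads the
net outlet decline (a lower bound on consumption whenever inflow and
gypsum resupply sulfate), while the balance closes the full budget. On a
closed, zero-order system they coincide - the package's consistency check
- and `analysis/02_estimate_rates.R` shows them diverging, as expected,
on flow-through conditions.

**Summaries** (`summarize_rates()`): arithmetic mean, sample SD (n-1) and
RSD = 100 sd/mean. The sample-SD convention is applied uniformly; the
published mass-balance column's printed spread happens to match the
population SD of its rounded rates instead, a discrepancy we note and do
not chase by switching conventions per column.

**Windowing** (`windowed_rate()`): independent fits on the two sides of a
breakpoint, for isolating flow regimes. A side with fewer than three
points yields NA with a warning rather than an abort, so a degenerate
split still returns the usable side.

### Validation scenarios and problem sizes

The validation suite runs at sizes chosen to exercise the estimators
properly while keeping the whole suite quick to re-run:

- *Conservation*: 50 simulations with parameters drawn across the
  plausible ranges (flow 0-32 uL/min, vmax 0.2-2, gypsum 0-10 mmol, 60
  days, step 0.02).
- *Consistency and recovery*: a closed-system zero-order scenario with
  `vmax_sr` = 1.75 umol/(day cm^3), `k_so4` = 0.1 mM, no flow, no
  gypsum, ample H2, and weekly sampling over 56 days. The starting
  concentration is 120 mM so that eight weekly samples all lie in the
  zero-order regime: a 1.75 mM/day depletion exhausts a 15 mM pool in
  nine days, so the volumetric rate scale and the experiment's ~100-day
  weekly schedule cannot coexist at porewater concentrations. This is a
  calibration scenario for the estimator, not a chemically realistic
  porewater. Parameter recovery uses 100 seeded replicates at 0.5 mM
  sulfate noise, triplicate sampling; the median absolute relative error
  is well under 1 %, against a 10 % requirement.
- *Test calibration*: 2000 null grids for the column t-test procedure;
  200 generated ASV grids for hotspot detection.

A property worth a caveat: the true rate responds monotonically to
`vmax_sr` (non-decreasing) and `k_so4` (non-increasing) in the direct
kinetics, and the suite verifies this with ample H2 and methanogenesis
off. Under the full default model the interaction of the daily H2 budget
with the sulfate gate can locally invert the `k_so4` response (slower
depletion keeps the gate closed and hands the whole budget to the SRB),
so monotonicity should not be assumed across regime switches.

## Budgets and scale-up

`molar_ratios()` reports H2:sulfate supply ratios against water-borne
sulfate alone and against water plus gypsum; display values round half-up
to one decimal, raw values are always retained (one published entry,
reactor 2's water ratio, is not reproducible from its own printed inputs
at that rounding - the package reproduces the three consistent reactors).
`h2_rate_from_sulfate()` is the exact 4x stoichiometric conversion.
`backfill_rate()` scales a per-void rate by porosity, exploiting
umol/cm^3 = mol/m^3. The porosity default 0.45 is the unique value
consistent with both published endpoint conversions (2 -> 0.9 and 7 ->
3.2 mol/(day m^3)) under half-up one-decimal rounding, the underlying
worked calculation being unavailable; the published pairing uses the
*integer-rounded* H2 conversions, and the package follows that pairing
when reproducing the range. `backfill_fraction_required()` converts the
H2 inventory (default 900e6 mol over 1000 years, 365.25-day years;
sensitivity to 365.0 is below 0.1 %) to a constant daily production and
divides by the backfill's consumption capacity: at 0.9 mol/(day m^3) and
390,000 m^3, about 0.70 % of the backfill suffices, comfortably below
the 1 % headline.

`classify_fe_s_ratio()` interprets Fe:S atomic ratios of sulfur hotspots
against pyrite (FeS2, Fe:S = 0.5) and mackinawite (FeS, Fe:S = 1):
within tolerance 0.25 of a target the nearer mineral wins (ties to the
lower, pyrite); below 0.25 is sulfur-excess, above 1.25 iron-excess.
Boundary values assign deterministically to the lower class, making the
classification piecewise-constant with ordered labels.

`methanogenesis_gas_balance()` is the five-for-one gas-mole accounting of
hydrogenotrophic methanogenesis: 5 moles of gas in, 1 out, net -4 -
pressure-reducing despite being gas-producing.

## Community analysis

**Kitome correction** (`kitome_correct()`): per ASV, the reagent-blank
("kitome") read count is subtracted from every sample, clamping at zero
with clamped cells flagged. **Normalisation order**: proportions divide
by the *post-subtraction* sample total, so rows sum to exactly 1; the
alternative (pre-subtraction totals) would leave sub-unit rows.
**Reactor-level summaries** (`reactor_mean_abundance()`) average reads
across the 35 samples *before* subtracting the kitome and normalising -
reads-first averaging, which differs measurably from averaging
per-sample proportions; the test suite pins the difference.

**Presence confirmation** (`confirm_presence()`): a taxon is present in a
sample group only if its mean raw reads strictly exceed its kitome reads;
ties are "not confirmed", the conservative reading of a contamination
floor.

**Ordination**: `hellinger()` (square root of proportions, mapping
compositions to the unit sphere) followed by `pca_ordination()`
(column-centred SVD via `prcomp`, cross-checked in the tests against an
independent eigendecomposition of the covariance). Explained-variance
fractions are non-increasing and sum to at most 1; rank-deficient
requests truncate with a warning; zero-variance input is flagged
degenerate rather than ordinated.

**Spatial biomass tests** (`column_biomass_tests()`): each off-centre
column (OL, CL, CR, OR) against the central column C, a two-sided
variance-ratio test at 0.05 gating between the pooled and Welch
two-sample t-test, then a one-sided test of "off-centre lower" - the
direction implied by H2 being delivered at the centre. Raw p-values are
reported without multiplicity correction, matching the original
analysis; with four non-independent comparisons per reactor the
family-wise error is correspondingly higher, which the documentation
flags rather than corrects. Biomass is analysed on the natural scale by
default (no transform was applied in the original analysis) with a log10
option. Calibration: over 2000 null grids (normal, equal variances, 7
per column) the realised type-I error of the compound procedure is ~5 %,
within the 7 % tolerance.

**Spatial maps** (`spatial_map()`): bilinear interpolation of the 5 x 7
grid onto a dense raster (via `pracma::interp2`), exact at the 35 nodes;
up to half the nodes may be missing and are filled by iterative
neighbour averaging first. Bilinear interpolation reproduces any plane
exactly, which the tests verify; it does not extrapolate beyond the
grid's convex hull.

### The ASV generator and what passing tests mean

`generate_asv_table()` draws counts from a negative binomial (size 8)
around expected compositions: a fixed power-law base profile (rank-0.9
decay over 20 ASVs, fronted by the taxa that dominate these reactors)
with the hotspot taxon's expectation multiplied by $1 + A
\exp(-d^2/2\ell^2)$ toward the H2 delivery point (centre column, middle
row). Defaults $A = 4$, $\ell = 1$ grid unit confine the elevation
essentially to the central column, emulating growth concentrated where
H2 is available; at these defaults the central-column excess of the
hotspot taxon is detectable in ~99 % of tables, and its presence is
confirmed against the default kitome (mean 40 reads/ASV, Poisson,
proportional to the base profile) in effectively all of them. Biomass is
log-normal (geometric mean 8.2e8 copies/g, the post-incubation average
of the monitored reactors; sdlog 0.6) with a 3x central-column
enrichment.

The generator emulates spatial hotspot structure, library-size noise,
overdispersion and reagent contamination. It does *not* emulate real
taxonomic richness (hundreds of ASVs), compositional correlations
between taxa, sample-to-sample library-size variation beyond NB noise,
sequencing chimeras, or taxonomy misassignment. Tests passing on
generated grids therefore demonstrate that the statistical machinery is
correct and calibrated under the stated model - not that the pipeline is
robust to every failure mode of real amplicon data.

## Degenerate inputs and numerical conventions

- Simulator: steps above 0.05 day or not dividing a day evenly are
  rejected; any state dipping below -1e-9 aborts with advice to reduce
  the step; negative parameters are rejected naming the offending field.
- Regression: fewer than three days, or zero day-variance, are rejected;
  exactly collinear input returns se 0 and adjusted R^2 1 with the
  "perfect fit" advisory muffled.
- Mass balance: a negative budget (net accumulation) is flagged, not
  rejected; zero void volume or duration is rejected; outflow exceeding
  water supplied plus the void volume is rejected as unphysical.
- Display rounding is half-up (`round_half_up()`), matching the printed
  tables' convention; all raw values are retained alongside.
- Every random draw flows from an explicit seed argument; the simulator
  chemistry is deterministic, and `run_report()` writes a seed manifest
  with every report.

## Known limitations

Spatially homogeneous chemistry (no reactive transport, no biofilm
structure); no gas-phase partitioning; dissolved sulfide overstated
relative to monitored outflows (no matrix-iron sulfide sink); the
pulse-budget H2 model is an assumption standing in for unmeasured
dissolved H2; biomass `growth` is a simple activity ramp, not a coupled
growth model; the mass-balance estimator propagates no uncertainty (none
was reported for the original application); and the community module
starts from count tables - read processing, denoising and taxonomy
assignment are upstream and out of scope.
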