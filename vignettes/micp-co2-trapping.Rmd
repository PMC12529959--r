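---
title: "Modeling CO2 trapping by ureolytic bacteria: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling CO2 trapping by ureolytic bacteria: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micptrap)
```

## The system being modeled

A closed bottle reactor: 50 mL of growth medium under 200 mL of headspace
gas, shaken at 30 °C and 1 atm. The headspace holds CO₂(g) (0.04–100
vol %) plus air; the liquid holds urea, optionally CaCl₂, pH buffers from
the medium, and a growing culture of urease-producing bacteria. Urease
hydrolyzes urea to carbamate and ammonia; carbamate decays to ammonia and
carbonic acid; ammonia protonation raises pH, which pulls CO₂ out of the
headspace as HCO₃⁻/CO₃²⁻ and, with calcium present, precipitates CaCO₃.
Carbonic anhydrase (CA), also produced by the bacteria, accelerates the
otherwise slow hydration of CO₂(aq).

All of this is represented as a single mass-action network: for a
reversible reaction A + B ⇌ C the net rate is −k_f[A][B] + k_b[C] with
k_b = k_f/K, so every kinetic simulation relaxes to the thermodynamically
consistent state. Gas–liquid transfer of CO₂ and NH₃ uses the same
functional form with an effective transfer constant and the Henry-law
partition ratio as K; the gas-side derivative is scaled by
V_liq/V_gas so that moles are conserved across the phase boundary (the
flux convention is a package choice; it is validated by the conservation
audits in the test suite). Water is held at constant activity (55.5 M
absorbed into the constants), so rate laws written with explicit H₂O are
evaluated first-order in the other reactant. Chloride from CaCl₂ is
carried as an inert spectator so charge bookkeeping closes.

## Enzymes and biomass

Ureolysis follows Michaelis–Menten kinetics with K_m = 355 mM and
v_max = 6.4 × 10⁻⁹ mmol h⁻¹ CFU⁻¹, scaled by the cell concentration [X]
in CFU mL⁻¹ (OD₆₀₀ of 1 ≙ 1.37 × 10⁹ CFU mL⁻¹; the product
CFU mL⁻¹ × mmol h⁻¹ CFU⁻¹ is numerically mol L⁻¹ h⁻¹ — the package makes
this unit step explicit because it is easy to get wrong by a factor of
1000). [X] is linearly interpolated between OD samples at 0, 2, 5, 8, 24,
31, 48, 54 h and held constant after the series' exponential-phase peak
(24, 31 or 54 h depending on the series), where OD stops being
proportional to viable cells. At full cell density the saturated rate is
~8.8 M h⁻¹ per OD unit — far faster than gas exchange, which is why a
250-fold biomass attenuation variant exists as a named option.

The CA contribution enters as the forward rate constant of CO₂(aq)
hydration, k_f = 0.065 s⁻¹ + 0.117 s⁻¹ · OD₆₀₀; the intercept is the
uncatalysed hydration rate. When a growth curve is supplied the OD (and
with it this constant) varies along the trajectory; a fixed OD models a
pre-grown, non-growing culture.

### The synthetic growth generator

Measured OD₆₀₀ values for the batch series exist only as a figure, so
batch-scenario simulations use a seeded synthetic stand-in
(`synthetic_growth()`): a logistic curve with OD(0) = 0.01 reaching within
1 % of its plateau at the series' peak time, sampled on the experimental
8-point grid, with 5 % lognormal sampling noise (deterministic per seed),
then made monotone and plateaued. It emulates the shape constraints that
matter to the kinetics — inoculation density, exponential rise, peak time,
post-peak plateau — and nothing else. It does not emulate lag-phase
structure, pH or ammonia toxicity feedback, or any coupling of growth to
chemistry. Consequently, batch-bottle tests check sign structure and
qualitative shape (trapping at high CO₂, outgassing at atmospheric CO₂,
the sharp early dissolution dip), never quantitative agreement with the
measured bottle curves; the quantitative claims of the package all come
from equilibrium calculations or from scenarios with a fixed OD, which do
not touch the generator.

## Equilibrium solver

For scenarios with the headspace CO₂(g) clamped (continuous injection),
the equilibrium state is computed algebraically rather than by long
integration. With [CO₂(g)] fixed, Henry's law fixes CO₂(aq), and every
carbonate, ammonia and buffer species is an explicit function of [H⁺]
through the equilibrium constants; urea is taken as fully hydrolyzed
(ureolysis is irreversible); ammonia outgassing uses the closed-bottle
volume ratio; calcium partitions between free Ca²⁺ and the CaCO₃ pool via
its equilibrium constant. That leaves pH as the single unknown.

The closing equation is a charge balance with a twist: the liquid is
initialized at pH 7.3 (media) with buffers pre-equilibrated, which leaves
a nonzero net charge among the *explicit* ions — the real medium's
counter-ions are implicit. Since every reaction conserves charge and only
neutral species cross the phase boundary, that net explicit charge is a
dynamical invariant. The solver therefore requires the equilibrium charge
to equal its initialization value, not zero. This is what makes the
algebraic solution agree with long-horizon kinetic integration to better
than 0.1 % species-wise (a property the test suite checks on randomized
scenarios); solving the naive electroneutral balance instead would
disagree with the dynamics whenever buffers are present.

The root in pH is bracketed on (0.5, 13.9) and located with `uniroot` at
1e-14 tolerance; the balance function is monotone in [H⁺], so the bracket
is robust over the full 13 decades. When Ca²⁺ is clamped as well, the
delivered calcium is assumed to arrive as neutral CaCl₂ so the charge
balance stays well-posed (in the kinetic clamp the reservoir supplies bare
Ca²⁺; the two conventions are documented and the clamped-Ca sweeps are
qualitative).

Capacity sweeps (`trapped_sweep()`, `caco3_map()`) run this solver on a
grid; the urea sweep refines its interior maximum by golden-section search
between the bracketing grid points so the reported optimum does not
depend on grid resolution.

## Numerical choices

**Integrator.** The default is `deSolve::ode(method = "vode")` — an
implicit BDF method — with the analytic Jacobian of the mass-action
system, rtol = 1e-8 and atol = 1e-12 M. Halving the tolerances moves
endpoints by well under 0.01 % (tested).

**"Instantaneous" constants.** Several constants are only known to be
effectively instantaneous (carbamate decay, ammonia protonation, NH₃
transfer, the buffer dissociations), with a placeholder value of
1 × 10¹⁰ s⁻¹ in the constant table. Integrating them at face value is
numerically infeasible in double precision: the derived backward constants
reach 5 × 10¹⁹ M⁻¹ s⁻¹, and the cancellation noise of the two opposing
~10⁷ M/s fluxes flowing through [H⁺] (~10⁻⁸ M) exceeds any usable error
tolerance, stalling every stiff integrator at sub-millisecond steps. The
simulator therefore integrates these reactions at a capped relaxation rate
`k_fast` (default 10⁴ s⁻¹, i.e. a 0.1 ms relaxation time, at least four
orders of magnitude faster than any resolved process) with k_b rescaled by
the same factor, which preserves every equilibrium constant exactly.
Endpoints and times-to-equilibrium are identical to six digits for
`k_fast` anywhere in 10³–10⁶ s⁻¹ (tested). The network object itself
stores the table values verbatim; the cap is purely an integration
setting. Measured large constants (H₂CO₃ dissociation at 10⁷ s⁻¹, H⁺/OH⁻
recombination at 1.4 × 10¹¹ M⁻¹ s⁻¹, the OH⁻ pathway constants) are never
touched.

**Negative concentrations.** The right-hand side evaluates the polynomial
mass-action rates without clamping at zero: a clip creates a derivative
discontinuity that defeats the Newton iteration of the implicit solver
(observed as step-size collapse). Tiny negative excursions at the
integrator's error level (≲10⁻¹² M in practice) are zeroed in the output;
anything below −10⁻⁹ M aborts the run naming the offending species.

**Clamping** zeroes the clamped species' derivative (an infinite external
reservoir), which is smooth for the solver; the clamped concentration is
bit-identical over the whole trajectory.

**Time units** are seconds internally and hours at the user interface
(growth curves are sampled in hours).

## Parameters that matter, and their defaults

| parameter | default | meaning |
|---|---|---|
| `v_liq`, `v_gas` | 0.05 L, 0.2 L | bottle geometry; sets the phase-transfer mole scaling and the NH₃ outgassing ratio |
| `temperature` | 303.15 K | incubation temperature; enters only the ideal-gas molarity (the constant table is used unmodified over 20–30 °C) |
| `kf_R8` | 2 × 10⁻² s⁻¹ | CO₂ gas–liquid transfer constant, a shaking-incubator estimate; 10¹⁰ models instantaneous dissolution |
| buffer totals | 5 mM each (HQa–HQg) | media buffering capacity; the acid constants are fixed, the totals are a plausible order of magnitude and **not validated** — every quantitative result in the package's checks uses buffers-off conditions |
| `k_fast` | 10⁴ s⁻¹ | relaxation cap for "instantaneous" reactions (see above) |
| `attenuation` | 1 | biomass divisor; 250 reproduces the reduced-ureolysis variant |

The default scenario temperature is 30 °C throughout because the
reference gas molarities (0.0402 M at 100 vol %, 0.033 M at 82 vol %)
imply it; the constant table's ~25 °C provenance is accepted as-is within
its stated validity range.

## Design choices that were genuinely open

* **CaCO₃ as a mass-action pool.** Precipitation is a reversible
  mass-action reaction on a well-mixed concentration pool — no nucleation
  threshold, saturation index or solid-phase activity. This matches the
  equilibrium cap behavior the model exists to study, but it gives the
  solid a very slow dissolution mode (k_b = 10⁻⁸ s⁻¹, a ~3 year
  timescale). Kinetic runs that end in an acidic, carbonate-poor state can
  therefore sit measurably above the algebraic equilibrium for a long
  time; the cross-validation scenarios keep urea ≥ 3 × Ca so the endpoint
  is reached by fast precipitation instead.
* **Trapped CO₂ is mole-based**: liquid-phase carbon moles (DIC,
  carbamate, CaCO₃) minus hydrolyzed-urea moles, per liquid volume, with
  the hydrolysis tally integrated alongside the state. A symbolic
  gas-minus-liquid identity would mix molarities referenced to different
  volumes; for clamped-headspace equilibria the two readings coincide.
* **The nominal "60 vol %" batch series is initialized at 70 vol %**, the
  value consistent with its first headspace measurement.
* **NH₃(g) always evolves freely**, also in constant-CO₂(g) scenarios
  (clamping is per-species and the ammonia headspace is never claimed
  constant).
* **Sedimentary step-(iii) scenario**: the pre-injection state is the
  algebraic equilibrium of the clamped system (100 vol % CO₂, 0.66 M
  Ca²⁺, 0.66 M pKa-10 buffer initialized at pH 10); at t = 0 urea jumps to
  0.33 M and the clamp is released. Its pH excursion depends strongly on
  the unvalidated media-buffer totals, so the package only asserts the
  qualitative structure (substantial pH rise after injection, urea
  consumed within hours, CaCO₃ non-decreasing).

## Problem sizes

The shipped checks use desk-scale problems chosen for precision, not
load: capacity sweeps of ~60–120 equilibrium solves per curve (each solve
is a bracketed one-dimensional root search, < 5 ms), kinetic runs of 2–54
simulated hours (hundreds of BDF steps, ≲2 s each), and ten randomized
100-hour cross-validation integrations. The refined sweep optimum is
grid-independent by construction.

## Known limitations

* No activity-coefficient corrections: all equilibria use concentrations,
  so high-ionic-strength results (multi-molar urea/ammonium) are
  idealized; the constant-water assumption also degrades there.
* No temperature or pressure dependence of the constants; the model is
  for ~1 atm and 20–30 °C, not supercritical reservoir conditions.
* Bacterial physiology is an input, not a model: no Monod growth, no pH
  or ammonia toxicity, no urease expression dynamics, and biomass carbon
  is tracked only as a side metric (`biomass_carbon()`), never coupled
  into the reaction network.
* Mineral dissolution chemistry (the rock-buffering step between CO₂
  injection and carbonate precipitation in real reservoirs) is
  represented only by a configurable generic buffer.
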