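---
title: "A two-compartment lung model with density-dependent resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-compartment lung model with density-dependent resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungtau)
```

## The physical problem

Patients with obstructive lung disease empty their lungs slowly, and they
empty them unevenly: an obstructed region can lag far behind the rest of
the lung, trapping gas and raising end-expiratory pressure.  Where the
obstruction sits in large, proximal airways, its resistance is dominated
by flow inertia and therefore scales with gas density — which is why
low-density helium/oxygen (heliox) mixtures can speed regional emptying.
`lungtau` models the standard bench surrogate for this situation: a dual
adult test lung whose two compliant chambers vent through orifice-type
("parabolic") resistors and a shared ventilator breathing circuit, under
volume-control, constant-flow ventilation.

## The model

### Components

Every resistive element is an orifice-type loss,

$$\Delta P = \tfrac{k}{2}\,\rho\,\bar U\,|\bar U|, \qquad \bar U = Q/A,$$

with a dimensionless, purely geometric loss coefficient $k$ and entrance
area $A$.  The signed form keeps the law antisymmetric, so reverse
(pendelluft) flows are representable.  The corresponding *equivalent
linear resistance* $R = \Delta P / Q$ grows linearly in both flow and gas
density; its tabulated values at reference flows are what resistor vendors
print.  Because the table quotes $k$ and $R$ but not $A$,
`calibrate_area()` recovers the one entrance area consistent with a chosen
table cell; we calibrate from the Rp50/air/60 l/min cell
($k = 132.9$, $R = 108.4\ \mathrm{cmH_2O\,s/l}$), the cell printed with
the most significant figures, and the remaining eleven cells are then
reproduced within their two-significant-figure rounding.

Gas density comes from the ideal-gas law on the mole-fraction-weighted
molar mass; the bench gases are dry and near ambient, so no compressibility
factor is applied and the default reference state is 293.15 K, 101325 Pa
(configurable).  Viscosity is deliberately not modelled: every loss in
this system is inertial.  The 78/22 He/O$_2$–to–air density ratio is
0.3517, the factor by which every inertial resistance falls when heliox is
substituted at fixed flow.

### Governing equations

During expiration (atmospheric reference pressure zero) each chamber $i$
with opposite chamber $j$ obeys the quasi-steady energy balance

$$\frac{V_i}{C_i} \;=\; \frac{(k_i + k_{fs})}{2}\rho\left(\frac{Q_i}{A}\right)\left|\frac{Q_i}{A}\right|
\;+\; \frac{k_{cct}}{2}\rho\left(\frac{Q_i+Q_j}{A}\right)\left|\frac{Q_i+Q_j}{A}\right|,$$

elastic recoil balancing the branch loss (inserted resistor $k_i$ plus
branch flow sensor $k_{fs}$) and the shared expiratory-circuit loss
$k_{cct}$ at the combined flow.  During inspiration the expiratory valve
is closed and the ventilator's square-wave total flow splits so that both
branches see a common Y-piece pressure.  Flows at each instant satisfy the
static balance — gas compressibility and component inertia are neglected,
so phase transitions are instantaneous.

### Numerics

The coupled expiratory system reduces to one scalar equation in the
junction pressure $P_c$: given $P_c$ each branch flow follows in closed
form, and $P_c$ must equal the circuit loss at the combined flow.  The
residual is strictly increasing in $P_c$, so the root is unique, bracketed
by $[0, \max(P_L, P_R)]$, and found by `uniroot()` to a tolerance of
about $10^{-10}$ cm H$_2$O.  The inspiratory split is the analogous
monotone scalar problem in $Q_L$.  Volumes advance by explicit first-order
quadrature (default $dt = 1$ ms), clamped at zero (volumes are measured
above the relaxed volume, so recoil pressure vanishes at $V = 0$).
Halving $dt$ halves the end-expiratory volume error; at 1 ms the simulated
single-chamber emptying matches its closed form to well under 0.5% RMS of
the peak flow.

A configuration switch (`allow_pendelluft`) controls whether expiratory
branch flows may go negative.  With it on (default), a chamber whose
recoil falls below the junction pressure transiently receives gas expired
by the other chamber — the pendelluft redistribution seen in bench
experiments as the two compartments cycle out of phase.  With it off,
outflows are clamped at zero and the chambers empty independently.

### The single-chamber oracle

With one chamber and all loss lumped into $k_{tot}$, the balance
integrates exactly: $\sqrt{V}$ decreases linearly, the flow decays
*linearly* (not exponentially), and the chamber empties at

$$t_{empty} = \frac{\sqrt{2\,V_0\,C\,\rho\,k_{tot}}}{A}.$$

`single_chamber_emptying()` implements this closed form; the test suite
verifies the time-stepping simulator against it, including the exact
$\sqrt{\rho}$ scaling of $t_{empty}$ between air and heliox.

## Time constants

A linear one-compartment lung empties mono-exponentially with
$\tau = RC$.  Quadratic-resistance emptying is not exponential, so an
*apparent* time constant is computed by a fixed-point iteration on the
end-expiration volume relation:

$$\tau = \frac{V_{e,tot}}{Q_{e,p}}\left(1 - e^{-t_e/\tau}\right)^{-1},
\qquad \tau_0 = \frac{V_{e,tot}}{Q_{e,p}}, \qquad
\tau_{k+1} = \frac{\tau_0}{1 - e^{-t_e/\tau_k}}.$$

The iterates increase monotonically from $\tau_0$ and are bounded, so the
scheme converges for any summary with $V_{e,tot} < Q_{e,p}t_e$; for a
truncated mono-exponential the fixed point is exactly the generating
$\tau$.  The contraction rate is
$x e^{-x}/(1 - e^{-x})$ with $x = t_e/\tau$: fast when the window spans
several time constants, but slow as $\tau$ approaches and exceeds $t_e$ —
for $\tau \approx 2 t_e$ a dozen iterations are needed to settle below 1%
change.  In that regime $V_{e,tot}/(Q_{e,p}t_e) \to 1$ and the estimate is
ill-conditioned; it should be read as an index of expiratory flow, not a
decay constant.

`ventilator_rc()` emulates the expiratory RC a ventilator reports: the
ratio of expiratory tidal volume to expiratory flow read at 75% of the
tidal volume.  The phrase is ambiguous; we read it as (remaining
volume)/(flow) at the first instant where 75% of the expired volume
remains, because for an ideal mono-exponential remaining volume and flow
stay strictly proportional and that reading returns $\tau$ exactly.  Two
alternative readings (`"exhaled25"`, `"exhaled75"`) are provided behind an
argument rather than silently chosen.

For noisy recorded traces, `extract_breath_summary(peak_window = ...)`
refines the peak-flow estimate by a local quadratic fit around the
maximum of a lightly smoothed copy; the raw sample maximum rides on the
largest noise excursion and biases $\tau$ low by several percent at 2%
RMS noise, while the refined estimate is unbiased to within 0.1%.
Unlabelled traces are segmented into expirations by zero crossings with a
hysteresis threshold (default 1% of the trace peak).

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| resistor $k$ (Rp5/Rp20/Rp50) | – | 3.3 / 21.5 / 132.9 | catalogue loss coefficients of the bench resistors |
| entrance area $A$ | m$^2$ | $8.66\times10^{-5}$ | calibrated from the Rp50/air/60 l/min cell; shared by all resistors (the table's internal ratios confirm a common geometry) |
| compliance $C$ | l/cmH$_2$O | 0.02 / 0.05 / 0.10 | the bench study's compliance settings (equal left/right) |
| flow-sensor loss $k_{fs}$ | – | 1.2 | assumption: a variable-orifice sensor dropping $\sim$1 cmH$_2$O at 60 l/min of air |
| circuit loss $k_{cct}$ | – | 5.0 | assumption: whole expiratory path $\sim$5 cmH$_2$O·s/l at 60 l/min of air, between the Rp5 and Rp20 elements, with losses dominated by flow sensor and expiratory valve |
| ventilation patterns | – | 500 ml @ 12/min, 1000 ml @ 20/min, I:E = ½, square flow | the two study breathing patterns (6 and 20 l/min minute ventilation) |
| time step $dt$ | s | 0.001 | first-order quadrature error $\ll$ all stated tolerances |
| steady-cycle tolerance | l | $10^{-4}$ | end-expiratory volume change per breath below 0.1 ml |

The $k_{fs}$ and $k_{cct}$ defaults are documented **assumptions, not
measurements**: the study's measured circuit pressure–flow polynomials
were never published.  Users with bench data should replace them via
`fit_pressure_flow_polynomial()` on a measured `pressure_flow_curve()`
(per-gas, zero intercept), or adjust the inertial coefficients.
Polynomial fits apply only to their fitted gas; transferring a circuit to
another gas requires the inertial form, which scales with density —
`inertial_collapse_check()` diagnoses whether measured curves actually
collapse on $\rho Q^2$ as a purely inertial element must.

### Sensitivity to the assumed circuit

The apparent time constant of an obstructed chamber depends appreciably
on the circuit assumption.  For the worked heliox case (C = 0.05, right
branch Rp50, 1000 ml @ 20/min), sweeping the circuit from lossless to
twice the default moves $\tau_{right}$ from about 0.90 s to about 1.77 s
(default: 1.49 s); the lossless value is the structural floor, since the
inhalation split delivers $\approx$0.34 l to the obstructed chamber and
its closed-form lossless emptying already takes 1.60 s.  The acceptance
test for this case reports the sensitivity table alongside its check.

## What the simulations do and do not show

The study grid (`run_study_grid()`) sweeps 3 right-branch resistors × 3
compliances × 2 gases × 2 patterns = 36 points, each run to a steady
cycle (extension in chunks up to 24 breaths; deep gas-trapping points
need ~12).  Reproduced qualitative conclusions, asserted as orderings in
the tests: heliox shortens every time constant; higher minute ventilation
lengthens them; the obstructed chamber's $\tau$ rises steeply with its
loss coefficient while the whole-lung $\tau$ rises much less and the
opposite chamber's $\tau$ *falls* slightly (pendelluft); $\tau$ grows
near-linearly with compliance in the symmetric configuration
($R^2 > 0.98$); and the ventilator-style RC correlates well with the
whole-lung and unobstructed-chamber $\tau$ but poorly with the obstructed
chamber's — the clinical point that ventilator-level monitoring can miss
regional trapping.

Known limitations, deliberate:

* Quasi-steady flows — no component inertia or friction of the test-lung
  hardware (bellows, plates, hinges), which is the main reason modelled
  traces switch phase instantly while bench traces lag, and modelled
  time constants differ from measured ones.
* The left-chamber $\tau$ decrease with rising right-side obstruction is
  reported, not asserted as an invariant: its size depends on the signed
  flow option and the circuit magnitude.
* In the deepest trapping corner (air, 20 l/min minute ventilation,
  C = 0.10) the apparent-$\tau$ index saturates ($t_e/\tau < 1$) and is
  no longer monotone in the obstruction coefficient; with the stronger
  default circuit coupling the right chamber's emptying there is
  pendelluft-delayed and nearly flat-topped.
* Two compartments only; equal left/right compliance is the tested
  regime (unequal values are accepted in configuration but heterogeneous
  compliance is not studied).  Dry gas; no humidity or temperature
  conditioning; no endotracheal tube; no PEEP-dependent valve behaviour.

## A worked example

```{r example, eval = FALSE}
A <- default_resistor_area()
sys <- lung_system(
  left  = lung_chamber(0.05, parabolic_resistor(3.3, A)),   # healthy side
  right = lung_chamber(0.05, parabolic_resistor(132.9, A)), # obstructed
  gas = heliox())
sim <- simulate_lung(sys, ventilator_settings(1.0, 20))
breath_time_constants(sim)
```

The synthetic-trace generators (`make_synthetic_trace()`) provide
mono-exponential, bi-exponential and simulator-derived fixtures with known
ground truth for estimator validation; they emulate idealised expiratory
flow signals with optional additive Gaussian noise, not the
sensor-specific artefacts (drift, quantisation, valve chatter) of real
bench recordings, so passing estimator tests demonstrate correctness of
the algorithms, not robustness to every measurement pathology.
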