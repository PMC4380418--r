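---
title: "Modelling a rotary-zone thermal cycler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a rotary-zone thermal cycler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rzcycler)
```

## The machine and its model

A rotary-zone thermal cycler (RZTC) performs PCR *spatially*: instead of
ramping one block up and down, several blocks held at fixed temperatures
sit on a stepper-driven wheel, and the wheel rotates to bring each block
into contact with a stationary sample capillary. Ramp rate is then limited
not by block thermal mass but by (i) how fast the wheel turns and (ii) how
fast the small sample/capillary lump equilibrates with the newly arrived
block. `rzcycler` is a digital twin of this machine class: it predicts
sample temperature histories, protocol runtimes and reagent budgets from
geometry, material properties and motor settings, and fits the thermal
response model to logged traces.

### Lumped-capacitance thermal response

The sample plus the engaged capillary wall are treated as a single
isothermal lump exchanging heat with an effectively infinite block
reservoir. After a block at temperature $T_B$ engages at time $t_0$, the
lump temperature follows a bounded exponential

$$T(t) = T_B + (T_{SC} - T_B)\, e^{-(t - t_0)/\tau},$$

where $T_{SC}$ is the lump temperature at engagement and $\tau = RC$ is
the product of

* the half-cylinder radial conductive resistance of the capillary wall,
  $R = \ln(d_o/d_i) / (\pi L k_c)$, and
* the lump capacitance
  $C = L \tfrac{\pi}{4}\left[\rho_s c_s d_i^2 +
  \rho_c c_c (d_o^2 - d_i^2)\right]$,

with $d_i, d_o$ the bore and outer diameters, $L$ the engaged length,
$k_c$ the wall conductivity, and $\rho c$ volumetric heat capacities of
sample ($s$) and wall ($c$). Because $R \propto 1/L$ and $C \propto L$,
the time constant is a property of the tube cross-section and its
contents alone — the package asserts this cancellation to twelve
significant digits. Assumptions inherited from the model: contact
resistance between tube and block is negligible (tensioned tube; an
optional additive term is available on `wall_resistance()` and
`predict_time_constant()`), internal sample resistance is negligible
(sub-millimetre bore), and convective losses are ignored.

```{r tau}
mats <- default_materials()
fep <- capillary_spec(406e-6, 794e-6, mats$FEP)
predict_time_constant(fep)          # water-filled FEP tubing

wire <- list(diameter = 50e-6, material = mats$thermocouple)
pc <- capillary_spec(562e-6, 750e-6, mats$polycarbonate)
predict_time_constant(pc, bore_contents(mats$water, list(wire, wire)))
```

The property table behind these numbers (water 997 kg/m³, 4181 J/kg·K;
FEP k = 0.195 W/m·K, 2150 kg/m³, 1172 J/kg·K; polycarbonate k = 0.20,
1200, 1200; aluminum c_p = 897 J/kg·K; K-type thermocouple wire averaged
to 8700 kg/m³, 450 J/kg·K) uses handbook values and is overridable
through the cycler configuration file. A fine-gauge in-bore thermocouple
is modelled as two parallel wire cylinders displacing sample water; the
junction bead is ignored (its contribution to bore capacitance is below
2%).

Finite blocks are handled by `equilibrium_temperature()`: engaging a lump
of capacitance $C_{SC}$ with a block of capacitance $C_B$ settles at the
capacitance-weighted mean of the two temperatures. With a 55 g aluminum
block ($C_B \approx 49.3$ J/K) and a ~4 µL engaged sample the ratio
$C_{SC}/C_B$ is below $10^{-3}$, which is why treating blocks as
reservoirs is sound for this hardware.

### Wheel kinematics

The stepper drive uses a trapezoidal velocity profile: accelerate at $a$
to cruise velocity $v$, cruise, decelerate. A move of $d$ microsteps takes
$t = d/v + v/a$ (or the triangular $2\sqrt{d/a}$ for short moves). The
microstep-per-segment distance is never assumed from motor resolution;
`calibrate_steps_per_segment()` inverts the trapezoidal formula at one
observed single-segment transition. With the reference settings
(a = 6103.52 µsteps/s², v = 4000 µsteps/s) calibrated at 1.32 s:

```{r kin}
motion <- motion_profile(6103.52, 4000)
layout <- wheel_layout(4, calibrate_steps_per_segment(1.32, motion))
transition_time(1:3, motion, layout)
```

Note the calibrated increments are $d/v = 0.665$ s per extra segment, so
the two- and three-segment times (1.985, 2.649 s) sit a few milliseconds
under their commonly quoted rounded values (1.99, 2.66 s); the printed
triplet implies a 0.67 s increment that is not exactly consistent with a
1.32 s single-segment time under this profile. The package reports what
the calibrated model computes.

Because heater power and sensor wiring reach the wheel through a fixed
harness, cumulative rotation is limited to ±270°. `plan_rotation()`
minimises segment count, breaks ties toward unwinding the harness, and
takes the long way around when the short way would exceed the limit; a
property test drives it with random request sequences and asserts the
limit is never violated. One practical consequence: protocols that cycle
the same three adjacent blocks repeatedly eventually pin the twist at the
limit and must reverse with a long rotation — the compiled two-stage STR
protocol below spends an extra ~1.3 s per stage-2 cycle for exactly this
reason.

`drive_temperature_schedule()` converts a rotation plan into the forcing
seen by a point on the sample bolus. Points offset from the bolus centre
switch blocks earlier or later (by $2\,\delta/\omega$ at cruise angular
rate $\omega$ for offset $\delta$), which is the mechanism by which
block-to-block transitions deviate from ideal steps. The insulated
inter-block gaps are treated as adiabatic holds — the sample keeps its
temperature while over felt insulation for the <0.2 s of gap traversal.

### Protocol compilation

`compile_protocol()` turns a thermal program (hot start, cycled stages,
final step) into rotations plus dwells. Conventions that matter:

* heated blocks are arranged around the wheel in order of increasing
  (final) temperature; a spare segment is reserved unheated for
  load/unload when the protocol needs fewer temperatures than segments;
* the dwell timer starts when rotation stops, not when the sample has
  settled (settling shortfalls are reported by `validate_protocol()`,
  which warns when a dwell is under $3\tau$ or when adjacent segments
  differ by more than 60 K);
* the initial rotation from the load segment counts toward the runtime,
  the final unload rotation does not;
* when a protocol needs more temperatures than the wheel has segments, a
  block setpoint change reuses a block between stages. Its stabilization
  time is a user-supplied parameter (heater control dynamics are not
  modelled); the compiler runs it concurrently with cycling and inserts a
  wait only if the block would be engaged too early.

```{r compile}
ph <- load_protocol("phusion_gapdh")
compile_protocol(ph, assign_blocks(ph, layout), layout, motion)

pp <- load_protocol("powerplex16")
compile_protocol(pp, assign_blocks(pp, layout), layout, motion)
```

The 26-cycle single-plex protocol compiles to 20.5 min and the 32-cycle
two-stage STR protocol to 91.0 min, matching the reference run times of
21 and 91 min to within a minute. For the STR protocol, ordering blocks
by *final* setpoint places the dual-setpoint (96 → 90 °C) block at wheel
position 2 between 70 and 94 °C — the arrangement the reference hardware
used — and its 18 min stabilization completes during stage-1 cycling
(~18.5 min), so no wait is inserted.

### Fitting logged traces

`fit_exponential()` implements the two-parameter $(\tau, t_0)$ fit:
solve the bounded exponential exactly through two points of the
transition, then refine by derivative-free maximisation of $R^2$
(Nelder-Mead, function tolerance $10^{-12}$), never returning a fit worse
than the two-point seed. Choices the procedure leaves open and how this
implementation resolves them:

* *Which two points seed the fit* is not dictated by the method; the
  samples nearest 33% and 80% of the temperature span are used (robust to
  noise at both extremes) and are configurable via `anchor_fractions`.
* *Asymptote temperatures* come from 10%-trimmed means of the flanking
  plateau samples, restricted to samples within 10% of span of the
  trace-level plateau temperature so that still-settling samples cannot
  bias the estimate. Across segments the median is used, which tolerates
  one segment with a truncated plateau (e.g. at the start of a log).
* *The fit range* runs from transition onset (departure beyond 2% of
  span) to the end of the segment.

Upstream of the fit, `segment_cycles()` splits a cycling trace at 10%/90%
span thresholds into alternating rising/falling transitions (plateau runs
are merged across noise-induced threshold wiggle), and
`baseline_align_average()` rescales each segment to common asymptotes,
aligns them by mid-span crossing plus correlation refinement, and
averages pointwise on a common grid.

```{r fit}
spec <- synthetic_trace_spec(0.57, square_wave_schedule(60, 96, 60, 5),
                             noise_sd = 0.3, rate = 10, seed = 42,
                             T_initial = 60)
tr <- generate_trace(spec)
segs <- segment_cycles(tr)
rising <- segs[vapply(segs, `[[`, character(1), "direction") == "heating"]
fit <- fit_exponential(baseline_align_average(rising))
fit
rise_fall_report(fit, 36)
```

## What the synthetic generator does and does not emulate

`generate_trace()` produces the closed-form response to a drive schedule,
sampled at a nominal 10 Hz, with i.i.d. Gaussian sensor noise
(σ = 0.3 °C by default, chosen so fitted $R^2$ sits at the ~0.99 level
typical of real in-capillary thermocouple logs) and an optional linear
drift. It emulates the reference characterisation conditions: cycling
between 60 and 96 °C with ~60 s dwells, five cycles, logging through one
full final dwell. It does **not** emulate: non-ideal step forcing during
rotation (available separately via the bolus-offset schedule), heating /
cooling asymmetry from wheel friction (supported as an optional
per-direction τ but not generated), sensor lag, quantisation, or
autocorrelated noise. Passing the recovery tests therefore shows the
estimator is unbiased and precise under the stated noise model, not that
every real-world artefact is handled.

Under those conditions the seeded experiment in the test suite (100
averaged-5-cycle fits) recovers τ with a median relative error of about
0.5% and a worst case under 2%.

## Cleaning ledgers

The five between-run cleaning protocols (A conservative … E minimal) are
shipped as data files and summed by `reagent_totals()` /
`duration_estimate()`. Published totals pin the bleach budgets (270, 270,
270, 90, 0 µL) and protocol E's water (three 500 µL syringe flushes);
per-step volumes that were never printed are reconstructed so the ledger
reproduces the published water totals (4.3, 3.8, 3.8, 2.3, 1.5 mL) and
are marked as such in the files. Water totals count syringe-delivered
water only. Manual tip-agitation steps carry 75 s (five vials at a
nominal 15 s each, the midpoint of the quoted 10–20 s range). The timing
configuration (12.3 µL/s normal flow, 25 µL/s fast, 21 s per-operation
overhead, 3 s per valve actuation) was calibrated once against the five
published run times and reproduces all of them within 10%; it is a
fixture, not a measurement.

## Numerical choices and limitations

* Simulation is closed-form per drive interval; the sampling interval
  `dt` (default 0.1 s, matching 10 Hz logging) affects only where the
  trace is sampled. Test oracles integrate the underlying ODE with
  explicit Euler at 0.25 ms substeps, keeping the oracle's own error well
  below the 0.01 °C comparison band.
* Problem sizes in the shipped tests (five 5-cycle traces per direction,
  100-fit recovery experiments, 50-move random rotation sequences) were
  chosen as the smallest sizes at which the statistical assertions are
  stable.
* Heater PID dynamics, block setpoint transients (e.g. undershoot after
  an in-run setpoint change), convection losses, bolus drift and bubble
  formation are out of scope; where the hardware exhibits them the model
  exposes parameters (stabilization time, per-direction τ) rather than
  physics.
* All temperatures are °C, times s, geometry SI; conversion happens only
  at file boundaries.
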