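---
title: "Dynamic range, respiratory gating, and treatment time in line-scanning proton therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic range, respiratory gating, and treatment time in line-scanning proton therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linegate)
```

## The delivery-time problem

In line-scanning proton delivery, a treatment field is an ordered stack of
energy layers, and each layer is a set of line segments painted at one
beam energy. The whole layer is delivered at a single dose rate, and the
scanning magnet cannot exceed a maximum speed `speed_max`. A segment of
length $L_i$ carrying monitor-unit weight $MU_i$ scanned at dose rate $R$
(MU/s) moves at speed $R \cdot L_i / MU_i$, so the segment with the
smallest $MU_i / L_i$ ratio pins the layer dose rate:

$$R_\mathrm{initial} = \min_i \frac{MU_i}{L_i} \cdot \mathrm{speed}_{\max}.$$

Plans optimized for dose conformality often place a few very low-MU
segments in a layer, dragging the dose rate of the *entire* layer down by
orders of magnitude and inflating beam-on time.

A **dynamic-range (DR) constraint** caps the permitted ratio of maximum to
minimum MU within each layer at a value $D \ge 1$. The model applies it in
four steps:

1. compute the baseline dose rate above;
2. raise the minimum-MU floor to $MU_{\max} / D$;
3. clamp every sub-floor segment up to the floor,
   $MU_i^{\mathrm{adj}} = \max(MU_i,\, MU_{\max}/D)$, and recompute the
   binding rate $R_D = \min_i (MU_i^{\mathrm{adj}} / L_i) \cdot
   \mathrm{speed}_{\max}$, capped at the machine dose-rate limit when one
   is configured;
4. per-segment beam-on time $BoT_i = MU_i^{\mathrm{adj}} / R_D$; the layer
   beam-on time is the sum.

Clamping (rather than rescaling all weights proportionally) is what a
minimum-MU threshold means operationally: only sub-floor weights move.
For a worked five-segment layer with MUs spanning
$10^{-3}$–$2\times10^{-2}$, DR = 10 elevates the two smallest weights to
the floor, doubles the layer dose rate, and roughly halves the layer
beam-on time:

```{r}
lay <- energy_layer(189.6, mu = c(0.0013, 0.0198, 0.0178, 0.0056, 0.0010),
                    length_cm = 0.6)
machine <- machine_spec(speed_max = 2000, t_ls = 2)
adjust_layer(lay, dr = Inf, machine)
adjust_layer(lay, dr = 10, machine)
```

Two identities anchor the model. An unconstrained DR (`Inf`) is a strict
no-op: MUs untouched, baseline rate, baseline beam-on time, bit for bit.
And a DR looser than the layer's intrinsic $MU_{\max}/MU_{\min}$ ratio
elevates nothing, so it reproduces the baseline rather than slowing
delivery — with uniform segment lengths the step-3 rate reduces exactly to
$\max\!\big(R_\mathrm{initial},\, (MU_{\max}/L)\cdot
\mathrm{speed}_{\max}/D\big)$, the printed two-formula form.

**Heterogeneous segment lengths.** The schema permits per-segment lengths,
and the dose-rate formulas then use per-segment $MU_i/L_i$ ratios (the
single-length formulas are the uniform special case). One consequence is
worth stating plainly: when lengths differ, the binding segment after
elevation need not be an elevated one, so raising the floor can add MU
without raising the rate — beam-on time can *increase* as DR decreases.
Monotonicity of beam-on time in DR is therefore guaranteed (and tested)
only in the uniform-length regime, which is the regime the four-step
formulas were written for; with mixed lengths the package still guarantees
the scan-speed bound, the path-length floor
$\sum_i L_i / \mathrm{speed}_{\max}$, and upward-only MU adjustment.

## Respiratory gating

The breathing surrogate is a three-component sinusoidal model evaluated at
the normalized phase $x = 2\pi t / T_R$:

$$\mathrm{Sig}(x) = \tfrac{1}{2}\big[\sin x + \sin(2x + 0.7\pi) +
\sin(2x + \pi) - 5.4\big].$$

The additive constant and global halving follow the published form of this
model; because gating only compares the signal to a threshold, neither
affects any schedule, and `respiratory_model(signal = ...)` accepts any
$2\pi$-periodic replacement. This waveform has two minima per cycle, so
moderate-duty gates open **twice** per breath — a feature, not a bug, of
the chosen waveform.

Amplitude gating permits the beam while the signal is at or below a
threshold (end-exhale gating, the clinical norm for liver; the sense is
configurable). Clinically one specifies a **duty cycle** — the open
fraction of the period — so `threshold_for_duty()` inverts the
dwell-fraction map by bisection against a 40 000-sample midpoint grid,
recovering any requested duty in $(0,1]$ to about $10^{-3}$. The duty has
no universal clinical default, so it is a required, logged parameter of
every sweep report; examples in this package use 0.3 as a representative
mid-range window. Gate-interval boundaries are then located by bisection
to $10^{-6}$ s, and schedules are exactly periodic in $T_R$ (intervals are
computed once per period and tiled, merging across cycle boundaries).
Intervals are half-open $[\mathrm{on}, \mathrm{off})$: an event landing
exactly on a boundary belongs to the earlier state, so a layer switch
ending exactly at gate close waits for the next window.

## Gated delivery simulation

`simulate_field()` walks the layers in order. Beam is delivered only
inside gate windows; by default delivery is **interruptible** — the beam
pauses at a gate-off edge, carries the residual beam-on time, and resumes
at the next window. (Segment granularity is milliseconds, far below the
gating timescale, so modeling beam-on time as a divisible per-layer fluid
is the natural resolution; a whole-layer deferral mode,
`sim_config(interruptible = FALSE)`, is provided for comparison and errors
if a layer cannot fit any window.) After each non-final layer the
energy-layer switch of duration `t_ls` starts immediately and runs
regardless of gate state — switching excludes beam-on but does not need
the gate, and this overlap with gate-off time is exactly where
synchronization benefits come from. The next layer starts at the first
post-switch, gate-open instant.

Every timeline satisfies, by construction and by test,

$$T_\mathrm{total} = T_\mathrm{BoT} + T_\mathrm{LS}\,(N_\mathrm{Layer}-1)
+ T_\mathrm{dead}, \qquad T_\mathrm{dead} \ge 0,$$

with $T_\mathrm{dead}$ absorbing all gating-induced waits. The clock
starts at the respiratory-cycle origin by default (`start_phase` shifts
it; `clock_origin = "first_beam_on"` reports from the first beam pulse
instead).

An independent **time-stepping oracle** (`oracle_simulate()`) re-derives
the totals by advancing a 1 ms clock against the same gate and is used in
the test suite to cross-validate the event-driven simulator to within
2 ms on randomized instances (mixed square and sinusoidal gates, random
layer counts, durations, switching times and start phases).

## The plateau

When every layer's beam-on time fits inside one gate window and the
layer-plus-switch interval spills past the window's close, the next layer
always begins at the next window start: delivery is quantized by the
respiratory cadence, and shrinking any non-final layer's beam-on time
cannot change the total. That is the plateau mechanism, and it is tested
as an exact invariance (halving non-final beam-on times leaves
$T_\mathrm{total}$ bit-identical in constructed cases).

`sweep_dr()` traces $T_\mathrm{total}$ over a DR grid (default:
unconstrained, then 200 down to 10 in steps of 10 — a dense superset of
the common five validation values) and `find_plateau()` reports, per
field, the **largest** DR whose total is within $\varepsilon$ of the grid
minimum — the point below which further DR reduction buys no time while
still costing intensity-modulation freedom. $\varepsilon$ defaults to 1%
of the minimum total (no published tolerance exists; 1% is well below any
clinically meaningful time difference and above simulation noise, and it
is overridable in seconds). If only the smallest grid value qualifies
there is no plateau. The plan-level plateau is the largest per-field
plateau, so no field is over-constrained, and is reported as none if any
field lacks one. Interpolated curves in plots are presentation only.

```{r, fig.width = 6, fig.height = 4}
plan <- generate_plan(plan_gen_spec(n_fields = 1, n_layers = 12,
                                    segments_per_layer = c(50, 150),
                                    seed = 11))
sw <- sweep_dr(plan, dr_values = c(Inf, seq(200, 10, by = -10)),
               resp = respiratory_model(period = 3),
               gate = gate_config(duty = 0.3),
               machine = machine_spec(t_ls = 2))
find_plateau(sw)
plot(sw)
```

## The synthetic plan generator

No public interchange format exists for line-scanning plans, so the
package defines a small versioned JSON schema (with a flat CSV dialect)
and ships a seeded generator for study-shaped plans: 2–3 fields, 25–35
energy layers per field stacked from high to low energy within
70–230 MeV, 100–500 segments per layer of 0.6 cm, and within-layer MU
weights drawn lognormal with meanlog $-4.5$ and sdlog $1.2$ — placing the
bulk of weights in the $10^{-3}$–$10^{-2}$ MU decade spanned by the worked
example layer, with min–max ratios frequently exceeding two orders of
magnitude so the DR constraint actually binds. Published per-layer MU
distributions for a clinical cohort do not exist; these defaults are
plausible stand-ins and nothing downstream depends on their exact shape.
Each field and layer draws from its own derived RNG stream, so a seed
pins the plan exactly and enlarging a plan never reshuffles earlier
layers.

What the generator does *not* emulate: anatomy-driven correlations
between layer energy, segment count and MU; optimizer re-distribution of
weights under a DR constraint (a planning-system behavior); irregular or
drifting breathing. Passing tests on synthetic plans therefore
demonstrate the correctness of the timing model and simulator, not
cohort-level clinical time savings.

## Numerical choices and problem sizes

- Gate boundary bisection: $10^{-6}$ s; duty calibration: $10^{-3}$
  absolute on the recovered duty; schedule tiling merges intervals that
  touch within $10^{-12}$ s, and delivery treats sub-picosecond window
  slivers as the boundary itself.
- Worked-example comparisons use the printed table's rounding grain
  ($5\times10^{-4}$ s on layer totals, $10^{-4}$ s per segment,
  $5\times10^{-5}$ MU on adjusted weights, 1% relative on dose rates),
  since the printed inputs are themselves 4-decimal roundings.
- The default machine has no dose-rate cap: the scanning-speed bound alone
  produces the DR $\to$ 1 plateau. An optional `max_dose_rate` cap is
  available where the machine limit is known.
- Test problem sizes: property suites use 40–200 random layers of 10–80
  segments, 500 random timelines, and 50 oracle cross-validations at 1 ms
  steps; these sizes make the full suite complete in well under a minute
  while exercising every code path.

## Known limitations

- No modeling of within-layer dead time between segments, beam-current
  ramping, spot-position verification, gantry or imaging time, or
  inter-field setup; per-field totals are reported independently, never
  summed by default.
- Dose is out of scope entirely: the package predicts *time*, not the
  dosimetric cost of MU elevation, and does not re-optimize plans.
- The breathing model is strictly periodic; irregular breathing shifts
  gate windows in ways the simulator does not attempt to capture.
- DICOM RT Ion Plan import is a documented extension point, not a
  feature: vendor spot-map conventions vary, so conversion to the JSON
  schema happens upstream.
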