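# linegate

Treatment-time prediction for respiratory-gated line-scanning proton
therapy under dynamic-range constraints.

## The problem

In line-scanning proton delivery every energy layer is painted at a single
dose rate, and the scanner cannot exceed its maximum speed, so the segment
with the smallest monitor-unit weight per centimetre pins the dose rate of
the whole layer:

    doserate_initial = min_i(MU_i / L_i) * Speed_max

Conformal plans often contain a few very low-MU segments that drag a
layer's dose rate down by orders of magnitude. A **dynamic-range (DR)**
constraint caps the permitted MU_max/MU_min ratio within each layer:
segments below the floor `MU_max / DR` are clamped up to it,

    MU_adj_i   = max(MU_i, MU_max / DR)
    doserate_DR = min_i(MU_adj_i / L_i) * Speed_max
    BoT_i      = MU_adj_i / doserate_DR

raising the dose rate and shrinking beam-on time at the cost of
intensity-modulation freedom.

Under amplitude-based respiratory gating, however, total treatment time

    T_total = T_BoT + T_LS * (N_Layer - 1) + T_dead,   T_dead >= 0

is quantized by the breathing cadence (T_LS is the energy-layer switching
time; T_dead absorbs all gate-off waits). Once each layer plus its switch
fits the gating rhythm, further DR reduction buys **no** time. `linegate`
models the DR effect per layer, simulates gated layer-by-layer delivery
with an event-driven engine (cross-validated against an independent
time-stepping oracle), and sweeps DR to find the patient-specific plateau
below which DR reduction only costs plan quality.

For whom: medical physicists and planners studying gated line-scanning
delivery efficiency, and anyone needing a reproducible delivery-time
simulator for method development.

## Worked example

The five-segment 189.6 MeV layer with MUs {0.0013, 0.0198, 0.0178, 0.0056,
0.0010}, 0.6 cm segments, at 2000 cm/s:

```r
library(linegate)
lay <- energy_layer(189.6, mu = c(0.0013, 0.0198, 0.0178, 0.0056, 0.0010),
                    length_cm = 0.6)
machine <- machine_spec(speed_max = 2000, t_ls = 2)
adjust_layer(lay, dr = Inf, machine)
#> DR-adjusted layer (189.6 MeV): dr = unconstrained, dose rate = 3.333 MU/s
#>   0/5 segments elevated; layer beam-on time = 0.01365 s
adjust_layer(lay, dr = 10, machine)
#> DR-adjusted layer (189.6 MeV): dr = 10, dose rate = 6.6 MU/s
#>   2/5 segments elevated; layer beam-on time = 0.007145 s
```

The lowest-MU segment (0.0010 MU over 0.6 cm) pins the baseline rate at
3.33 MU/s; DR = 10 clamps the two sub-floor segments up to 0.00198 MU,
doubling the rate to 6.6 MU/s and cutting layer beam-on time from
0.0137 s to 0.0071 s (reduction *to* 52%).

Sweeping a synthetic 12-layer field under gating (3 s breathing period,
30% duty cycle, 2 s layer switching):

```r
plan <- generate_plan(plan_gen_spec(n_fields = 1, n_layers = 12,
                                    segments_per_layer = c(50, 150),
                                    seed = 11))
sw <- sweep_dr(plan, dr_values = c(Inf, seq(200, 10, by = -10)),
               resp = respiratory_model(period = 3),
               gate = gate_config(duty = 0.3),
               machine = machine_spec(t_ls = 2))
sw
#> Dynamic-range sweep of plan 'synthetic_seed11': 21 dr values x 1 field(s)
#>   T_R = 3 s, t_ls = 2 s, duty = 0.3, phase = 0 s
#>   field_01: t_total 33.41-78.50 s, plateau dr = 40
find_plateau(sw)$plan
#> [1] 40
```

Beam-on time keeps falling all the way to DR = 10 (16.3 s unconstrained,
0.49 s at DR = 10), but below DR = 40 the *total* time is pinned at about
33.5 s by the gating cadence — the plateau. Choosing DR = 40 instead of 10
for this field buys the same treatment time with far less MU distortion.
`plot(sw)` draws the sweep; `render_report(sw, "sweep.csv", plot =
"sweep.png")` writes it out.

The same operations are available from the shell:

```sh
exec/linegate gen --seed 11 --n-fields 1 --layers 12 --segments 50:150 --out plan.json
exec/linegate sweep --plan plan.json --tr 3 --duty 0.3 --grid unconstrained,200:10:10 --out sweep.csv
```

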