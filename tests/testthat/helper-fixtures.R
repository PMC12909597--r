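# Shared fixtures built in code.

# The fully printed worked-example layer: 189.6 MeV, five 0.6 cm segments.
table1_layer <- function() {
  energy_layer(189.6, mu = c(0.0013, 0.0198, 0.0178, 0.0056, 0.0010),
               length_cm = 0.6)
}

table1_machine <- function() machine_spec(speed_max = 2000, t_ls = 2)

# Random layer with heavy-tailed MUs; optionally heterogeneous lengths.
rand_layer <- function(n = 50, mixed_lengths = FALSE) {
  suppressWarnings(energy_layer(
    runif(1, 70, 230),
    mu = rlnorm(n, -4.5, 1.2),
    length_cm = if (mixed_lengths) runif(n, 0.2, 1.5) else 0.6))
}

# Random gated-delivery instance for oracle cross-validation and
# property suites. Mixes square and sinusoidal-signal gates.
rand_delivery_case <- function(square = runif(1) < 0.5) {
  n <- sample(2:5, 1)
  bot <- runif(n, 0.3, 3)
  period <- runif(1, 3, 5)
  duty <- runif(1, 0.25, 0.8)
  machine <- machine_spec(t_ls = sample(c(0, 1, 2), 1))
  gates <- if (square) square_gate_schedule(period, duty, 10 * period)
  else gate_intervals(respiratory_model(period), gate_config(duty = duty),
                      10 * period)
  config <- sim_config(start_phase = runif(1, 0, period))
  list(bot = bot, gates = gates, machine = machine, config = config)
}
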