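# Seeded synthetic treatment plans.
#
# Emulates clinical line-scanning liver plans: 2-3 fields, tens of energy
# layers stacked from high to low energy (70-230 MeV), 100-500 line segments
# per layer, and heavy-tailed within-layer MU distributions spanning two or
# more orders of magnitude (a lognormal with meanlog -4.5, sdlog 1.2 puts
# most weights in the 1e-3 to 1e-2 MU decade, matching the magnitudes of a
# representative printed layer). The generator makes no attempt at anatomical
# realism; it exists so every downstream stage is testable without patient
# data.

#' Specification for a synthetic plan
#'
#' @param n_fields number of treatment fields (ports).
#' @param n_layers layers per field: a single count or a `c(min, max)` range.
#' @param segments_per_layer `c(min, max)` range of line segments per layer.
#' @param mu_distribution list describing the within-layer MU distribution:
#'   `list(kind = "lognormal", meanlog, sdlog)` or
#'   `list(kind = "uniform", min, max)` (uniform bounds must be > 0).
#' @param length_cm segment length in cm: a constant or a `c(min, max)` range.
#' @param energy_range `c(min, max)` beam energies in MeV; layer energies are
#'   drawn in this range and sorted descending (deepest layer first).
#' @param seed integer seed; the same seed always yields the identical plan.
#' @return Object of class `plan_gen_spec`.
#' @export
plan_gen_spec <- function(n_fields = 2,
                          n_layers = c(25, 35),
                          segments_per_layer = c(100, 500),
                          mu_distribution = list(kind = "lognormal",
                                                 meanlog = -4.5, sdlog = 1.2),
                          length_cm = 0.6,
                          energy_range = c(70, 230),
                          seed = 1L) {
  rng <- function(x) if (length(x) == 1L) c(x, x) else x
  n_layers <- rng(n_layers); segments_per_layer <- rng(segments_per_layer)
  length_cm <- rng(length_cm); energy_range <- rng(energy_range)
  if (n_fields < 1L) stop("n_fields must be >= 1")
  for (r in list(n_layers, segments_per_layer, length_cm, energy_range))
    if (r[1L] > r[2L]) stop("degenerate range: min > max")
  if (n_layers[1L] < 1L || segments_per_layer[1L] < 1L)
    stop("counts must be >= 1")
  if (length_cm[1L] <= 0) stop("length_cm must be positive")
  kind <- match.arg(mu_distribution$kind, c("lognormal", "uniform"))
  if (kind == "uniform" && mu_distribution$min <= 0)
    stop("uniform MU distribution must have positive lower bound")
  structure(list(n_fields = as.integer(n_fields), n_layers = n_layers,
                 segments_per_layer = segments_per_layer,
                 mu_distribution = mu_distribution, length_cm = length_cm,
                 energy_range = energy_range, seed = as.integer(seed)),
            class = "plan_gen_spec")
}

# Run `expr` under a derived seed without disturbing the caller's RNG state.
with_stream <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Stable per-(field, layer) sub-seed so adding layers or fields never
# reshuffles earlier draws; kept below 2^31 - 1.
stream_seed <- function(seed, field, layer = 0L) {
  (abs(seed) %% 1000003L) * 2039L + field * 7919L + layer * 104729L
}

#' Generate a synthetic treatment plan
#'
#' Deterministic given `spec$seed`: each field and each layer draws from its
#' own derived RNG stream, so the same seed reproduces the identical plan
#' and enlarging the plan does not reshuffle earlier layers.
#'
#' @param spec a [plan_gen_spec()].
#' @return A validated [treatment_plan()].
#' @examples
#' plan <- generate_plan(plan_gen_spec(seed = 42))
#' plan
#' @export
generate_plan <- function(spec) {
  stopifnot(inherits(spec, "plan_gen_spec"))
  pick <- function(r) {
    # sample() treats a length-1 vector as 1:n; guard degenerate ranges
    if (r[1L] == r[2L]) as.integer(r[1L]) else sample(r[1L]:r[2L], 1L)
  }
  draw_mu <- function(n) {
    d <- spec$mu_distribution
    if (d$kind == "lognormal") stats::rlnorm(n, d$meanlog, d$sdlog)
    else stats::runif(n, d$min, d$max)
  }
  fields <- lapply(seq_len(spec$n_fields), function(fi) {
    head <- with_stream(stream_seed(spec$seed, fi), {
      nl <- pick(spec$n_layers)
      list(nl = nl,
           energies = sort(stats::runif(nl, spec$energy_range[1L],
                                        spec$energy_range[2L]),
                           decreasing = TRUE))
    })
    layers <- lapply(seq_len(head$nl), function(li) {
      with_stream(stream_seed(spec$seed, fi, li), {
        ns <- pick(spec$segments_per_layer)
        len <- if (spec$length_cm[1L] == spec$length_cm[2L])
          spec$length_cm[1L]
        else stats::runif(ns, spec$length_cm[1L], spec$length_cm[2L])
        energy_layer(head$energies[li], mu = draw_mu(ns), length_cm = len)
      })
    })
    treatment_field(sprintf("field_%02d", fi), layers)
  })
  treatment_plan(sprintf("synthetic_seed%d", spec$seed), fields,
                 metadata = list(generator = "linegate::generate_plan",
                                 seed = spec$seed))
}

#' Square-wave gate test signal
#'
#' Reference gate indicator for hand-traceable tests: on exactly when
#' `(t %% period) < duty * period`.
#'
#' @param t time(s) in s (vectorized).
#' @param period gate period in s (> 0).
#' @param duty open fraction in (0, 1].
#' @return Logical vector: `TRUE` where the gate is open.
#' @export
square_gate_signal <- function(t, period, duty) {
  if (!is.numeric(period) || period <= 0) stop("period must be > 0")
  if (!is.numeric(duty) || duty <= 0 || duty > 1)
    stop("duty must be in (0, 1]")
  (t %% period) < duty * period
}
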