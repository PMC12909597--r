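# Dynamic-range beam-on-time model.
#
# In line scanning the whole layer is delivered at one dose rate, and the
# scanner cannot exceed speed_max, so the segment with the smallest MU per cm
# pins the layer dose rate: doserate = min_i(mu_i / length_i) * speed_max.
# A dynamic-range (DR) constraint raises the minimum permitted MU to
# mu_max / DR; sub-floor segments are clamped up to the floor, the binding
# ratio rises, and the layer delivers faster at the cost of intensity
# modulation. Beam-on time per segment is adjusted MU / layer dose rate.

check_dr <- function(dr) {
  stopifnot(is.numeric(dr), length(dr) == 1L)
  if (is.na(dr) || dr < 1)
    stop("dynamic range must be >= 1 (use Inf for unconstrained)")
  dr
}

#' Is a dynamic-range value unconstrained?
#'
#' `Inf` (or `NA`-free values >= 1) encode the constraint; `Inf` means no
#' dynamic-range constraint is applied.
#' @param dr numeric dynamic-range value.
#' @return Logical scalar.
#' @export
dr_unconstrained <- function(dr) is.infinite(check_dr(dr))

#' Baseline layer dose rate (no dynamic-range constraint)
#'
#' The dose rate the machine can sustain for the whole layer, pinned by the
#' segment minimizing `mu_i / length_i`:
#' `doserate_initial = min_i(mu_i / length_i) * speed_max`,
#' capped at the machine dose-rate limit when one is configured. For uniform
#' segment lengths this is `(mu_min / length) * speed_max`.
#'
#' @param layer an [energy_layer()].
#' @param machine a [machine_spec()].
#' @return Dose rate in MU/s.
#' @examples
#' lay <- energy_layer(189.6, c(0.0013, 0.0198, 0.0178, 0.0056, 0.0010), 0.6)
#' baseline_dose_rate(lay, machine_spec())  # 3.33 MU/s, pinned by segment 5
#' @export
baseline_dose_rate <- function(layer, machine) {
  stopifnot(inherits(layer, "energy_layer"), inherits(machine, "machine_spec"))
  rate <- min(layer$segments$mu / layer$segments$length_cm) * machine$speed_max
  cap_rate(rate, machine)
}

cap_rate <- function(rate, machine) {
  if (!is.null(machine$max_dose_rate)) min(rate, machine$max_dose_rate)
  else rate
}

#' Elevate segment MUs to the dynamic-range floor
#'
#' The DR constraint forbids MUs below `mu_max / dr`; any segment under the
#' floor is clamped up to it (segments already above it are untouched). The
#' clamp -- rather than a proportional rescale of all segments -- is what a
#' minimum-MU threshold means: only sub-floor weights move.
#'
#' @inheritParams baseline_dose_rate
#' @param dr dynamic-range value (>= 1; `Inf` = unconstrained, a no-op).
#' @return Numeric vector of adjusted MUs, one per segment, with attribute
#'   `n_elevated` counting the clamped segments.
#' @export
elevate_mu <- function(layer, dr) {
  stopifnot(inherits(layer, "energy_layer"))
  mu <- layer$segments$mu
  if (dr_unconstrained(dr)) return(structure(mu, n_elevated = 0L))
  floor_mu <- max(mu) / dr
  adj <- pmax(mu, floor_mu)
  structure(adj, n_elevated = sum(mu < floor_mu))
}

#' Layer dose rate under a dynamic-range constraint
#'
#' After elevation the binding segment is the one minimizing
#' `adjusted_mu_i / length_i`, so
#' `doserate_DR = min_i(adjusted_mu_i / length_i) * speed_max`,
#' capped at the machine limit when configured. With uniform segment lengths
#' and at least one elevated segment this reduces to
#' `(mu_max / length) * speed_max / dr`; when `dr` is looser than the layer's
#' intrinsic `mu_max/mu_min` ratio no segment is elevated and the baseline
#' rate is returned, so a loose constraint never slows delivery.
#'
#' @inheritParams elevate_mu
#' @param machine a [machine_spec()].
#' @return Dose rate in MU/s.
#' @export
dr_dose_rate <- function(layer, dr, machine) {
  stopifnot(inherits(machine, "machine_spec"))
  if (dr_unconstrained(dr)) return(baseline_dose_rate(layer, machine))
  adj <- elevate_mu(layer, dr)
  rate <- min(adj / layer$segments$length_cm) * machine$speed_max
  cap_rate(rate, machine)
}

#' Apply the dynamic-range model to one energy layer
#'
#' Composes the four model steps: baseline dose rate, minimum-MU elevation,
#' machine-limit enforcement, and per-segment beam-on time
#' `BoT_i = adjusted_mu_i / doserate_DR`. The layer beam-on time is the sum
#' over segments. An unconstrained `dr` reproduces the baseline exactly
#' (MUs untouched, baseline dose rate).
#'
#' @inheritParams dr_dose_rate
#' @return Object of class `dr_adjusted_layer`: a list with `source`, `dr`,
#'   `dose_rate` (MU/s), `adjusted_mu`, `segment_bot` (s), `layer_bot` (s)
#'   and `n_elevated`.
#' @examples
#' lay <- energy_layer(189.6, c(0.0013, 0.0198, 0.0178, 0.0056, 0.0010), 0.6)
#' adjust_layer(lay, dr = 10, machine_spec())
#' @export
adjust_layer <- function(layer, dr, machine) {
  check_dr(dr)
  adj <- elevate_mu(layer, dr)
  rate <- dr_dose_rate(layer, dr, machine)
  bot <- as.numeric(adj) / rate
  structure(list(source = layer, dr = dr, dose_rate = rate,
                 adjusted_mu = as.numeric(adj), segment_bot = bot,
                 layer_bot = sum(bot),
                 n_elevated = attr(adj, "n_elevated")),
            class = "dr_adjusted_layer")
}

#' @export
print.dr_adjusted_layer <- function(x, ...) {
  cat(sprintf(
    "DR-adjusted layer (%.1f MeV): dr = %s, dose rate = %.4g MU/s\n",
    x$source$energy, if (is.infinite(x$dr)) "unconstrained" else format(x$dr),
    x$dose_rate))
  cat(sprintf("  %d/%d segments elevated; layer beam-on time = %.4g s\n",
              x$n_elevated, length(x$adjusted_mu), x$layer_bot))
  invisible(x)
}

#' Field beam-on time under a dynamic-range constraint
#'
#' @param field a [treatment_field()].
#' @inheritParams dr_dose_rate
#' @return List with `total` (s, the field T_BoT) and `per_layer`
#'   (numeric vector of layer beam-on times in delivery order).
#' @export
field_bot <- function(field, dr, machine) {
  stopifnot(inherits(field, "treatment_field"))
  per_layer <- vapply(field$layers,
                      function(l) adjust_layer(l, dr, machine)$layer_bot,
                      numeric(1))
  list(total = sum(per_layer), per_layer = per_layer)
}

#' Per-segment dynamic-range adjustment table for a plan
#'
#' Flat table used by reports and the command-line tool: one row per segment
#' with original MU, adjusted MU and beam-on time.
#'
#' @param plan a [treatment_plan()].
#' @inheritParams dr_dose_rate
#' @return Data frame with columns `field`, `layer`, `energy_mev`, `segment`,
#'   `mu`, `mu_adjusted`, `dose_rate_mu_s`, `bot_s`.
#' @export
adjust_plan_table <- function(plan, dr, machine) {
  validate_plan(plan)
  rows <- list()
  for (f in plan$fields)
    for (li in seq_along(f$layers)) {
      a <- adjust_layer(f$layers[[li]], dr, machine)
      rows[[length(rows) + 1L]] <- data.frame(
        field = f$name, layer = li, energy_mev = f$layers[[li]]$energy,
        segment = seq_along(a$adjusted_mu),
        mu = f$layers[[li]]$segments$mu, mu_adjusted = a$adjusted_mu,
        dose_rate_mu_s = a$dose_rate, bot_s = a$segment_bot)
    }
  do.call(rbind, rows)
}
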