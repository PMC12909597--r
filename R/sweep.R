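# Dynamic-range sweep and plateau detection.
#
# Sweeping the simulator across a grid of dynamic-range values traces total
# treatment time as a function of the constraint. Because gating quantizes
# delivery into respiratory windows, the curve plateaus: below a
# patient-specific threshold, every layer-plus-switch already fits the gate
# cadence and further beam-on-time reduction buys nothing while still
# costing intensity-modulation freedom. The sweep finds that threshold.

#' Default dynamic-range grid
#'
#' Unconstrained first, then 200 down to 10 in steps of 10.
#' @return Numeric vector (descending; `Inf` = unconstrained).
#' @export
default_dr_grid <- function() c(Inf, seq(200, 10, by = -10))

#' Sweep total treatment time over dynamic-range values
#'
#' Runs the dynamic-range model and the gated-delivery simulation once per
#' grid value and per field. Deterministic for fixed inputs.
#'
#' @param plan a [treatment_plan()].
#' @param dr_values dynamic-range grid (each >= 1, `Inf` = unconstrained);
#'   sorted descending internally.
#' @param resp a [respiratory_model()].
#' @param gate a [gate_config()].
#' @param machine a [machine_spec()].
#' @param config a [sim_config()].
#' @return Object of class `dr_sweep`: `table` (long data frame with columns
#'   `field`, `dr`, `t_total_s`, `t_bot_s`, `t_ls_s`, `t_dead_s`),
#'   `dr_values`, and `params` echoing the run conditions.
#' @examples
#' plan <- generate_plan(plan_gen_spec(n_fields = 1, n_layers = 5,
#'                                     segments_per_layer = c(20, 40),
#'                                     seed = 7))
#' sw <- sweep_dr(plan, dr_values = c(Inf, 100, 50, 10))
#' find_plateau(sw)
#' @export
sweep_dr <- function(plan, dr_values = default_dr_grid(),
                     resp = respiratory_model(), gate = gate_config(),
                     machine = machine_spec(), config = sim_config()) {
  validate_plan(plan)
  if (length(dr_values) < 1L) stop("dr_values must be non-empty")
  for (v in dr_values) check_dr(v)
  dr_values <- sort(unique(dr_values), decreasing = TRUE)
  sched <- gate_intervals(resp, gate, horizon = 10 * resp$period)
  rows <- list()
  for (f in plan$fields) {
    for (dr in dr_values) {
      bots <- field_bot(f, dr, machine)
      tl <- simulate_field(bots$per_layer, sched, machine, config)
      rows[[length(rows) + 1L]] <- data.frame(
        field = f$name, dr = dr, t_total_s = tl$t_total,
        t_bot_s = tl$t_bot, t_ls_s = tl$t_ls_total, t_dead_s = tl$t_dead)
    }
  }
  structure(list(
    table = do.call(rbind, rows),
    dr_values = dr_values,
    params = list(
      period_s = resp$period,
      t_ls_s = machine$t_ls,
      duty = if (!is.null(gate$duty)) gate$duty else NA_real_,
      threshold = if (!is.null(gate$threshold)) gate$threshold else NA_real_,
      start_phase_s = config$start_phase,
      speed_max_cm_s = machine$speed_max,
      plan_id = plan$plan_id,
      plan_fingerprint = plan_fingerprint(plan))),
    class = "dr_sweep")
}

# cheap content fingerprint so reports are self-describing
plan_fingerprint <- function(plan) {
  tab <- plan_as_table(plan)
  sprintf("f%d_l%d_s%d_mu%.6g", length(plan$fields), max(tab$layer_index),
          nrow(tab), sum(tab$mu))
}

#' Detect the treatment-time plateau of a sweep
#'
#' For each field, returns the largest dynamic-range value whose total
#' treatment time is within `epsilon` of the field's minimum over the grid
#' -- the threshold below which further dynamic-range reduction gains
#' nothing. If only the smallest grid value qualifies there is no plateau
#' (`NA`). The plan-level plateau is the largest (most conservative)
#' per-field plateau, so no field is over-constrained; it is `NA` if any
#' field lacks one.
#'
#' @param result a `dr_sweep`.
#' @param epsilon tolerance in s; default 1% of the field's minimum total.
#' @return List with `per_field` (named numeric, `NA` = none), `plan`, and
#'   `epsilon_s` (named vector of the tolerances used).
#' @export
find_plateau <- function(result, epsilon = NULL) {
  stopifnot(inherits(result, "dr_sweep"))
  if (!is.null(epsilon) && (!is.numeric(epsilon) || epsilon < 0))
    stop("epsilon must be >= 0")
  fields <- unique(result$table$field)
  per_field <- eps_used <- stats::setNames(numeric(length(fields)), fields)
  for (fn in fields) {
    sub <- result$table[result$table$field == fn, ]
    sub <- sub[order(sub$dr, decreasing = TRUE), ]
    if (!isTRUE(all.equal(sub$dr, result$dr_values)))
      stop("sweep table misaligned with dr_values grid")
    if (nrow(sub) < 2L) stop("plateau detection needs >= 2 dr values")
    eps <- if (is.null(epsilon)) 0.01 * min(sub$t_total_s) else epsilon
    eps_used[fn] <- eps
    qual <- which(sub$t_total_s - min(sub$t_total_s) <= eps)
    per_field[fn] <- if (length(qual) == 1L && qual == nrow(sub))
      NA_real_ else sub$dr[min(qual)]
  }
  plan_level <- if (anyNA(per_field)) NA_real_ else max(per_field)
  list(per_field = per_field, plan = plan_level, epsilon_s = eps_used)
}

#' Write a sweep report
#'
#' Writes the sweep table (CSV, or JSON including the run parameters when
#' `out` ends in `.json`) and optionally a plot. Interpolation in the plot
#' is presentation-only and never used for plateau detection. As a sanity
#' gate, beam-on time must be non-increasing as dynamic range decreases.
#'
#' @param result a `dr_sweep`.
#' @param out output path (`.csv` or `.json`).
#' @param plot optional PNG path for the sweep figure.
#' @param epsilon passed to [find_plateau()] for the plot annotation.
#' @return `out`, invisibly.
#' @export
render_report <- function(result, out, plot = NULL, epsilon = NULL) {
  stopifnot(inherits(result, "dr_sweep"))
  for (fn in unique(result$table$field)) {
    sub <- result$table[result$table$field == fn, ]
    sub <- sub[order(sub$dr, decreasing = TRUE), ]
    if (any(diff(sub$t_bot_s) > 1e-9))
      stop("sanity gate failed: t_bot increases as dr decreases")
  }
  if (grepl("\\.json$", out, ignore.case = TRUE)) {
    jsonlite::write_json(list(params = result$params,
                              dr_values = result$dr_values,
                              sweep = result$table),
                         out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(result$table, out, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(plot)) {
    grDevices::png(plot, width = 800, height = 500)
    on.exit(grDevices::dev.off())
    plot(result, epsilon = epsilon)
  }
  invisible(out)
}

#' @export
print.dr_sweep <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Dynamic-range sweep of plan '%s': %d dr values x %d field(s)\n",
    p$plan_id, length(x$dr_values), length(unique(x$table$field))))
  cat(sprintf("  T_R = %g s, t_ls = %g s, duty = %s, phase = %g s\n",
              p$period_s, p$t_ls_s,
              if (is.na(p$duty)) sprintf("(threshold %g)", p$threshold)
              else format(p$duty), p$start_phase_s))
  pl <- find_plateau(x)
  for (fn in names(pl$per_field)) {
    sub <- x$table[x$table$field == fn, ]
    cat(sprintf("  %s: t_total %.2f-%.2f s, plateau dr = %s\n", fn,
                min(sub$t_total_s), max(sub$t_total_s),
                if (is.na(pl$per_field[fn])) "none"
                else format(pl$per_field[fn])))
  }
  invisible(x)
}

#' @export
summary.dr_sweep <- function(object, epsilon = NULL, ...) {
  pl <- find_plateau(object, epsilon)
  structure(list(params = object$params, table = object$table,
                 plateau = pl), class = "summary.dr_sweep")
}

#' @export
print.summary.dr_sweep <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("plan-level plateau dr: %s\n",
              if (is.na(x$plateau$plan)) "none" else format(x$plateau$plan)))
  invisible(x)
}

#' Plot a dynamic-range sweep
#'
#' Computed points as markers with piecewise-linear interpolation between
#' them (presentation only); the unconstrained point is drawn at the right
#' edge, and detected plateaus are marked with vertical dashed lines.
#'
#' @param x a `dr_sweep`.
#' @param epsilon plateau tolerance passed to [find_plateau()].
#' @param ... further graphical arguments.
#' @return `x`, invisibly.
#' @export
plot.dr_sweep <- function(x, epsilon = NULL, ...) {
  tab <- x$table
  finite_max <- max(tab$dr[is.finite(tab$dr)], 10)
  xpos <- ifelse(is.finite(tab$dr), tab$dr, finite_max * 1.25)
  fields <- unique(tab$field)
  cols <- grDevices::hcl.colors(max(3L, length(fields)), "Dark 3")
  graphics::plot(NA, xlim = range(xpos), ylim = range(tab$t_total_s),
                 xlab = "dynamic range", ylab = "total treatment time (s)",
                 main = "Treatment time vs dynamic range", ...)
  pl <- find_plateau(x, epsilon)
  for (i in seq_along(fields)) {
    sub <- tab[tab$field == fields[i], ]
    o <- order(ifelse(is.finite(sub$dr), sub$dr, finite_max * 1.25))
    xs <- ifelse(is.finite(sub$dr), sub$dr, finite_max * 1.25)[o]
    graphics::lines(xs, sub$t_total_s[o], col = cols[i])
    graphics::points(xs, sub$t_total_s[o], col = cols[i], pch = 19)
    if (!is.na(pl$per_field[fields[i]]))
      graphics::abline(v = pl$per_field[fields[i]], col = cols[i], lty = 2)
  }
  graphics::legend("topleft", legend = fields, col = cols[seq_along(fields)],
                   lty = 1, pch = 19, bty = "n")
  invisible(x)
}
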