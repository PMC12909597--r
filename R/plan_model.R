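#' Construct an energy layer
#'
#' An energy layer is the set of line segments delivered at one proton energy
#' (one depth). Each segment carries a monitor-unit (MU) weight and a path
#' length in cm; the minimum MU within the layer constrains the dose rate of
#' the whole layer, which is why the dynamic-range constraint acts per layer.
#'
#' @param energy beam energy in MeV. Values outside the 70--230 MeV clinical
#'   range of a cyclotron line-scanning system trigger a warning, not an error.
#' @param mu numeric vector of segment MU weights (dimensionless, all > 0).
#' @param length_cm segment path lengths in cm (recycled to `length(mu)`).
#' @return An object of class `energy_layer`: a list with elements `energy`
#'   (MeV) and `segments` (a data frame with columns `mu`, `length_cm`, in
#'   delivery order). Segment order is preserved but does not affect beam-on
#'   time in this model.
#' @examples
#' lay <- energy_layer(189.6, mu = c(0.0013, 0.0198, 0.0178, 0.0056, 0.0010),
#'                     length_cm = 0.6)
#' layer_extrema(lay)
#' @export
energy_layer <- function(energy, mu, length_cm = 0.6) {
  stopifnot(is.numeric(energy), length(energy) == 1L, is.finite(energy))
  if (length(mu) < 1L) stop("energy layer must contain at least one segment")
  length_cm <- rep_len(length_cm, length(mu))
  layer <- structure(
    list(energy = as.numeric(energy),
         segments = data.frame(mu = as.numeric(mu),
                               length_cm = as.numeric(length_cm))),
    class = "energy_layer")
  validate_layer(layer)
  layer
}

validate_layer <- function(layer, where = "") {
  seg <- layer$segments
  bad <- which(!is.finite(seg$mu) | seg$mu <= 0)
  if (length(bad))
    stop(sprintf("segment mu must be finite and > 0%s (segment %d, mu = %g)",
                 where, bad[1L], seg$mu[bad[1L]]))
  bad <- which(!is.finite(seg$length_cm) | seg$length_cm <= 0)
  if (length(bad))
    stop(sprintf("segment length_cm must be finite and > 0%s (segment %d)",
                 where, bad[1L]))
  if (layer$energy < 70 || layer$energy > 230)
    warning(sprintf("energy %.1f MeV outside the usual 70-230 MeV range%s",
                    layer$energy, where))
  invisible(layer)
}

#' Minimum and maximum MU of a layer
#'
#' @param layer an [energy_layer()].
#' @return Named numeric vector `c(mu_min, mu_max)`, the exact extrema of the
#'   segment MU weights.
#' @export
layer_extrema <- function(layer) {
  stopifnot(inherits(layer, "energy_layer"))
  c(mu_min = min(layer$segments$mu), mu_max = max(layer$segments$mu))
}

#' Construct a treatment field
#'
#' A field (port) is an ordered stack of energy layers; the order is the
#' delivery order, and each change of energy costs one layer-switching time.
#'
#' @param name field label.
#' @param layers list of [energy_layer()] objects, in delivery order.
#' @return Object of class `treatment_field`.
#' @export
treatment_field <- function(name, layers) {
  if (length(layers) < 1L) stop("field must contain at least one layer")
  ok <- vapply(layers, inherits, logical(1), "energy_layer")
  if (!all(ok)) stop("all elements of `layers` must be energy_layer objects")
  structure(list(name = as.character(name), layers = layers),
            class = "treatment_field")
}

#' Construct a treatment plan
#'
#' @param plan_id plan label.
#' @param fields list of [treatment_field()] objects. Fields are delivered and
#'   simulated independently (per-port reporting).
#' @param metadata free-form named list carried through save/load.
#' @return Object of class `treatment_plan`.
#' @export
treatment_plan <- function(plan_id, fields, metadata = list()) {
  if (length(fields) < 1L) stop("plan must contain at least one field")
  ok <- vapply(fields, inherits, logical(1), "treatment_field")
  if (!all(ok)) stop("all elements of `fields` must be treatment_field objects")
  structure(list(plan_id = as.character(plan_id), fields = fields,
                 metadata = metadata),
            class = "treatment_plan")
}

#' Machine delivery parameters
#'
#' @param speed_max maximum scanning speed in cm/s (default 2000, a cyclotron
#'   line-scanning system).
#' @param t_ls energy-layer switching time in s (default 2).
#' @param max_dose_rate optional machine dose-rate cap in MU/s; `NULL` (the
#'   default) means unbounded, in which case `speed_max` alone produces the
#'   low-dynamic-range plateau.
#' @return Object of class `machine_spec`.
#' @export
machine_spec <- function(speed_max = 2000, t_ls = 2, max_dose_rate = NULL) {
  stopifnot(is.numeric(speed_max), speed_max > 0, is.numeric(t_ls), t_ls >= 0)
  if (!is.null(max_dose_rate))
    stopifnot(is.numeric(max_dose_rate), max_dose_rate > 0)
  structure(list(speed_max = as.numeric(speed_max), t_ls = as.numeric(t_ls),
                 max_dose_rate = if (is.null(max_dose_rate)) NULL
                                 else as.numeric(max_dose_rate)),
            class = "machine_spec")
}

validate_plan <- function(plan) {
  stopifnot(inherits(plan, "treatment_plan"))
  if (length(plan$fields) < 1L) stop("plan must contain at least one field")
  for (fi in seq_along(plan$fields)) {
    fld <- plan$fields[[fi]]
    if (length(fld$layers) < 1L)
      stop(sprintf("field %d ('%s') has no layers", fi, fld$name))
    for (li in seq_along(fld$layers))
      validate_layer(fld$layers[[li]],
                     where = sprintf(" (field %d, layer %d)", fi, li))
  }
  invisible(plan)
}

plan_schema_version <- 1L

#' Read a treatment plan from disk
#'
#' The canonical interchange format is a versioned JSON document:
#' \preformatted{
#' {"schema_version": 1, "plan_id": "...",
#'  "fields": [{"name": "...",
#'              "layers": [{"energy_mev": 189.6,
#'                          "segments": [{"mu": 0.0013, "length_cm": 0.6},
#'                                       ...]}]}]}
#' }
#' The CSV dialect is a flat table with columns `field_name, layer_index,
#' energy_mev, segment_index, mu, length_cm`, one row per segment. DICOM RT
#' Ion Plan import is deliberately not implemented (vendor spot-map
#' conventions vary); convert to this schema upstream.
#'
#' @param path file to read.
#' @param format `"json"` or `"csv"`; default inferred from the extension.
#' @return A validated [treatment_plan()]. Schema violations name the
#'   offending key; invariant violations name the field/layer/segment index.
#' @export
load_plan <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (!file.exists(path)) stop("plan file not found: ", path)
  plan <- if (format == "json") plan_from_json(path) else plan_from_csv(path)
  validate_plan(plan)
}

plan_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("schema_version", "plan_id", "fields"))
    if (is.null(doc[[key]])) stop("plan schema error: missing key '", key, "'")
  if (doc$schema_version != plan_schema_version)
    stop("unsupported plan schema_version: ", doc$schema_version)
  fields <- lapply(doc$fields, function(f) {
    if (is.null(f$name)) stop("plan schema error: field missing key 'name'")
    if (is.null(f$layers)) stop("plan schema error: field missing key 'layers'")
    layers <- lapply(f$layers, function(l) {
      if (is.null(l$energy_mev))
        stop("plan schema error: layer missing key 'energy_mev'")
      if (is.null(l$segments))
        stop("plan schema error: layer missing key 'segments'")
      mu <- vapply(l$segments, function(s) {
        if (is.null(s$mu)) stop("plan schema error: segment missing key 'mu'")
        as.numeric(s$mu)
      }, numeric(1))
      len <- vapply(l$segments, function(s) {
        if (is.null(s$length_cm))
          stop("plan schema error: segment missing key 'length_cm'")
        as.numeric(s$length_cm)
      }, numeric(1))
      energy_layer(l$energy_mev, mu = mu, length_cm = len)
    })
    treatment_field(f$name, layers)
  })
  meta <- if (is.null(doc$metadata)) list() else doc$metadata
  treatment_plan(doc$plan_id, fields, metadata = meta)
}

plan_from_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("field_name", "layer_index", "energy_mev", "segment_index",
            "mu", "length_cm")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("plan schema error: missing column '", missing[1L], "'")
  fields <- lapply(split(tab, factor(tab$field_name,
                                     levels = unique(tab$field_name))),
                   function(ft) {
    layers <- lapply(split(ft, ft$layer_index), function(lt) {
      lt <- lt[order(lt$segment_index), ]
      energy_layer(lt$energy_mev[1L], mu = lt$mu, length_cm = lt$length_cm)
    })
    treatment_field(ft$field_name[1L],
                    unname(layers[order(as.integer(names(layers)))]))
  })
  plan_id <- sub("\\.csv$", "", basename(path), ignore.case = TRUE)
  treatment_plan(plan_id, fields[unique(tab$field_name)])
}

#' Write a treatment plan to disk
#'
#' Numeric values are serialized with full double precision so that
#' `load_plan(save_plan(plan))` round-trips exactly; canonical key ordering
#' makes repeated saves byte-identical.
#'
#' @param plan a valid [treatment_plan()].
#' @inheritParams load_plan
#' @return `path`, invisibly.
#' @export
save_plan <- function(plan, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  validate_plan(plan)
  if (format == "json") {
    doc <- list(
      schema_version = plan_schema_version,
      plan_id = plan$plan_id,
      fields = lapply(plan$fields, function(f) list(
        name = f$name,
        layers = lapply(f$layers, function(l) list(
          energy_mev = l$energy,
          segments = lapply(seq_len(nrow(l$segments)), function(i)
            list(mu = l$segments$mu[i], length_cm = l$segments$length_cm[i]))
        ))
      ))
    )
    if (length(plan$metadata)) doc$metadata <- plan$metadata
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    utils::write.csv(plan_as_table(plan), path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

plan_as_table <- function(plan) {
  rows <- list()
  for (f in plan$fields)
    for (li in seq_along(f$layers)) {
      l <- f$layers[[li]]
      rows[[length(rows) + 1L]] <- data.frame(
        field_name = f$name, layer_index = li, energy_mev = l$energy,
        segment_index = seq_len(nrow(l$segments)),
        mu = l$segments$mu, length_cm = l$segments$length_cm)
    }
  do.call(rbind, rows)
}

#' Read machine parameters from a JSON config
#'
#' Expected keys: `speed_max_cm_s`, `t_ls_s`, `max_dose_rate_mu_s`
#' (`null` for unbounded).
#'
#' @param path JSON file.
#' @return A [machine_spec()].
#' @export
load_machine <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  machine_spec(
    speed_max = if (is.null(doc$speed_max_cm_s)) 2000 else doc$speed_max_cm_s,
    t_ls = if (is.null(doc$t_ls_s)) 2 else doc$t_ls_s,
    max_dose_rate = doc$max_dose_rate_mu_s)
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat(sprintf("Treatment plan '%s': %d field(s)\n", x$plan_id,
              length(x$fields)))
  for (f in x$fields) {
    nseg <- sum(vapply(f$layers, function(l) nrow(l$segments), integer(1)))
    en <- range(vapply(f$layers, function(l) l$energy, numeric(1)))
    cat(sprintf("  field '%s': %d layers (%.1f-%.1f MeV), %d segments\n",
                f$name, length(f$layers), en[1L], en[2L], nseg))
  }
  invisible(x)
}

#' @export
print.machine_spec <- function(x, ...) {
  cat(sprintf("Machine: speed_max = %g cm/s, t_ls = %g s, max dose rate = %s\n",
              x$speed_max, x$t_ls,
              if (is.null(x$max_dose_rate)) "unbounded"
              else sprintf("%g MU/s", x$max_dose_rate)))
  invisible(x)
}
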