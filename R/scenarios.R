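# Scenario synthesis: the packaged reference exposure conditions and a
# seeded generator of physically plausible random parameter records for
# property-based testing and sweeps.
#
# Every sampled parameter spans orders of magnitude, so sampling is
# log-uniform per parameter; the tau_p < tau_rep constraint is enforced by
# rejection so the marginal distributions stay simple.  The seed is a
# mandatory argument: no hidden global RNG state.

#' Reference single-cell exposure conditions
#'
#' The baseline condition this package models: a 1550 nm, 100 fs, 50 MHz
#' (20 ns spacing) fibre laser focused to a 1.5 um spot on a ~10 um cell in
#' aqueous medium, at average powers of 15 and 24 mW (the bracket within
#' which selective propidium-iodide delivery into CHO cells is observed),
#' 40 s exposure.
#'
#' @return list with `exposure_low` (15 mW), `exposure_high` (24 mW)
#'   [laser_exposure()] records, a water [medium_thermal()] and the default
#'   [membrane_model()].
#' @examples
#' sc <- reference_scenario()
#' sc$exposure_high$pulse_spacing  # 2e-8 s
#' @export
reference_scenario <- function() {
  mk <- function(power) {
    laser_exposure(wavelength = "1550 nm", pulse_duration = "100 fs",
                   pulse_spacing = "20 ns", average_power = power,
                   spot_diameter = "1.5 um", exposure_time = "40 s")
  }
  list(
    exposure_low = mk("15 mW"),
    exposure_high = mk("24 mW"),
    medium = medium_thermal(density = 1000, specific_heat = 4200,
                            thermal_conductivity = 0.6,
                            absorption_coefficient = "10 cm-1"),
    membrane = membrane_model()
  )
}

#' Wide-field reference exposure
#'
#' The prior-generation wide-field condition used as the comparison point
#' for dose concentration: the same pulse train delivered at 120 mW over a
#' 50 um spot.
#'
#' @return a [laser_exposure()].
#' @export
reference_wide_field <- function() {
  laser_exposure(wavelength = "1550 nm", pulse_duration = "100 fs",
                 pulse_spacing = "20 ns", average_power = "120 mW",
                 spot_diameter = "50 um", exposure_time = "40 s")
}

#' Sampling specification for synthetic scenarios
#'
#' Per-parameter log-uniform sampling ranges (SI), a sample count and a
#' mandatory seed.  Defaults span the plausible space for pulsed-laser
#' single-cell exposure: pulse durations 1 fs - 100 ps, spacings 1 ns -
#' 10 us, powers 1-200 mW, spots 0.5-50 um, cells 2-20 um, water-like media
#' and membrane parameters around the conventional electropermeabilization
#' range.
#'
#' @param n number of records to draw.
#' @param seed integer RNG seed (mandatory).
#' @param ranges named list of `c(low, high)` SI ranges overriding the
#'   defaults; names among `pulse_duration`, `pulse_spacing`,
#'   `average_power`, `spot_diameter`, `cell_radius`, `density`,
#'   `specific_heat`, `thermal_conductivity`, `absorption_coefficient`,
#'   `vm_threshold`, `thermo_factor`, `membrane_thickness`.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(n, seed, ranges = list()) {
  defaults <- list(
    pulse_duration         = c(1e-15, 1e-10),
    pulse_spacing          = c(1e-9, 1e-5),
    average_power          = c(1e-3, 0.2),
    spot_diameter          = c(0.5e-6, 50e-6),
    cell_radius            = c(2e-6, 20e-6),
    density                = c(900, 1100),
    specific_heat          = c(3500, 4500),
    thermal_conductivity   = c(0.4, 0.7),
    absorption_coefficient = c(1e2, 1e4),
    vm_threshold           = c(0.1, 1),
    thermo_factor          = c(50, 200),
    membrane_thickness     = c(4e-9, 1e-8)
  )
  unknown <- setdiff(names(ranges), names(defaults))
  if (length(unknown)) {
    stop("unknown range name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(ranges)) defaults[[nm]] <- as.numeric(ranges[[nm]])
  for (nm in names(defaults)) {
    r <- defaults[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || any(r <= 0) || r[1] >= r[2]) {
      stop(sprintf("range '%s' must be positive with low < high", nm),
           call. = FALSE)
    }
  }
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n)) {
    stop("'n' must be a non-negative integer", call. = FALSE)
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("'seed' is mandatory and must be a single integer", call. = FALSE)
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 ranges = defaults),
            class = "scenario_spec")
}

#' Draw synthetic scenario records
#'
#' Samples `spec$n` parameter records log-uniformly within the spec's
#' ranges, rejecting draws violating `pulse_duration < pulse_spacing` until
#' all records are valid.  Identical specs (including seed) give identical
#' records across runs; the caller's RNG state is left untouched.
#'
#' @param spec a [scenario_spec()].
#' @return list of records, each a list with components `exposure`
#'   ([laser_exposure()]), `medium` ([medium_thermal()]) and `membrane`
#'   ([membrane_model()] with the gradient threshold derived from the
#'   sampled Vm, S and thickness).
#' @export
sample_scenarios <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$n == 0L) return(list())
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  rlog <- function(nm, k) {
    r <- spec$ranges[[nm]]
    exp(stats::runif(k, log(r[1]), log(r[2])))
  }
  draw <- function(k) {
    list(
      pulse_duration = rlog("pulse_duration", k),
      pulse_spacing = rlog("pulse_spacing", k),
      average_power = rlog("average_power", k),
      spot_diameter = rlog("spot_diameter", k),
      cell_radius = rlog("cell_radius", k),
      density = rlog("density", k),
      specific_heat = rlog("specific_heat", k),
      thermal_conductivity = rlog("thermal_conductivity", k),
      absorption_coefficient = rlog("absorption_coefficient", k),
      vm_threshold = rlog("vm_threshold", k),
      thermo_factor = rlog("thermo_factor", k),
      membrane_thickness = rlog("membrane_thickness", k)
    )
  }
  cols <- draw(spec$n)
  # rejection: redraw rows violating tau_p < tau_rep until none remain
  bad <- which(cols$pulse_duration >= cols$pulse_spacing)
  while (length(bad)) {
    redraw <- draw(length(bad))
    for (nm in names(cols)) cols[[nm]][bad] <- redraw[[nm]]
    bad <- which(cols$pulse_duration >= cols$pulse_spacing)
  }
  lapply(seq_len(spec$n), function(i) {
    list(
      exposure = laser_exposure(
        wavelength = 1550e-9,
        pulse_duration = cols$pulse_duration[i],
        pulse_spacing = cols$pulse_spacing[i],
        average_power = cols$average_power[i],
        spot_diameter = cols$spot_diameter[i]),
      medium = medium_thermal(
        density = cols$density[i],
        specific_heat = cols$specific_heat[i],
        thermal_conductivity = cols$thermal_conductivity[i],
        absorption_coefficient = cols$absorption_coefficient[i]),
      membrane = membrane_model(
        cell_radius = cols$cell_radius[i],
        membrane_thickness = cols$membrane_thickness[i],
        vm_threshold = cols$vm_threshold[i],
        thermo_factor = cols$thermo_factor[i],
        grad_threshold = NULL)
    )
  })
}

#' Sweep one parameter over a set of values
#'
#' Returns records identical to `base` except for the swept field, in the
#' order of `values`.
#'
#' @param parameter one of the exposure fields (`wavelength`,
#'   `pulse_duration`, `pulse_spacing`, `average_power`, `spot_diameter`,
#'   `exposure_time`), medium fields (`density`, `specific_heat`,
#'   `thermal_conductivity`, `absorption_coefficient`) or membrane fields
#'   (`cell_radius`, `membrane_thickness`, `vm_threshold`, `thermo_factor`,
#'   `grad_threshold`).
#' @param values positive values for the swept parameter; SI numerics or
#'   `"value unit"` strings.
#' @param base a record list with `exposure`, `medium`, `membrane`
#'   components (e.g. one element of [sample_scenarios()], or assembled from
#'   [reference_scenario()]).
#' @return list of records (same shape as `base`), one per value.
#' @examples
#' sc <- reference_scenario()
#' base <- list(exposure = sc$exposure_high, medium = sc$medium,
#'              membrane = sc$membrane)
#' pts <- sweep_grid("average_power", c("15 mW", "24 mW"), base)
#' @export
sweep_grid <- function(parameter, values, base) {
  stopifnot(is.list(base), inherits(base$exposure, "laser_exposure"),
            inherits(base$medium, "medium_thermal"),
            inherits(base$membrane, "membrane_model"))
  field_map <- list(
    exposure = c("wavelength", "pulse_duration", "pulse_spacing",
                 "average_power", "spot_diameter", "exposure_time"),
    medium = c("density", "specific_heat", "thermal_conductivity",
               "absorption_coefficient"),
    membrane = c("cell_radius", "membrane_thickness", "vm_threshold",
                 "thermo_factor", "grad_threshold")
  )
  comp <- NULL
  for (cn in names(field_map)) {
    if (parameter %in% field_map[[cn]]) comp <- cn
  }
  if (is.null(comp)) {
    stop(sprintf("unknown parameter '%s'", parameter), call. = FALSE)
  }
  if (length(values) == 0L) return(list())
  lapply(values, function(v) {
    rec <- base
    args <- unclass(rec[[comp]])
    if (comp == "membrane") {
      args <- args[setdiff(names(args), c("grad_threshold", "grad_source"))]
      # keep a supplied gradient threshold unless it is itself being swept
      if (parameter != "grad_threshold" &&
          base$membrane$grad_source == "supplied") {
        args$grad_threshold <- base$membrane$grad_threshold
      } else if (parameter != "grad_threshold") {
        args$grad_threshold <- NULL
      }
    }
    args[[parameter]] <- as_si(v)
    ctor <- switch(comp, exposure = laser_exposure, medium = medium_thermal,
                   membrane = membrane_model)
    rec[[comp]] <- do.call(ctor, args)
    rec
  })
}

#' Serialize scenario records as JSON lines
#'
#' One record per line, SI values, stable field order: byte-identical output
#' for identical inputs, suitable for diff-based testing.
#'
#' @param records list of records from [sample_scenarios()].
#' @param path output file; when NULL the lines are returned invisibly
#'   instead of written.
#' @return invisibly, the character vector of JSON lines.
#' @export
write_scenarios_jsonl <- function(records, path = NULL) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(list(
      exposure = unclass(r$exposure),
      medium = unclass(r$medium),
      membrane = unclass(r$membrane)
    ), auto_unbox = TRUE, digits = NA)
  }, character(1))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
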