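# Regime diagrams: families of critical pulse-spacing curves versus pulse
# duration, at fixed per-pulse energy density or fixed average power density,
# with operating-point placement.
#
# For fixed Ep the satisfied region lies BELOW a curve (spacing short enough
# for heat to accumulate); for fixed <w> it lies ABOVE (spacing long enough
# that each pulse carries sufficient energy).  Curves are tabulated, not
# rendered; plotting is a thin layer over the table.

#' Build a critical-spacing curve
#'
#' Tabulates the critical pulse spacing as a function of pulse duration at a
#' fixed dose level, by calling [critical_tau_rep_fixed_Ep()] or
#' [critical_tau_rep_fixed_w()] at every grid point (no separate
#' re-derivation).
#'
#' @param mode `"fixed_Ep"` or `"fixed_w"`.
#' @param level the dose level: energy density (J/m^3, e.g. `"0.22 J/cm^3"`)
#'   for `"fixed_Ep"`, power density (W/m^3, e.g. `"1.1e7 W/cm^3"`) for
#'   `"fixed_w"`.
#' @param tau_p_grid strictly increasing pulse-duration grid (s); default
#'   200 log-spaced points over 1e-15..1e-9 s.
#' @param medium a [medium_thermal()].
#' @param membrane a [membrane_model()].
#' @return object of class `regime_curve`: a data.frame with columns
#'   `tau_p_s`, `tau_rep_crit_s` and `flag`, plus attributes `mode`, `level`
#'   (SI) and `satisfied_side` (`"below"` or `"above"`).
#' @examples
#' crv <- build_curve("fixed_Ep", "0.22 J/cm^3")
#' @export
build_curve <- function(mode = c("fixed_Ep", "fixed_w"), level,
                        tau_p_grid = NULL,
                        medium = medium_thermal(),
                        membrane = membrane_model()) {
  mode <- match.arg(mode)
  if (is.null(tau_p_grid)) {
    tau_p_grid <- 10^seq(log10(1e-15), log10(1e-9), length.out = 200L)
  }
  tau_p_grid <- as_si(tau_p_grid)
  if (any(tau_p_grid <= 0) || is.unsorted(tau_p_grid, strictly = TRUE)) {
    stop("'tau_p_grid' must be positive and strictly increasing", call. = FALSE)
  }
  lv <- as_si(level)
  .check_positive(level = lv)
  fn <- if (mode == "fixed_Ep") critical_tau_rep_fixed_Ep else
    critical_tau_rep_fixed_w
  crit <- lapply(tau_p_grid, function(tp) fn(lv, tp, medium, membrane))
  out <- data.frame(
    tau_p_s = tau_p_grid,
    tau_rep_crit_s = vapply(crit, as.numeric, numeric(1)),
    flag = vapply(crit, critical_flag, character(1)),
    stringsAsFactors = FALSE
  )
  structure(out,
            mode = mode, level = lv,
            satisfied_side = if (mode == "fixed_Ep") "below" else "above",
            class = c("regime_curve", "data.frame"))
}

#' Default curve families for the two diagram modes
#'
#' The levels bracketing a 15-24 mW, 1.5 um-spot exposure: per-pulse energy
#' densities 0.13, 0.22 and 0.32 J/cm^3, and average power densities 6.6e6,
#' 1.1e7, 1.6e7 and 3e7 W/cm^3.
#'
#' @param mode `"fixed_Ep"` or `"fixed_w"`.
#' @return numeric vector of SI levels (J/m^3 or W/m^3).
#' @export
default_curve_levels <- function(mode = c("fixed_Ep", "fixed_w")) {
  mode <- match.arg(mode)
  if (mode == "fixed_Ep") c(0.13, 0.22, 0.32) * 1e6
  else c(6.6e6, 1.1e7, 1.6e7, 3e7) * 1e6
}

#' Place an operating point relative to a regime curve
#'
#' Interpolates the curve (log-log between grid nodes; exact closed form is
#' already stored at the nodes) at the operating point's pulse duration and
#' reports which side of the curve the point falls on and the distance
#' factor `tau_rep / critical tau_rep`.  A point exactly on the curve counts
#' as satisfied.
#'
#' @param curve a [build_curve()] result.
#' @param pulse_spacing operating \eqn{\tau_{rep}} (s).
#' @param pulse_duration operating \eqn{\tau_p} (s); must lie within the
#'   curve's grid span.
#' @return list with `side` (`"satisfied"` or `"unsatisfied"`),
#'   `distance_factor`, `tau_rep_crit` (interpolated, s) and `flag`.
#' @export
place_point <- function(curve, pulse_spacing, pulse_duration) {
  stopifnot(inherits(curve, "regime_curve"))
  tr <- as_si(pulse_spacing)
  tp <- as_si(pulse_duration)
  .check_positive(pulse_spacing = tr, pulse_duration = tp)
  grid <- curve$tau_p_s
  if (tp < min(grid) || tp > max(grid)) {
    stop("pulse_duration outside the curve's grid span", call. = FALSE)
  }
  mode <- attr(curve, "mode")
  i <- findInterval(tp, grid)
  if (grid[i] == tp) {
    crit <- curve$tau_rep_crit_s[i]
    flag <- curve$flag[i]
  } else {
    lo <- i; hi <- i + 1L
    f_lo <- curve$flag[lo]; f_hi <- curve$flag[hi]
    if (f_lo != "ok" || f_hi != "ok") {
      # degenerate bracket: both nodes share the verdict for these flags
      crit <- curve$tau_rep_crit_s[lo]
      flag <- if (f_lo != "ok") f_lo else f_hi
    } else {
      t <- (log(tp) - log(grid[lo])) / (log(grid[hi]) - log(grid[lo]))
      crit <- exp((1 - t) * log(curve$tau_rep_crit_s[lo]) +
                    t * log(curve$tau_rep_crit_s[hi]))
      flag <- "ok"
    }
  }
  satisfied <- if (flag == "always_satisfied") {
    TRUE
  } else if (flag == "unreachable") {
    FALSE
  } else if (mode == "fixed_Ep") {
    tr <= crit
  } else {
    tr >= crit
  }
  list(
    side = if (satisfied) "satisfied" else "unsatisfied",
    distance_factor = tr / crit,
    tau_rep_crit = crit,
    flag = flag
  )
}

#' Write a family of regime curves as plot-ready CSV
#'
#' One file per level, columns `tau_p_s`, `tau_rep_crit_s`, `flag`.
#'
#' @param mode `"fixed_Ep"` or `"fixed_w"`.
#' @param levels SI levels; defaults to [default_curve_levels()].
#' @param dir output directory (created if missing).
#' @param tau_p_grid optional grid passed to [build_curve()].
#' @param medium,membrane model records.
#' @return invisibly, a character vector of the files written.
#' @export
write_curve_family <- function(mode = c("fixed_Ep", "fixed_w"), levels = NULL,
                               dir = ".", tau_p_grid = NULL,
                               medium = medium_thermal(),
                               membrane = membrane_model()) {
  mode <- match.arg(mode)
  if (is.null(levels)) levels <- default_curve_levels(mode)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  unit <- if (mode == "fixed_Ep") "J/cm^3" else "W/cm^3"
  paths <- vapply(levels, function(lv) {
    crv <- build_curve(mode, lv, tau_p_grid, medium, membrane)
    path <- file.path(dir, sprintf("curves_%s_%g.csv", mode,
                                   from_si(lv, unit)))
    utils::write.csv(as.data.frame(crv), path, row.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}

#' @export
plot.regime_curve <- function(x, ..., add = FALSE) {
  ok <- x$flag == "ok"
  unit <- if (attr(x, "mode") == "fixed_Ep") "J/cm^3" else "W/cm^3"
  if (!add) {
    plot(x$tau_p_s[ok], x$tau_rep_crit_s[ok], type = "l", log = "xy",
         xlab = "pulse duration tau_p (s)",
         ylab = "critical pulse spacing tau_rep (s)",
         main = sprintf("%s = %.3g %s (satisfied %s curve)",
                        attr(x, "mode"), from_si(attr(x, "level"), unit),
                        unit, attr(x, "satisfied_side")), ...)
  } else {
    graphics::lines(x$tau_p_s[ok], x$tau_rep_crit_s[ok], ...)
  }
  invisible(x)
}
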