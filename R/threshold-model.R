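# Thermoelectric temperature-gradient electropermeabilization threshold.
#
# A pulse train depositing energy density Ep per pulse (or average power
# density <w> = Ep/tau_rep) drives a plasma-membrane temperature gradient
# with two contributions: a per-pulse transient that scales as
# Ep*sqrt(tau_diff/tau_p) and a steady-state accumulation term that scales
# as Ep*tau_diff/tau_rep, both normalized by rho*cv*R.  Permeabilization by
# this mechanism requires the combined gradient to reach the membrane
# threshold grad_Tep, i.e.
#
#     Ep*sqrt(tau_diff/tau_p) + Ep*tau_diff/tau_rep >= rho*cv*R*grad_Tep
#
# with tau_diff = rho*cv*R^2/kappa the thermal diffusion time over a cell
# radius.  All critical values below are closed-form inversions of this
# single inequality for one variable at a time; the fixed-Ep and fixed-<w>
# forms are algebraically equivalent under Ep = tau_rep*<w>.
#
# Boundary convention: equality with a critical value counts as satisfied
# (margin = 1 is a pass).  Degenerate outcomes are returned as flagged
# values, never errors, so parameter sweeps do not abort:
#   "always_satisfied" - the threshold is met for every value of the
#                        inverted variable (value Inf or 0 as appropriate);
#   "unreachable"      - the critical pulse spacing is shorter than the
#                        pulse itself, so no physical pulse train satisfies
#                        the condition at this Ep and tau_p.

.critical <- function(value, flag = "ok") {
  structure(value, flag = flag, class = "critical_value")
}

#' Flag attached to a critical value
#'
#' @param x a value returned by one of the `critical_*` functions.
#' @return `"ok"`, `"always_satisfied"` or `"unreachable"`.
#' @export
critical_flag <- function(x) attr(x, "flag") %||% "ok"

#' @export
print.critical_value <- function(x, ...) {
  cat(format(as.numeric(x)), " [", critical_flag(x), "]\n", sep = "")
  invisible(x)
}

# rho*cv*R and rho*cv*R*gradTep, the two composites every formula uses
.rcr <- function(medium, membrane) {
  medium$density * medium$specific_heat * membrane$cell_radius
}

#' Thermal diffusion time across a cell radius
#'
#' \deqn{\tau_{diff} = \rho c_v R^2 / \kappa.}
#' The timescale over which heat diffuses a cell radius; pulse spacings
#' short compared to it accumulate heat between pulses.
#'
#' @param density mass density (kg/m^3).
#' @param specific_heat specific heat (J/(kg K)).
#' @param cell_radius cell radius (m).
#' @param thermal_conductivity (W/(m K)).
#' @return time (s).
#' @examples
#' thermal_diffusion_time(1000, 4200, "10 um", 0.6)  # 7e-4 s
#' @export
thermal_diffusion_time <- function(density, specific_heat, cell_radius,
                                   thermal_conductivity) {
  rho <- as_si(density); cv <- as_si(specific_heat)
  r <- as_si(cell_radius); k <- as_si(thermal_conductivity)
  .check_positive(density = rho, specific_heat = cv, cell_radius = r,
                  thermal_conductivity = k)
  rho * cv * r^2 / k
}

.tau_diff <- function(medium, membrane) {
  thermal_diffusion_time(medium$density, medium$specific_heat,
                         membrane$cell_radius, medium$thermal_conductivity)
}

#' Does an exposure satisfy the temperature-gradient threshold?
#'
#' Evaluates the threshold inequality for a pulse train, given either the
#' per-pulse peak energy density `energy_density` or the average power
#' density `power_density` (exactly one of the two; they are related by
#' `Ep = tau_rep * <w>`).  Equality counts as satisfied.
#'
#' @param pulse_spacing \eqn{\tau_{rep}} (s).
#' @param pulse_duration \eqn{\tau_p} (s).
#' @param energy_density \eqn{E_p} (J/m^3), or NULL.
#' @param power_density \eqn{\langle w\rangle} (W/m^3), or NULL.
#' @param medium a [medium_thermal()].
#' @param membrane a [membrane_model()].
#' @return logical.
#' @export
threshold_satisfied <- function(pulse_spacing, pulse_duration,
                                energy_density = NULL, power_density = NULL,
                                medium = medium_thermal(),
                                membrane = membrane_model()) {
  tr <- as_si(pulse_spacing); tp <- as_si(pulse_duration)
  .check_positive(pulse_spacing = tr, pulse_duration = tp)
  if (is.null(energy_density) == is.null(power_density)) {
    stop("supply exactly one of 'energy_density' or 'power_density'",
         call. = FALSE)
  }
  ep <- if (is.null(energy_density)) tr * as_si(power_density)
        else as_si(energy_density)
  .check_positive(energy_density = ep)
  td <- .tau_diff(medium, membrane)
  rcr <- .rcr(medium, membrane)
  # boundary convention: equality satisfies; the 1e-9 relative slack keeps
  # operating points computed *from* a critical value on the satisfied side
  # despite floating-point round-off
  ep * sqrt(td / tp) + ep * td / tr >=
    rcr * membrane$grad_threshold * (1 - 1e-9)
}

#' Critical pulse spacing at fixed per-pulse energy density
#'
#' Largest pulse spacing for which a train of pulses of energy density
#' \eqn{E_p} still reaches the membrane temperature-gradient threshold:
#' \deqn{\tau_{rep}^{crit} = \frac{E_p \tau_{diff}}
#'   {\rho c_v R \nabla T_{ep} - E_p \sqrt{\tau_{diff}/\tau_p}}.}
#' The condition is satisfied for pulse spacings at or below this value.
#' When the denominator is non-positive a single pulse's transient alone
#' reaches the threshold and the result is `Inf` with flag
#' `"always_satisfied"`; when the critical spacing falls below the pulse
#' duration itself no physical train satisfies the condition and the flag is
#' `"unreachable"`.
#'
#' @param energy_density \eqn{E_p} (J/m^3), e.g. `"0.22 J/cm^3"`.
#' @param pulse_duration \eqn{\tau_p} (s).
#' @param medium a [medium_thermal()].
#' @param membrane a [membrane_model()].
#' @return critical time (s) with a flag attribute (see [critical_flag()]).
#' @examples
#' critical_tau_rep_fixed_Ep("0.22 J/cm^3", "100 fs")   # ~6.53e-9 s
#' critical_tau_rep_fixed_Ep("0.132 J/cm^3", "100 fs")  # ~2.98e-9 s
#' @export
critical_tau_rep_fixed_Ep <- function(energy_density, pulse_duration,
                                      medium = medium_thermal(),
                                      membrane = membrane_model()) {
  ep <- as_si(energy_density); tp <- as_si(pulse_duration)
  .check_positive(energy_density = ep, pulse_duration = tp)
  td <- .tau_diff(medium, membrane)
  denom <- .rcr(medium, membrane) * membrane$grad_threshold - ep * sqrt(td / tp)
  if (denom <= 0) return(.critical(Inf, "always_satisfied"))
  v <- ep * td / denom
  .critical(v, if (v <= tp) "unreachable" else "ok")
}

#' Critical pulse spacing at fixed average power density
#'
#' Smallest pulse spacing for which a train at average power density
#' \eqn{\langle w\rangle} reaches the threshold:
#' \deqn{\tau_{rep}^{crit} = \frac{\rho c_v R \nabla T_{ep}
#'   - \tau_{diff}\langle w\rangle}{\langle w\rangle\sqrt{\tau_{diff}/\tau_p}}.}
#' At fixed \eqn{\langle w\rangle}, longer spacing means more energy per
#' pulse, so the condition is satisfied for spacings at or ABOVE this value.
#' When the numerator is non-positive the steady-state term alone suffices
#' and the result is 0 with flag `"always_satisfied"`.
#'
#' @param power_density \eqn{\langle w\rangle} (W/m^3), e.g. `"1.1e7 W/cm^3"`.
#' @inheritParams critical_tau_rep_fixed_Ep
#' @return critical time (s) with a flag attribute.
#' @examples
#' critical_tau_rep_fixed_w("1.1e7 W/cm^3", "100 fs")  # ~3.73e-8 s
#' critical_tau_rep_fixed_w("6.6e6 W/cm^3", "100 fs")  # ~6.77e-8 s
#' @export
critical_tau_rep_fixed_w <- function(power_density, pulse_duration,
                                     medium = medium_thermal(),
                                     membrane = membrane_model()) {
  w <- as_si(power_density); tp <- as_si(pulse_duration)
  .check_positive(power_density = w, pulse_duration = tp)
  td <- .tau_diff(medium, membrane)
  num <- .rcr(medium, membrane) * membrane$grad_threshold - td * w
  if (num <= 0) return(.critical(0, "always_satisfied"))
  .critical(num / (w * sqrt(td / tp)), "ok")
}

#' Critical pulse duration
#'
#' Longest pulse duration for which the threshold is reached, at fixed pulse
#' spacing and either fixed energy density (default) or fixed average power
#' density (converted via \eqn{E_p = \tau_{rep}\langle w\rangle}):
#' \deqn{\tau_p^{crit} = \tau_{diff}\Big/
#'   \Big[\frac{\rho c_v R \nabla T_{ep} - E_p \tau_{diff}/\tau_{rep}}
#'   {E_p}\Big]^2.}
#' Shorter pulses concentrate the same energy into a steeper transient, so
#' the condition is satisfied at or below this duration.  When the
#' steady-state term alone already exceeds the threshold the result is `Inf`
#' with flag `"always_satisfied"`.
#'
#' @param pulse_spacing \eqn{\tau_{rep}} (s).
#' @param energy_density \eqn{E_p} (J/m^3), or NULL if `power_density` given.
#' @param power_density \eqn{\langle w\rangle} (W/m^3), or NULL.
#' @inheritParams critical_tau_rep_fixed_Ep
#' @return critical time (s) with a flag attribute.
#' @examples
#' critical_tau_p("20 ns", energy_density = "0.22 J/cm^3")   # ~2.88e-14 s
#' critical_tau_p("20 ns", energy_density = "0.132 J/cm^3")  # ~8.73e-15 s
#' @export
critical_tau_p <- function(pulse_spacing, energy_density = NULL,
                           power_density = NULL,
                           medium = medium_thermal(),
                           membrane = membrane_model()) {
  tr <- as_si(pulse_spacing)
  .check_positive(pulse_spacing = tr)
  if (is.null(energy_density) == is.null(power_density)) {
    stop("supply exactly one of 'energy_density' or 'power_density'",
         call. = FALSE)
  }
  ep <- if (is.null(energy_density)) tr * as_si(power_density)
        else as_si(energy_density)
  .check_positive(energy_density = ep)
  td <- .tau_diff(medium, membrane)
  q <- (.rcr(medium, membrane) * membrane$grad_threshold - ep * td / tr) / ep
  if (q <= 0) return(.critical(Inf, "always_satisfied"))
  .critical(td / q^2, "ok")
}

#' Critical per-pulse energy density
#'
#' Energy density at which a pulse train with the given timing exactly
#' reaches the threshold:
#' \deqn{E_p^{crit} = \frac{\rho c_v R \nabla T_{ep}}
#'   {\tau_{diff}/\tau_{rep} + \sqrt{\tau_{diff}/\tau_p}}.}
#'
#' @inheritParams critical_tau_rep_fixed_Ep
#' @param pulse_spacing \eqn{\tau_{rep}} (s).
#' @return energy density (J/m^3); divide by 1e6 for J/cm^3.
#' @examples
#' from_si(critical_Ep("20 ns", "100 fs"), "J/cm^3")  # ~0.354
#' @export
critical_Ep <- function(pulse_spacing, pulse_duration,
                        medium = medium_thermal(),
                        membrane = membrane_model()) {
  tr <- as_si(pulse_spacing); tp <- as_si(pulse_duration)
  .check_positive(pulse_spacing = tr, pulse_duration = tp)
  td <- .tau_diff(medium, membrane)
  .rcr(medium, membrane) * membrane$grad_threshold /
    (td / tr + sqrt(td / tp))
}

#' Critical average power density
#'
#' Average power density at which a train with the given timing exactly
#' reaches the threshold:
#' \deqn{\langle w\rangle^{crit} = \frac{\rho c_v R \nabla T_{ep}}
#'   {\tau_{rep}\sqrt{\tau_{diff}/\tau_p} + \tau_{diff}}
#'   = E_p^{crit}/\tau_{rep}.}
#'
#' @inheritParams critical_Ep
#' @return power density (W/m^3); divide by 1e6 for W/cm^3.
#' @examples
#' from_si(critical_w("20 ns", "100 fs"), "W/cm^3")  # ~1.77e7
#' @export
critical_w <- function(pulse_spacing, pulse_duration,
                       medium = medium_thermal(),
                       membrane = membrane_model()) {
  tr <- as_si(pulse_spacing); tp <- as_si(pulse_duration)
  .check_positive(pulse_spacing = tr, pulse_duration = tp)
  td <- .tau_diff(medium, membrane)
  .rcr(medium, membrane) * membrane$grad_threshold /
    (tr * sqrt(td / tp) + td)
}

#' Evaluate an operating point against the threshold
#'
#' Runs the full chain for one exposure: dosimetry, thermal diffusion time,
#' all critical values at the operating point, the satisfied flag, and the
#' margin factor `<w> / critical <w>` (equivalently `Ep / critical Ep`): a
#' margin of 1 means the exposure sits exactly on the threshold, below 1
#' means a factor `1/margin` short of it.
#'
#' Critical values are exact closed-form inversions of the threshold
#' inequality, not graphical readings from regime diagrams; the two can
#' differ by ~10% when diagrams are read by eye.
#'
#' @param exposure a [laser_exposure()].
#' @param medium a [medium_thermal()].
#' @param membrane a [membrane_model()].
#' @param area_convention passed to [dose_summary()].
#' @return object of class `threshold_report`: a list with the dose summary,
#'   `tau_diff`, critical values (`crit_tau_rep_fixed_Ep`,
#'   `crit_tau_rep_fixed_w`, `crit_tau_p`, `crit_Ep`, `crit_w`), `satisfied`,
#'   `margin` and the conventions applied.
#' @examples
#' exp24 <- laser_exposure("1550 nm", "100 fs", "20 ns", "24 mW", "1.5 um")
#' rep <- evaluate_operating_point(exp24)
#' rep$margin  # ~0.60: a factor ~1.7 below threshold
#' @export
evaluate_operating_point <- function(exposure, medium = medium_thermal(),
                                     membrane = membrane_model(),
                                     area_convention = c("square", "circular")) {
  stopifnot(inherits(exposure, "laser_exposure"),
            inherits(medium, "medium_thermal"),
            inherits(membrane, "membrane_model"))
  area_convention <- match.arg(area_convention)
  dose <- dose_summary(exposure, medium, area_convention)
  tp <- exposure$pulse_duration
  tr <- exposure$pulse_spacing
  cw <- critical_w(tr, tp, medium, membrane)
  margin <- dose$avg_power_density / cw
  structure(list(
    exposure = exposure,
    dose = dose,
    tau_diff = .tau_diff(medium, membrane),
    crit_tau_rep_fixed_Ep = critical_tau_rep_fixed_Ep(
      dose$peak_energy_density, tp, medium, membrane),
    crit_tau_rep_fixed_w = critical_tau_rep_fixed_w(
      dose$avg_power_density, tp, medium, membrane),
    crit_tau_p = critical_tau_p(tr, energy_density = dose$peak_energy_density,
                                medium = medium, membrane = membrane),
    crit_Ep = critical_Ep(tr, tp, medium, membrane),
    crit_w = cw,
    satisfied = margin >= 1 - 1e-9,
    margin = margin,
    conventions = list(
      area_convention = area_convention,
      grad_threshold = membrane$grad_threshold,
      grad_source = membrane$grad_source,
      boundary = "equality counts as satisfied",
      critical_values = "exact closed-form inversions (not diagram readings)"
    )
  ), class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("<threshold_report>\n")
  cat(sprintf("  tau_diff:                  %.4g s\n", x$tau_diff))
  cat(sprintf("  <w>:                       %.4g W/cm^3\n",
              from_si(x$dose$avg_power_density, "W/cm^3")))
  cat(sprintf("  Ep:                        %.4g J/cm^3\n",
              from_si(x$dose$peak_energy_density, "J/cm^3")))
  cat(sprintf("  critical <w>:              %.4g W/cm^3\n",
              from_si(x$crit_w, "W/cm^3")))
  cat(sprintf("  critical Ep:               %.4g J/cm^3\n",
              from_si(x$crit_Ep, "J/cm^3")))
  cat(sprintf("  critical tau_rep (fix Ep): %.4g s [%s]\n",
              as.numeric(x$crit_tau_rep_fixed_Ep),
              critical_flag(x$crit_tau_rep_fixed_Ep)))
  cat(sprintf("  critical tau_rep (fix w):  %.4g s [%s]\n",
              as.numeric(x$crit_tau_rep_fixed_w),
              critical_flag(x$crit_tau_rep_fixed_w)))
  cat(sprintf("  critical tau_p:            %.4g s [%s]\n",
              as.numeric(x$crit_tau_p), critical_flag(x$crit_tau_p)))
  cat(sprintf("  satisfied: %s   margin: %.3g (factor %.3g %s threshold)\n",
              x$satisfied, x$margin,
              if (x$margin >= 1) x$margin else 1 / x$margin,
              if (x$margin >= 1) "above" else "below"))
  cat(sprintf("  conventions: area=%s, grad threshold=%.3g K/m (%s)\n",
              x$conventions$area_convention, x$conventions$grad_threshold,
              x$conventions$grad_source))
  cat("  note: critical values are exact closed-form inversions;",
      "diagram-read\n  estimates in the literature can differ by ~10%.\n")
  invisible(x)
}
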