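# Independent oracles used across the suite.  These re-derive results by a
# different route than the package (boolean bisection instead of closed
# forms, 2-D quadrature instead of the encircled-power formula) so agreement
# is evidence, not tautology.

# The threshold inequality written directly from its definition, used as the
# boolean predicate for bisection.  Takes raw SI scalars, not package
# objects, and shares no code with the implementation.
oracle_gradient_satisfied <- function(tau_rep, tau_p, ep, rho, cv, r, kappa,
                                      grad_ep) {
  td <- rho * cv * r^2 / kappa
  ep * sqrt(td / tau_p) + ep * td / tau_rep >= rho * cv * r * grad_ep
}

# Geometric (log-space) bisection for the boundary of a monotone boolean
# predicate on (lo, hi).  Requires pred(lo) != pred(hi).
bisect_boundary <- function(pred, lo, hi, iter = 80L) {
  p_lo <- pred(lo)
  stopifnot(p_lo != pred(hi))
  for (i in seq_len(iter)) {
    mid <- sqrt(lo * hi)
    if (pred(mid) == p_lo) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# Brute-force transmission of a centered Gaussian beam through a circular
# aperture: 2-D quadrature of the irradiance over the disc, normalized by
# the analytic total beam power pi*w^2/2.
numeric_pinhole_transmission <- function(a, w) {
  irr <- function(x, y) exp(-2 * (x^2 + y^2) / w^2)
  q <- pracma::integral2(irr, -a, a,
                         function(x) -sqrt(pmax(a^2 - x^2, 0)),
                         function(x) sqrt(pmax(a^2 - x^2, 0)),
                         reltol = 1e-10)$Q
  q / (pi * w^2 / 2)
}

# Random positive draws spanning orders of magnitude, for property tests.
rlog_unif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

# Random physically plausible medium/membrane pairs (raw SI lists).
random_model_pair <- function() {
  med <- medium_thermal(density = runif(1, 900, 1100),
                        specific_heat = runif(1, 3500, 4500),
                        thermal_conductivity = runif(1, 0.4, 0.7),
                        absorption_coefficient = rlog_unif(1, 1e2, 1e4))
  mem <- membrane_model(cell_radius = rlog_unif(1, 2e-6, 2e-5),
                        membrane_thickness = rlog_unif(1, 4e-9, 1e-8),
                        vm_threshold = rlog_unif(1, 0.1, 1),
                        thermo_factor = rlog_unif(1, 50, 200),
                        grad_threshold = NULL)
  list(medium = med, membrane = mem)
}
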