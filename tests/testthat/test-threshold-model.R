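test_that("thermal diffusion time follows rho*cv*R^2/kappa", {
  expect_equal(thermal_diffusion_time(1, 1, 1, 1), 1)
  expect_equal(thermal_diffusion_time(1000, 4200, "10 um", 0.6), 7e-4,
               tolerance = 1e-12)
  # quadratic in the radius
  expect_equal(thermal_diffusion_time(1000, 4200, 5e-6, 0.6),
               7e-4 / 4, tolerance = 1e-12)
  expect_error(thermal_diffusion_time(-1, 4200, 1e-5, 0.6), "positive")
})

test_that("critical pulse spacings reproduce the 1550 nm working values", {
  # fixed per-pulse energy density, 100 fs pulses, gradient threshold 1e9 K/m
  expect_equal(as.numeric(critical_tau_rep_fixed_Ep("0.22 J/cm^3", "100 fs")),
               6.53e-9, tolerance = 1e-3)
  expect_equal(as.numeric(critical_tau_rep_fixed_Ep("0.132 J/cm^3", "100 fs")),
               2.985e-9, tolerance = 1e-3)
  # fixed average power density
  expect_equal(as.numeric(critical_tau_rep_fixed_w("1.1e7 W/cm^3", "100 fs")),
               3.73e-8, tolerance = 1e-3)
  expect_equal(as.numeric(critical_tau_rep_fixed_w("6.6e6 W/cm^3", "100 fs")),
               6.77e-8, tolerance = 1e-3)
  # critical pulse durations at 20 ns spacing
  expect_equal(as.numeric(critical_tau_p("20 ns", energy_density = "0.22 J/cm^3")),
               2.88e-14, tolerance = 1e-3)
  expect_equal(as.numeric(critical_tau_p("20 ns", energy_density = "0.132 J/cm^3")),
               8.73e-15, tolerance = 1e-3)
})

test_that("critical dose levels at the 20 ns / 100 fs operating point", {
  expect_equal(from_si(critical_Ep("20 ns", "100 fs"), "J/cm^3"), 0.354,
               tolerance = 1e-3)
  expect_equal(from_si(critical_w("20 ns", "100 fs"), "W/cm^3"), 1.77e7,
               tolerance = 1e-3)
  # the two are tied by Ep = tau_rep * <w> for any inputs
  set.seed(41)
  for (i in 1:50) {
    pm <- random_model_pair()
    tr <- rlog_unif(1, 1e-9, 1e-5); tp <- rlog_unif(1, 1e-15, 1e-10)
    expect_equal(critical_w(tr, tp, pm$medium, pm$membrane),
                 critical_Ep(tr, tp, pm$medium, pm$membrane) / tr,
                 tolerance = 1e-12)
  }
  # linear in the gradient threshold
  m1 <- membrane_model(grad_threshold = 1e9)
  m2 <- membrane_model(grad_threshold = 2e9)
  expect_equal(critical_Ep("20 ns", "100 fs", membrane = m2),
               2 * critical_Ep("20 ns", "100 fs", membrane = m1),
               tolerance = 1e-12)
})

test_that("fixed-Ep and fixed-w predicates are equivalent under Ep = tau_rep*<w>", {
  set.seed(43)
  n <- 1200
  for (i in seq_len(n)) {
    pm <- random_model_pair()
    tr <- rlog_unif(1, 1e-9, 1e-4)
    tp <- rlog_unif(1, 1e-15, 1e-10)
    w <- rlog_unif(1, 1e6, 1e16)
    ans_w <- threshold_satisfied(tr, tp, power_density = w,
                                 medium = pm$medium, membrane = pm$membrane)
    ans_ep <- threshold_satisfied(tr, tp, energy_density = tr * w,
                                  medium = pm$medium, membrane = pm$membrane)
    expect_identical(ans_w, ans_ep)
  }
})

test_that("closed-form criticals match bisection on the raw inequality to 1e-6", {
  set.seed(47)
  for (i in 1:60) {
    pm <- random_model_pair()
    med <- pm$medium; mem <- pm$membrane
    tp <- rlog_unif(1, 1e-15, 1e-10)
    tr <- rlog_unif(1, 1e-9, 1e-4)
    pred_ep <- function(ep) {
      oracle_gradient_satisfied(tr, tp, ep, med$density, med$specific_heat,
                                mem$cell_radius, med$thermal_conductivity,
                                mem$grad_threshold)
    }
    # critical Ep: boundary of the predicate in Ep
    expect_equal(critical_Ep(tr, tp, med, mem),
                 bisect_boundary(pred_ep, 1e-6, 1e20), tolerance = 1e-6)
    # critical <w>: same boundary expressed as a power density
    expect_equal(critical_w(tr, tp, med, mem),
                 bisect_boundary(pred_ep, 1e-6, 1e20) / tr, tolerance = 1e-6)

    # critical tau_rep at the fixed Ep of a near-threshold train
    ep0 <- 0.5 * critical_Ep(tr, tp, med, mem)
    ct <- critical_tau_rep_fixed_Ep(ep0, tp, med, mem)
    if (critical_flag(ct) != "always_satisfied") {
      pred_tr <- function(x) {
        oracle_gradient_satisfied(x, tp, ep0, med$density, med$specific_heat,
                                  mem$cell_radius, med$thermal_conductivity,
                                  mem$grad_threshold)
      }
      expect_equal(as.numeric(ct),
                   bisect_boundary(pred_tr, 1e-20, 1e10), tolerance = 1e-6)
    }
    # critical tau_p at a sub-threshold Ep
    ctp <- critical_tau_p(tr, energy_density = ep0, medium = med,
                          membrane = mem)
    if (critical_flag(ctp) != "always_satisfied") {
      pred_tp <- function(x) {
        oracle_gradient_satisfied(tr, x, ep0, med$density, med$specific_heat,
                                  mem$cell_radius, med$thermal_conductivity,
                                  mem$grad_threshold)
      }
      expect_equal(as.numeric(ctp),
                   bisect_boundary(pred_tp, 1e-30, 1e5), tolerance = 1e-6)
    }
  }
})

test_that("inversions are mutually consistent at the threshold boundary", {
  set.seed(53)
  for (i in 1:40) {
    pm <- random_model_pair()
    tr <- rlog_unif(1, 1e-9, 1e-5); tp <- rlog_unif(1, 1e-15, 1e-10)
    ep_star <- critical_Ep(tr, tp, pm$medium, pm$membrane)
    # feeding the critical Ep back returns the original tau_rep and tau_p
    expect_equal(as.numeric(critical_tau_rep_fixed_Ep(ep_star, tp, pm$medium,
                                                      pm$membrane)),
                 tr, tolerance = 1e-9)
    expect_equal(as.numeric(critical_tau_p(tr, energy_density = ep_star,
                                           medium = pm$medium,
                                           membrane = pm$membrane)),
                 tp, tolerance = 1e-9)
    # exactly-critical operating point counts as satisfied
    expect_true(threshold_satisfied(tr, tp, energy_density = ep_star,
                                    medium = pm$medium,
                                    membrane = pm$membrane))
  }
})

test_that("criticals are monotone in the expected directions", {
  tp <- 1e-13
  ep_grid <- seq(0.05, 0.3, by = 0.05) * 1e6
  crit_tr <- vapply(ep_grid, function(e)
    as.numeric(critical_tau_rep_fixed_Ep(e, tp)), numeric(1))
  expect_true(all(diff(crit_tr) > 0))  # more energy per pulse buys spacing

  tr_grid <- 10^seq(-9, -5, length.out = 12)
  cw <- vapply(tr_grid, function(tr) critical_w(tr, tp), numeric(1))
  expect_true(all(diff(cw) < 0))  # longer spacing -> lower <w> needed

  tp_grid <- 10^seq(-15, -10, length.out = 12)
  cw_tp <- vapply(tp_grid, function(t) critical_w(2e-8, t), numeric(1))
  expect_true(all(diff(cw_tp) > 0))  # longer pulses -> weaker transient

  # margin grows with average power
  sc <- reference_scenario()
  m <- vapply(c(0.005, 0.015, 0.024, 0.05), function(p) {
    e <- laser_exposure(1.55e-6, 1e-13, 2e-8, p, 1.5e-6)
    evaluate_operating_point(e, sc$medium, sc$membrane)$margin
  }, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("continuous-wave limit degenerates to the steady-state condition", {
  pm <- random_model_pair()
  med <- pm$medium; mem <- pm$membrane
  td <- thermal_diffusion_time(med$density, med$specific_heat,
                               mem$cell_radius, med$thermal_conductivity)
  steady <- med$density * med$specific_heat * mem$cell_radius *
    mem$grad_threshold / td
  tr <- 1e-6
  cw_long_pulse <- critical_w(tr, tr * 0.999999, med, mem)
  # as tau_p -> tau_rep the transient term's weight vanishes relative to
  # accumulation only when tau_rep*sqrt(td/tau_p) << td
  expect_equal(critical_w(tr, 1e6 * td, med, mem), steady, tolerance = 1e-2)
  expect_lt(cw_long_pulse, 10 * steady)
})

test_that("degenerate outcomes are flagged results, not errors", {
  # a single pulse's transient alone crosses the threshold
  big <- critical_tau_rep_fixed_Ep("1e3 J/cm^3", "100 fs")
  expect_identical(critical_flag(big), "always_satisfied")
  expect_identical(as.numeric(big), Inf)
  # steady state alone suffices at enormous <w>
  hot <- critical_tau_rep_fixed_w("1e12 W/cm^3", "100 fs")
  expect_identical(critical_flag(hot), "always_satisfied")
  expect_identical(as.numeric(hot), 0)
  expect_identical(critical_flag(critical_tau_p("20 ns",
                                                energy_density = "1e3 J/cm^3")),
                   "always_satisfied")
  # critical spacing shorter than the pulse itself: no physical train
  tiny <- critical_tau_rep_fixed_Ep(1e-2, 1e-10)
  expect_identical(critical_flag(tiny), "unreachable")
})

test_that("operating-point evaluation ties the stages together", {
  sc <- reference_scenario()
  hi <- evaluate_operating_point(sc$exposure_high, sc$medium, sc$membrane)
  lo <- evaluate_operating_point(sc$exposure_low, sc$medium, sc$membrane)
  expect_s3_class(hi, "threshold_report")
  expect_false(hi$satisfied)
  expect_false(lo$satisfied)
  # 24 mW sits a factor ~1.66 below threshold, 15 mW a factor ~2.65
  expect_equal(hi$margin, 0.6027, tolerance = 1e-3)
  expect_equal(lo$margin, 0.3767, tolerance = 1e-3)
  expect_equal(hi$margin,
               hi$dose$avg_power_density / hi$crit_w, tolerance = 1e-12)
  # exactly-critical power gives margin 1 and satisfied
  p_star <- 0.024 / hi$margin
  e_star <- laser_exposure(1.55e-6, 1e-13, 2e-8, p_star, 1.5e-6)
  r_star <- evaluate_operating_point(e_star, sc$medium, sc$membrane)
  expect_equal(r_star$margin, 1, tolerance = 1e-9)
  expect_true(r_star$satisfied)
})
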