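test_that("curve points equal direct threshold-model calls", {
  crv <- build_curve("fixed_Ep", "0.22 J/cm^3")
  expect_s3_class(crv, "regime_curve")
  expect_true(is.unsorted(crv$tau_p_s) == FALSE)
  i <- sample(nrow(crv), 20)
  direct <- vapply(crv$tau_p_s[i], function(tp)
    as.numeric(critical_tau_rep_fixed_Ep(2.2e5, tp)), numeric(1))
  expect_equal(crv$tau_rep_crit_s[i], direct, tolerance = 1e-12)

  crw <- build_curve("fixed_w", "6.6e6 W/cm^3")
  j <- sample(nrow(crw), 20)
  direct_w <- vapply(crw$tau_p_s[j], function(tp)
    as.numeric(critical_tau_rep_fixed_w(6.6e12, tp)), numeric(1))
  expect_equal(crw$tau_rep_crit_s[j], direct_w, tolerance = 1e-12)
})

test_that("curves contain the named working values at tau_p = 100 fs", {
  # 1e-13 s is a node of the default grid only approximately; use exact grid
  grid <- c(1e-14, 1e-13, 1e-12)
  c_ep <- build_curve("fixed_Ep", "0.22 J/cm^3", grid)
  expect_equal(c_ep$tau_rep_crit_s[2], 6.53e-9, tolerance = 1e-3)
  c_w <- build_curve("fixed_w", "6.6e6 W/cm^3", grid)
  expect_equal(c_w$tau_rep_crit_s[2], 6.77e-8, tolerance = 1e-3)
  c_mid <- build_curve("fixed_Ep", "0.32 J/cm^3", grid)
  expect_equal(c_mid$tau_rep_crit_s[2], 1.47e-8, tolerance = 2e-3)
})

test_that("curve families shift monotonically with their dose level", {
  grid <- 10^seq(-15, -10, length.out = 30)
  ep_levels <- default_curve_levels("fixed_Ep")
  curves <- lapply(ep_levels, function(l) build_curve("fixed_Ep", l, grid))
  for (k in seq_len(length(curves) - 1)) {
    ok <- curves[[k]]$flag == "ok" & curves[[k + 1]]$flag == "ok"
    expect_true(all(curves[[k + 1]]$tau_rep_crit_s[ok] >
                      curves[[k]]$tau_rep_crit_s[ok]))
  }
  w_levels <- default_curve_levels("fixed_w")
  wcurves <- lapply(w_levels, function(l) build_curve("fixed_w", l, grid))
  for (k in seq_len(length(wcurves) - 1)) {
    ok <- wcurves[[k]]$flag == "ok" & wcurves[[k + 1]]$flag == "ok"
    expect_true(all(wcurves[[k + 1]]$tau_rep_crit_s[ok] <
                      wcurves[[k]]$tau_rep_crit_s[ok]))
  }
})

test_that("operating-point placement matches the satisfaction regions", {
  # the 20 ns / 100 fs point misses the fixed-Ep condition at 0.22 J/cm^3
  c_ep <- build_curve("fixed_Ep", "0.22 J/cm^3")
  p1 <- place_point(c_ep, "20 ns", "100 fs")
  expect_identical(p1$side, "unsatisfied")
  expect_gt(p1$distance_factor, 1)  # spacing too long for this mode
  # and misses the fixed-w condition at 1.1e7 W/cm^3
  c_w <- build_curve("fixed_w", "1.1e7 W/cm^3")
  p2 <- place_point(c_w, "20 ns", "100 fs")
  expect_identical(p2$side, "unsatisfied")
  expect_lt(p2$distance_factor, 1)  # spacing too short for this mode
  # a point exactly on the curve counts as satisfied
  grid <- c(5e-14, 1e-13, 5e-13)
  c_x <- build_curve("fixed_Ep", "0.22 J/cm^3", grid)
  p3 <- place_point(c_x, c_x$tau_rep_crit_s[2], 1e-13)
  expect_identical(p3$side, "satisfied")
  expect_equal(p3$distance_factor, 1, tolerance = 1e-12)
  expect_error(place_point(c_x, 2e-8, 1e-9), "grid span")
})

test_that("placement agrees with evaluate_operating_point wherever both apply", {
  set.seed(61)
  sc <- reference_scenario()
  for (i in 1:25) {
    p <- rlog_unif(1, 1e-3, 0.2)
    tp <- rlog_unif(1, 1e-14, 1e-11)
    tr <- rlog_unif(1, 1e-9, 1e-6)
    if (tp >= tr) next
    e <- laser_exposure(1.55e-6, tp, tr, p, 1.5e-6)
    rep <- evaluate_operating_point(e, sc$medium, sc$membrane)
    crv <- build_curve("fixed_w", rep$dose$avg_power_density,
                       medium = sc$medium, membrane = sc$membrane)
    pl <- place_point(crv, tr, tp)
    expect_identical(pl$side == "satisfied", rep$satisfied)
  }
})

test_that("log-log interpolation between nodes is sane", {
  # deliberately coarse two-node bracket around tau_p = 1e-13 s
  grid <- c(5e-14, 2e-13)
  crv <- build_curve("fixed_Ep", "0.22 J/cm^3", grid)
  dense <- build_curve("fixed_Ep", "0.22 J/cm^3", c(5e-14, 1e-13, 2e-13))
  pl <- place_point(crv, "20 ns", 1e-13)
  exact <- dense$tau_rep_crit_s[2]
  # interpolant stays within the node bracket and lands near the exact value
  expect_true(pl$tau_rep_crit <= max(crv$tau_rep_crit_s) &&
                pl$tau_rep_crit >= min(crv$tau_rep_crit_s))
  expect_equal(pl$tau_rep_crit, exact, tolerance = 0.15)
})

test_that("curve CSVs are written one file per level with the declared columns", {
  dir <- withr::local_tempdir()
  files <- write_curve_family("fixed_w", dir = dir,
                              tau_p_grid = 10^seq(-15, -10, length.out = 10))
  expect_length(files, 4)
  expect_true(all(file.exists(files)))
  tab <- utils::read.csv(files[1])
  expect_named(tab, c("tau_p_s", "tau_rep_crit_s", "flag"))
  expect_equal(nrow(tab), 10)
})
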