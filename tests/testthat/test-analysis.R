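# Dispersion statistics, bifurcation structure of the isolated switches,
# limit-cycle detection and parameter robustness.

test_that("qcd matches hand computations and is scale invariant", {
  expect_equal(qcd(c(2, 2, 2, 2)), 0)
  expect_equal(qcd(1:5), 1 / 3)          # Q1 = 2, Q3 = 4 under type-7
  set.seed(8)
  x <- runif(40, 1, 3)
  expect_equal(qcd(17 * x), qcd(x))
  expect_error(qcd(1:3), "at least 4")
  expect_error(qcd(c(1, 2, 3, -1)), "positive")
})

test_that("fit_slope reproduces closed-form OLS results", {
  expect_equal(fit_slope(1:10, 1:10), 1)
  expect_equal(fit_slope(1:10, 3 - (1:10)), -1)
  expect_equal(fit_slope(c(1, 2, 3), c(0.5, 0.9, 1.2)), 0.35)
  expect_error(fit_slope(rep(1, 4), 1:4), "constant")
})

test_that("dispersion_summary tabulates checkpoint QCDs and ratios", {
  pop <- fx_population("si", fx_flags_si(), 1)
  ds <- dispersion_summary(pop)
  expect_equal(ds$ratio_g1s_birth, ds$qcd_g1s / ds$qcd_birth)
  expect_equal(ds$ratio_g2m_birth,
               ds$ratio_g1s_birth * ds$ratio_g2m_g1s, tolerance = 1e-12)
  # an ideal sizer population has (numerically) zero dispersion at division
  sizer <- simulate_ideal(ideal_rule("sizer", 2, 0.001), 1,
                          division_sampler(0.05), seed = 1)
  expect_lt(dispersion_summary(sizer)$qcd_g2m, 1e-9)
  expect_error(dispersion_summary(pop[0, ]), "completed cells")
})

test_that("the isolated G1/S switch is bistable and folds", {
  scan <- bifurcation_scan("g1s", seq(0.05, 1.2, length.out = 30),
                           fx_params())
  bc <- branch_counts(scan)
  # a contiguous window with three steady states, two of them stable
  tri <- bc[bc$n_steady == 3, ]
  expect_gt(nrow(tri), 2)
  expect_true(all(tri$n_stable == 2))
  expect_true(all(diff(which(bc$n_steady == 3)) == 1))
  # monostable on both flanks, with high KRP at low kinase and low KRP at
  # high kinase
  expect_equal(bc$n_steady[1], 1)
  expect_equal(bc$n_steady[nrow(bc)], 1)
  lo <- scan$value[scan$control == min(scan$control)]
  hi <- scan$value[scan$control == max(scan$control)]
  expect_gt(lo, 10 * hi)
  # two saddle-node folds delimit the window
  expect_equal(length(attr(scan, "folds")), 2)
})

test_that("the isolated G2/M switch is bistable; removing SMR makes it
           monostable", {
  scan <- bifurcation_scan("g2m", seq(0.05, 1.5, length.out = 30),
                           fx_params())
  bc <- branch_counts(scan)
  expect_gt(sum(bc$n_steady == 3), 2)
  expect_equal(length(attr(scan, "folds")), 2)
  # high-SMR branch at low kinase, low-SMR branch at high kinase
  lo <- max(scan$value[scan$control == min(scan$control)])
  hi <- max(scan$value[scan$control == max(scan$control)])
  expect_gt(lo, 5 * hi)

  nosmr <- bifurcation_scan("g2m_nosmr", seq(0.05, 1.5, length.out = 30),
                            fx_params())
  bcn <- branch_counts(nosmr)
  expect_true(all(bcn$n_steady == 1))
  expect_equal(length(attr(nosmr, "folds")), 0)
  # the repressor declines smoothly with the clamped kinase instead of
  # switching
  vals <- nosmr$value[order(nosmr$control)]
  expect_true(all(diff(vals) < 0))
})

test_that("stability labels agree with direct simulation of the reduced
           subsystem", {
  p <- fx_params()
  scan <- bifurcation_scan("g2m", seq(0.45, 0.6, length.out = 3), p)
  states <- scan[!is.na(scan$value), ]
  expect_gte(nrow(states), 6)
  for (i in seq_len(nrow(states))) {
    y0 <- as.numeric(states[i, c("MYB3R3", "MYB3R4", "SMR")])
    cb_total <- states$control[i]
    rhs <- function(t, y, parms) {
      list(phytocycle:::.g2m_rhs(y, cb_total, p, 1))
    }
    # nudge by 1% and integrate
    out <- deSolve::ode(y0 * 1.01, seq(0, 4000, 50), rhs, NULL,
                        rtol = 1e-9, atol = 1e-11)
    yT <- as.numeric(out[nrow(out), -1])
    returned <- sqrt(sum((yT - y0)^2)) < 0.02 * (1 + sqrt(sum(y0^2)))
    if (states$stable[i]) {
      expect_true(returned)
    } else {
      expect_false(returned)
    }
  }
})

test_that("default parameters admit a limit cycle; broken ones do not", {
  lc <- fx_limit_cycle()
  expect_true(lc$cycling)
  expect_gt(lc$period, 100)
  expect_gte(length(lc$peaks), 3)
  # no G1/S activator synthesis, no cycle
  expect_false(limit_cycle_detect(default_parameters(r_ca = 0))$cycling)
  # 100x faster degradation everywhere: proteins cannot accumulate
  p <- fx_params()
  degr <- grep("^d_", names(p), value = TRUE)
  p[degr] <- 100 * p[degr]
  expect_false(limit_cycle_detect(p)$cycling)
})

test_that("one G1/S and one G2/M switch occur per limit-cycle period", {
  lc <- fx_limit_cycle()
  p <- fx_params()
  p[["r_gr"]] <- 0
  start <- cell_state(volume = 1, masses = lc$state_end[-1])
  tr <- phytocycle:::.integrate_dense(start, p, hypothesis_flags(),
                                      seq(0, 3 * lc$period, lc$period / 400))
  ups <- function(frac) sum(diff(frac >= 0.5) == 1)
  n_g1s <- ups(tr$E2FA_free / tr$E2FA)
  n_g2m <- ups(tr$MYB3R4_p / tr$MYB3R4)
  expect_equal(n_g1s, 3)   # three periods, one switch each
  expect_equal(n_g2m, 3)
})

test_that("limit-cycle period is insensitive to integration tolerances", {
  p <- fx_params()
  lc1 <- limit_cycle_detect(p, horizon = 6000, dt = 2)
  lc2 <- limit_cycle_detect(p, horizon = 6000, dt = 1)
  expect_equal(lc1$period, lc2$period, tolerance = 1e-3)
})

test_that("robustness scan brackets the default and reports loss directions", {
  p <- fx_params()
  rs <- robustness_scan(p, parameters = c("r_ca", "r_krp"), n_grid = 5)
  iv <- robustness_intervals(rs)
  # the default value always cycles, hence lies inside its own interval
  expect_true(all(iv$rel_lower <= 1 & iv$rel_upper >= 1))
  # the G1/S activator synthesis cannot be too small
  expect_true(iv$bounded_below[iv$parameter == "r_ca"])
  # the KRP synthesis rate cannot be too large
  expect_true(iv$bounded_above[iv$parameter == "r_krp"])
})
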