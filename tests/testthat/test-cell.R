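# Single-cell simulation: event detection, division bookkeeping, growth-rate
# calibration.

test_that("a full cycle orders its events and doubles the volume", {
  cyc <- fx_cycle()
  ev <- cyc$events
  expect_true(ev$completed)
  expect_lt(ev$t_birth, ev$t_g1s)
  expect_lt(ev$t_g1s, ev$t_g2m)
  expect_lt(ev$t_g2m, ev$t_div)
  expect_true(all(diff(cyc$trajectory$V) > 0))        # r_gr > 0
  # calibrated growth: the volume doubles over one cycle
  expect_gt(ev$V_div / ev$V_birth, 1.95)
  expect_lt(ev$V_div / ev$V_birth, 2.05)
})

test_that("trajectory-based detectors agree with the root-located events", {
  cyc <- fx_cycle()
  tr <- cyc$trajectory
  step <- diff(tr$time[1:2])
  expect_equal(detect_g1s(tr), cyc$events$t_g1s, tolerance = step)
  expect_equal(detect_g2m(tr, after = cyc$events$t_g1s), cyc$events$t_g2m,
               tolerance = step)
})

test_that("detectors handle degenerate trajectories", {
  # without RBR, E2FA is free from the start: no upward crossing through
  # theta exists because the fraction never drops below it; with CYCB
  # production removed the G2/M readout never rises
  p <- default_parameters(r_rbr = 0, r_cb = 0, r_cb_e2fb = 0)
  s <- cell_state(volume = 1, E2FA = 1)
  tr <- phytocycle:::.integrate_dense(s, p, hypothesis_flags(),
                                      seq(0, 50, 1))
  expect_true(all(tr$E2FA_free / tr$E2FA > 0.99))
  expect_warning(t1 <- detect_g1s(tr), "no G1/S")
  expect_true(is.na(t1))
  # without any CYCB the G2/M readout never rises
  expect_warning(t2 <- detect_g2m(tr), "no G2/M")
  expect_true(is.na(t2))
})

test_that("transition timing is insensitive to the threshold choice", {
  # the switches are sharp: moving theta from 0.4 to 0.6 moves the detected
  # times by well under 5% of the cycle period
  p <- fx_params()
  f <- fx_founder()
  period <- attr(calibrate_growth_rate(p), "period")
  lo <- run_cycle(f, p, horizon = 6000, theta_e2fa = 0.4, theta_myb4 = 0.4)
  hi <- run_cycle(f, p, horizon = 6000, theta_e2fa = 0.6, theta_myb4 = 0.6)
  expect_lt(abs(lo$events$t_g1s - hi$events$t_g1s), 0.05 * period)
  expect_lt(abs(lo$events$t_g2m - hi$events$t_g2m), 0.05 * period)
})

test_that("division conserves volume and mass, and splits as directed", {
  m <- cell_state(volume = 2, CDKA_CYCD = 0.4, KRP = 1, RBR = 2, SMR = 0.6)
  # symmetric, proportional
  d5 <- divide_cell(m, 0.5)
  expect_equal(d5$daughters[[1]], d5$daughters[[2]])
  # asymmetric with equal inheritance of KRP
  h <- hypothesis_flags(equal_inheritance = "KRP")
  d7 <- divide_cell(m, 0.7, h)
  s1 <- d7$daughters[[1]]; s2 <- d7$daughters[[2]]
  expect_equal(s1[["V"]] + s2[["V"]], m[["V"]])
  for (prot in phytocycle:::.phyto_proteins) {
    expect_equal(s1[[prot]] + s2[[prot]], m[[prot]])
  }
  expect_equal(s1[["KRP"]], m[["KRP"]] / 2)
  expect_equal(s2[["KRP"]], m[["KRP"]] / 2)
  # equal mass in unequal volumes: lower concentration in the big daughter
  expect_lt(s1[["KRP"]] / s1[["V"]], s2[["KRP"]] / s2[["V"]])
  # proportional proteins keep the mother's concentration
  expect_equal(s1[["RBR"]] / s1[["V"]], m[["RBR"]] / m[["V"]])
  expect_error(divide_cell(m, 0), "strictly")
  expect_error(divide_cell(m, 1), "strictly")
})

test_that("the all-size-dependent cycle is a timer: duration independent of size", {
  p <- fx_params()
  f <- fx_founder()
  big <- f * 2
  names(big) <- names(f)
  c1 <- run_cycle(f, p, horizon = 6000)
  c2 <- run_cycle(big, p, horizon = 6000)
  d1 <- c1$events$t_div - c1$events$t_birth
  d2 <- c2$events$t_div - c2$events$t_birth
  expect_equal(d1, d2, tolerance = 1e-4)
})

test_that("growth-rate calibration is self-consistent and rescales with time", {
  p <- fx_params()
  r <- calibrate_growth_rate(p)
  expect_equal(exp(as.numeric(r) * attr(r, "period")), 2, tolerance = 1e-9)
  # shipped default is this calibrated value
  expect_equal(as.numeric(r), p[["r_gr"]], tolerance = 0.002)
  # uniform x2 speed-up of every rate constant halves the period and
  # doubles the calibrated growth rate
  rates <- setdiff(grep("^[rd]_", names(p), value = TRUE), "r_gr")
  p2 <- p
  p2[rates] <- 2 * p2[rates]
  validate_parameters(p2)
  r2 <- calibrate_growth_rate(p2)
  expect_equal(as.numeric(r2), 2 * as.numeric(r), tolerance = 0.01)
})

test_that("birth-volume sweeps reproduce the size-control shapes", {
  p <- fx_params()
  vols <- seq(0.3, 1.2, length.out = 8)
  # all size-dependent: added G1 volume increases with birth volume
  sw0 <- sweep_birth_volume(vols, p)
  expect_true(all(sw0$completed))
  expect_true(all(diff(sw0$added_g1) > 0))
  # KRP size-independent: negative trend for small cells, flattening for
  # large ones (imperfect sizer -> adder)
  sw_krp <- sweep_birth_volume(vols, p,
                               hypothesis_flags(size_independent = "KRP"))
  small <- diff(sw_krp$added_g1[1:4])
  large <- diff(sw_krp$added_g1[5:8])
  expect_true(all(small < 0))
  expect_true(all(abs(large) < abs(small[1])))
  # RBR size-independent behaves the same way at G1/S
  sw_rbr <- sweep_birth_volume(vols, p,
                               hypothesis_flags(size_independent = "RBR"))
  expect_true(all(diff(sw_rbr$added_g1[1:4]) < 0))
  # SMR size-independent: G2/M duration falls steeply with size
  sw_smr <- sweep_birth_volume(vols, p,
                               hypothesis_flags(size_independent = "SMR"))
  expect_true(all(diff(sw_smr$g2m_duration) < 0))
})
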