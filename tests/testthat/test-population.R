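# Population engine: sampler properties, determinism, lineage consistency.

test_that("division sampler draws strictly inside (0,1) with mean 1/2", {
  s <- division_sampler(sd = 0.3)   # wide, so truncation is exercised
  set.seed(5)
  d <- draw_asymmetry(s, 5000)
  expect_true(all(d > 0 & d < 1))
  expect_equal(mean(d), 0.5, tolerance = 0.02)
  # sd = 0 collapses to the symmetric point
  expect_equal(draw_asymmetry(division_sampler(sd = 0), 3), rep(0.5, 3))
})

test_that("population runs are byte-identical under a fixed seed", {
  pop1 <- simulate_population(fx_params(), fx_flags_si(), seed = 99,
                              max_cells = 64)
  pop2 <- simulate_population(fx_params(), fx_flags_si(), seed = 99,
                              max_cells = 64)
  expect_identical(tibble::as_tibble(pop1), tibble::as_tibble(pop2))
})

test_that("lineage records are internally consistent", {
  pop <- fx_population("si", fx_flags_si(), 1)
  cc <- pop[pop$completed, ]
  expect_gte(nrow(cc), 100)
  # event ordering and growth within each completed cell
  expect_true(all(cc$t_birth < cc$t_g1s))
  expect_true(all(cc$t_g1s < cc$t_g2m))
  expect_true(all(cc$t_g2m < cc$t_div))
  expect_true(all(cc$V_birth < cc$V_g1s))
  expect_true(all(cc$V_g1s < cc$V_g2m))
  # every child is born exactly when its parent divides
  kids <- pop[!is.na(pop$parent), ]
  parent_div <- cc$t_div[match(kids$parent, cc$cell)]
  expect_equal(kids$t_birth, parent_div)
  # sibling volumes sum to the parent division volume
  sums <- tapply(kids$V_birth, kids$parent, sum)
  parent_vol <- cc$V_div[match(as.integer(names(sums)), cc$cell)]
  expect_equal(as.numeric(sums), parent_vol, tolerance = 1e-9)
  # generations increment along the lineage
  parent_gen <- cc$generation[match(kids$parent, cc$cell)]
  expect_true(all(kids$generation == parent_gen + 1L))
})

test_that("a symmetric deterministic population divides synchronously", {
  pop <- simulate_population(fx_params(), sampler = division_sampler(sd = 0),
                             max_cells = 64, seed = 1)
  cc <- pop[pop$completed, ]
  # within each generation, all birth volumes and division times coincide
  for (g in unique(cc$generation)) {
    sub <- cc[cc$generation == g, ]
    expect_lt(diff(range(sub$V_birth)), 1e-8)
    expect_lt(diff(range(sub$t_div)), 1e-6)
  }
})

test_that("phase_scatter summarises completed cells only, consistently", {
  pop <- fx_population("si", fx_flags_si(), 1)
  ps <- phase_scatter(pop)
  expect_equal(nrow(ps), sum(pop$completed))
  expect_equal(ps$added_g1, ps$V_g1s - ps$V_birth)
  expect_true(all(ps$g1_duration > 0))
  expect_true(all(ps$g2m_duration > 0))
  # empty case
  empty <- pop[pop$completed == FALSE & is.na(pop$t_g1s), ][0, ]
  class(empty) <- class(pop)
  expect_equal(nrow(phase_scatter(empty)), 0)
})

test_that("population CSV + JSON sidecar round-trip the records", {
  pop <- simulate_population(fx_params(), fx_flags_si(), seed = 3,
                             max_cells = 32)
  f <- tempfile(fileext = ".csv")
  write_population(pop, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(pop))
  expect_equal(back$V_birth, pop$V_birth, tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$seed, 3)
  expect_equal(meta$hypothesis$size_independent,
               list("KRP", "SMR"))
  expect_equal(meta$parameters$r_ca, 0.01)
  unlink(c(f, paste0(f, ".json")))
})

test_that("size-independent inhibitors keep the size range bounded; the
           fully size-dependent model does not", {
  pop_si <- fx_population("si", fx_flags_si(), 1)
  pop_sd <- fx_population("sd", hypothesis_flags(), 1)
  ds_si <- dispersion_summary(pop_si)
  ds_sd <- dispersion_summary(pop_sd)
  # dual size-independence compresses dispersion within the cycle
  expect_lt(ds_si$ratio_g2m_birth, 0.8)
  # the timer model leaves dispersion unchanged (no control)
  expect_gt(ds_sd$ratio_g2m_birth, 0.95)
  # and its birth-volume spread grows over generations (all born cells,
  # well-populated generations only)
  v <- generation_spread(pop_sd)
  expect_gt(tail(v, 1), 1.2 * v[1])
})
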