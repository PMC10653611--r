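# Network core: binding/phosphorylation algebra, conservation closures, and
# agreement between the reference R right-hand side and the compiled one.

test_that("qss_complex matches limits and the closed-form example", {
  expect_equal(qss_complex(0, 5, 1, 1), 0)            # no A, no complex
  expect_equal(qss_complex(5, 0, 1, 1), 0)
  expect_equal(qss_complex(1, 1, 1, 0), 1)            # infinite affinity
  expect_equal(qss_complex(1, 1, 1, 1), (3 - sqrt(5)) / 2, tolerance = 1e-12)
  expect_error(qss_complex(-1, 1, 1, 1), "non-negative")
  expect_error(qss_complex(1, 1, 0, 1), "positive")
})

test_that("qss_complex agrees with a mass-action equilibrium root-finder", {
  # Independent oracle: solve k+ (A-C)(B-C)/V = k- C for C directly.
  oracle <- function(A, B, V, kD) {
    if (A == 0 || B == 0) return(0)
    f <- function(C) (A - C) * (B - C) / V - kD * C
    uniroot(f, c(0, min(A, B)), tol = 1e-14)$root
  }
  set.seed(42)
  for (i in 1:100) {
    A <- runif(1, 0, 5); B <- runif(1, 0, 5)
    V <- runif(1, 0.2, 4); kD <- 10^runif(1, -4, 1)
    expect_equal(qss_complex(A, B, V, kD), oracle(A, B, V, kD),
                 tolerance = 1e-8)
  }
})

test_that("qss_complex is bounded by both partner totals", {
  set.seed(7)
  A <- runif(50, 0, 3); B <- runif(50, 0, 3)
  V <- runif(50, 0.5, 2); kD <- 10^runif(50, -4, 0)
  C <- qss_complex(A, B, V, kD)
  expect_true(all(C >= 0))
  expect_true(all(C <= pmin(A, B) + 1e-12))
})

test_that("phospho_fraction matches limits, half-saturation and direct form", {
  expect_equal(phospho_fraction(0, 1, 1), 0)
  expect_equal(phospho_fraction(1, 0.25, 4), 0.5)     # A == kdp * V
  expect_equal(phospho_fraction(3, 1, 1), 0.75)
  # monotone in kinase, anti-monotone in volume
  a <- phospho_fraction(c(0.5, 1, 2), 0.25, 1)
  expect_true(all(diff(a) > 0))
  v <- phospho_fraction(1, 0.25, c(1, 2, 4))
  expect_true(all(diff(v) < 0))
  expect_error(phospho_fraction(1, 1, 0), "positive")
})

test_that("regulated_synthesis covers basal, saturated and generic cases", {
  expect_equal(
    regulated_synthesis(0.01, 0, 5, 0.001, volume = 2, size_dependent = TRUE),
    0.02)
  # full induction: activator >> volume / kat
  expect_equal(
    regulated_synthesis(0, 0.1, 1e12, 1, volume = 1, size_dependent = FALSE),
    0.1, tolerance = 1e-9)
  expect_equal(
    regulated_synthesis(0, 0.01, 1, 0.001, volume = 1, size_dependent = FALSE),
    0.01 / 1.001, tolerance = 1e-12)
})

test_that("algebraic_state satisfies its conservation closures", {
  p <- fx_params()
  # degenerate states
  zero <- cell_state(volume = 1)
  expect_true(all(as.numeric(algebraic_state(zero, p)) == 0))
  no_krp <- cell_state(volume = 1, CDKA_CYCD = 0.7)
  a <- algebraic_state(no_krp, p)
  expect_equal(a$CDKA_CYCD_free, 0.7)                 # no inhibitor, all free
  # random states: closures to 1e-9 relative
  set.seed(11)
  for (i in 1:50) {
    s <- fx_random_state(function(n, lo, hi) runif(n, lo, hi))
    a <- algebraic_state(s, p)
    expect_equal(a$CDKA_CYCD_KRP + a$CDKA_CYCD_free, s[["CDKA_CYCD"]],
                 tolerance = 1e-9)
    expect_equal(a$RBR_p + a$RBR_u, s[["RBR"]], tolerance = 1e-9)
    expect_equal(a$E2FA_RBR + a$E2FA_free, s[["E2FA"]], tolerance = 1e-9)
    expect_equal(a$CDKB_CYCB_SMR + a$CDKB_CYCB_free, s[["CDKB_CYCB"]],
                 tolerance = 1e-9)
    expect_equal(a$MYB3R3_p + a$MYB3R3_u, s[["MYB3R3"]], tolerance = 1e-9)
    expect_equal(a$SMR_p + a$SMR_u, s[["SMR"]], tolerance = 1e-9)
    expect_true(a$CDKA_CYCD_KRP <= min(s[["CDKA_CYCD"]], s[["KRP"]]) + 1e-12)
    expect_true(a$E2FA_RBR <= min(s[["E2FA"]], a$RBR_u) + 1e-12)
    expect_true(all(as.numeric(a) >= -1e-12))
  }
})

test_that("rhs reduces to basal synthesis at the empty state", {
  p <- fx_params()
  d <- cycle_rhs(0, cell_state(volume = 1), p)[[1]]
  names(d) <- c("V", phytocycle:::.phyto_proteins)
  expect_equal(d[["V"]], p[["r_gr"]])
  expect_equal(d[["E2FA"]], p[["r_e2fa"]])
  expect_equal(d[["RBR"]], p[["r_rbr"]])   # size-dependent at V = 1
  expect_equal(d[["CDKA_CYCD"]], p[["r_ca"]])
  expect_equal(d[["CDKB_CYCB"]], 0)        # no E2FB, basal rate is 0
})

test_that("with zero growth and zero synthesis every mass decays", {
  p <- fx_params()
  synth <- grep("^r_", names(p), value = TRUE)
  p[synth] <- 0
  validate_parameters(p)
  set.seed(3)
  for (i in 1:10) {
    s <- fx_random_state(function(n, lo, hi) runif(n, 0.1, hi))
    d <- cycle_rhs(0, s, p)[[1]]
    expect_true(all(d <= 1e-12))
  }
})

test_that("compiled rhs agrees with the reference R rhs", {
  p <- fx_params()
  configs <- list(
    hypothesis_flags(),
    fx_flags_si(),
    fx_flags_pd_sd()
  )
  set.seed(19)
  for (flags in configs) {
    parms <- phytocycle:::.ode_parms(p, flags)
    for (i in 1:20) {
      s <- fx_random_state(function(n, lo, hi) runif(n, lo, hi))
      dR <- cycle_rhs(0, s, p, flags)[[1]]
      dC <- deSolve::DLLfunc(
        func = "cycle_derivs", dllname = "phytocycle",
        initfunc = "cycle_initmod",
        times = 0, y = unname(s), parms = parms, nout = 13
      )$dy
      expect_equal(dR, unname(dC), tolerance = 1e-12)
    }
  }
})

test_that("the size-dependent model is scale-invariant in concentration", {
  # With all proteins size-dependent and r_gr = 0, scaling volume and all
  # masses by the same factor rescales the derivatives by that factor, so
  # concentration dynamics are identical at V = 1 and V = 10.
  p <- fx_params()
  p[["r_gr"]] <- 0
  set.seed(23)
  for (i in 1:10) {
    s1 <- fx_random_state(function(n, lo, hi) runif(n, 0.05, 2))
    s10 <- s1 * 10
    names(s10) <- names(s1)
    d1 <- cycle_rhs(0, s1, p)[[1]]
    d10 <- cycle_rhs(0, s10, p)[[1]]
    expect_equal(d10, 10 * d1, tolerance = 1e-9)
  }
})

test_that("parameter constructor validates and rejects bad input", {
  expect_error(default_parameters(nonsense = 1), "unknown parameter")
  expect_error(default_parameters(r_ca = -1), "negative")
  p <- fx_params()
  expect_identical(names(p), phytocycle:::.phyto_param_order)
  expect_s3_class(tidy(p), "tbl_df")
  expect_equal(nrow(tidy(p)), length(p))
})

test_that("hypothesis flags validate their protein lists", {
  expect_error(hypothesis_flags(size_independent = "E2FA"), "size-independent")
  expect_error(hypothesis_flags(equal_inheritance = "XYZ"), "unknown protein")
  h <- hypothesis_flags(size_independent = c("KRP", "SMR"),
                        equal_inheritance = "KRP",
                        krp_phase_dependent = TRUE)
  p2 <- phytocycle:::.apply_hypothesis_params(fx_params(), h)
  expect_equal(p2[["r_krp"]], 0)
  expect_equal(p2[["d_krp"]], 0)
  expect_equal(p2[["r_krp_myb4"]], 0.05)
})
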