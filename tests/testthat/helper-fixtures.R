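# Shared fixtures, computed lazily and cached for the whole test run.
# The shipped default r_gr is already the calibrated value, so most tests can
# use default_parameters() directly; expensive population runs used by
# several tests are memoised here.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

fx_params <- function() default_parameters()

# Flags for the four standard hypothesis rows.
fx_flags_si <- function() hypothesis_flags(size_independent = c("KRP", "SMR"))
fx_flags_eqinh <- function() {
  hypothesis_flags(size_independent = "SMR", equal_inheritance = "KRP")
}
fx_flags_pd_si <- function() {
  hypothesis_flags(size_independent = "SMR", equal_inheritance = "KRP",
                   krp_phase_dependent = TRUE)
}
fx_flags_pd_sd <- function() {
  hypothesis_flags(equal_inheritance = "KRP", krp_phase_dependent = TRUE)
}

# Population run for a hypothesis, memoised per (label, seed).  Nine
# doubling times so every configuration accumulates well over 200 completed
# cells.
fx_population <- function(label, flags, seed) {
  fixture(paste0("pop_", label, "_", seed), {
    p <- fx_params()
    simulate_population(p, flags, seed = seed,
                        t_max = 9 * log(2) / p[["r_gr"]])
  })
}

fx_founder <- function() {
  fixture("founder", make_founder(fx_params()))
}

# A recorded full-cycle trajectory from the canonical founder.
fx_cycle <- function() {
  fixture("cycle", {
    run_cycle(fx_founder(), fx_params(), horizon = 6000,
              record = TRUE, n_grid = 800)
  })
}

# Limit-cycle detection at default parameters.
fx_limit_cycle <- function() {
  fixture("limit_cycle", limit_cycle_detect(fx_params()))
}

# Variance of log birth volume per generation.  Only fully populated
# generations (all 2^g cells born before the stop time) are used: the last
# generations are truncated at t_max towards fast -- hence atypical --
# lineages, which biases their spread.
generation_spread <- function(pop, min_n = 16) {
  n <- table(pop$generation)
  g <- as.integer(names(n))
  gens <- g[n == 2^g & n >= min_n]
  vapply(gens, function(g) var(log(pop$V_birth[pop$generation == g])),
         numeric(1))
}

# A plain R-side random state generator for property tests.
fx_random_state <- function(rng) {
  cell_state(volume = rng(1, 0.3, 3),
             masses = setNames(rng(12, 0, 3),
                               phytocycle:::.phyto_proteins))
}
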