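## Internal integration engine: staged event detection on the compiled
## right-hand side.  The two transition readouts are
##   1: free-E2FA fraction of total E2FA   (G1/S)
##   2: phosphorylated fraction of MYB3R4  (G2/M)
## Each stage integrates until the readout crosses its threshold (deSolve's
## lsodar locates the root internally to high precision); crossings are made
## directional by staging: a readout that starts above threshold is first
## integrated down through it.

.phyto_state_names <- function() c("V", .phyto_proteins)

## Transition readout fractions at a single state.
.readout_fractions <- function(state, params, flags = hypothesis_flags()) {
  p <- .apply_hypothesis_params(params, flags)
  a <- .algebraic_one(state, p)
  e2fa_t <- state[["E2FA"]]
  myb4_t <- state[["MYB3R4"]]
  c(e2fa = if (e2fa_t > 0) a[["E2FA_free"]] / e2fa_t else 0,
    myb4 = if (myb4_t > 0) a[["MYB3R4_p"]] / myb4_t else 0)
}

## One lsodar stage: integrate from t0 until the selected readout crosses
## theta (either direction) or tend is reached.  Returns the root time (NA if
## none) and the state there.
.stage_run <- function(state, parms, root_var, theta, t0, tend,
                       rtol = 1e-8, atol = 1e-10) {
  parms[length(parms) - 1L] <- root_var
  parms[length(parms)] <- theta
  out <- deSolve::lsodar(
    y = unname(state[.phyto_state_names()]),
    times = c(t0, tend),
    func = "cycle_derivs", parms = parms,
    dllname = "phytocycle", initfunc = "cycle_initmod",
    rootfunc = "cycle_root", nroot = 1,
    rtol = rtol, atol = atol
  )
  troot <- attr(out, "troot")
  yend <- setNames(as.numeric(out[nrow(out), 1 + seq_len(13)]),
                   .phyto_state_names())
  list(t = if (length(troot)) troot[1] else NA_real_, state = yend)
}

## Integrate one full cycle from birth to division.  Events:
##   t_g1s:  first upward crossing of the free-E2FA fraction through theta_e2fa
##   t_g2m:  first upward crossing of the phospho-MYB3R4 fraction through
##           theta_myb4 after t_g1s (the G2/M checkpoint)
##   t_div:  the subsequent downward crossing of the same readout -- the end
##           of the mitotic program, where division occurs
## Returns NULL if any event is missing within the horizon.
.cycle_events <- function(state, params, flags, t0, horizon,
                          theta_e2fa = 0.5, theta_myb4 = 0.5,
                          rtol = 1e-8, atol = 1e-10) {
  parms <- .ode_parms(params, flags)
  tend <- t0 + horizon
  fr <- .readout_fractions(state, params, flags)
  tcur <- t0

  ## G1/S: if born with E2FA already free (post-mitotic state), wait for the
  ## reset first.
  if (fr[["e2fa"]] >= theta_e2fa) {
    s <- .stage_run(state, parms, 1, theta_e2fa, tcur, tend, rtol, atol)
    if (is.na(s$t)) return(NULL)
    tcur <- s$t; state <- s$state
  }
  s <- .stage_run(state, parms, 1, theta_e2fa, tcur, tend, rtol, atol)
  if (is.na(s$t)) return(NULL)
  t_g1s <- s$t; state <- s$state; tcur <- t_g1s
  V_g1s <- state[["V"]]

  ## G2/M checkpoint.
  fr <- .readout_fractions(state, params, flags)
  if (fr[["myb4"]] >= theta_myb4) {
    s <- .stage_run(state, parms, 2, theta_myb4, tcur, tend, rtol, atol)
    if (is.na(s$t)) return(NULL)
    tcur <- s$t; state <- s$state
  }
  s <- .stage_run(state, parms, 2, theta_myb4, tcur, tend, rtol, atol)
  if (is.na(s$t)) return(NULL)
  t_g2m <- s$t; state <- s$state; tcur <- t_g2m
  V_g2m <- state[["V"]]

  ## End of mitosis: the readout falls back through the threshold.
  s <- .stage_run(state, parms, 2, theta_myb4, tcur, tend, rtol, atol)
  if (is.na(s$t)) return(NULL)

  list(t_g1s = t_g1s, V_g1s = V_g1s,
       t_g2m = t_g2m, V_g2m = V_g2m,
       t_div = s$t, state_div = s$state)
}

## Dense trajectory (fixed grid) of the compiled model, with the algebraic
## layer appended; no event handling.
.integrate_dense <- function(state, params, flags, times,
                             rtol = 1e-8, atol = 1e-10) {
  parms <- .ode_parms(params, flags)
  out <- deSolve::ode(
    y = unname(state[.phyto_state_names()]),
    times = times,
    func = "cycle_derivs", parms = parms,
    dllname = "phytocycle", initfunc = "cycle_initmod",
    nout = 13, outnames = .phyto_algebraic,
    rtol = rtol, atol = atol
  )
  colnames(out) <- c("time", .phyto_state_names(), .phyto_algebraic)
  tibble::as_tibble(as.data.frame(out))
}
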