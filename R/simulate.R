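## Single-cell simulation: one full cycle with event detection, division,
## growth-rate calibration, founder construction, and birth-volume sweeps.

#' Simulate one cell cycle with transition detection
#'
#' Integrates a single growing cell from birth until division.  The G1/S
#' transition is detected as the first upward crossing of the free-E2FA
#' fraction (free E2FA / total E2FA) through `theta_e2fa`; the G2/M
#' transition as the first upward crossing of the phosphorylated-MYB3R4
#' fraction through `theta_myb4` after G1/S.  Division occurs at the end of
#' the mitotic program, when the MYB3R4 readout falls back through its
#' threshold (after the APC pulse has reset the cyclins); the G2/M checkpoint
#' time and volume are recorded separately.  Readouts that start above their
#' threshold (as in a freshly born, post-mitotic cell) are first integrated
#' down through it, so only genuine low-to-high switches count.
#'
#' @param state birth state, from [cell_state()] or a previous division.
#' @param params a `phyto_params` vector.
#' @param flags a `phyto_hypothesis`.
#' @param horizon maximum simulated time for the cycle; cells that do not
#'   divide within it are reported as incomplete.
#' @param t0 birth time (only offsets the reported times).
#' @param theta_e2fa,theta_myb4 transition thresholds (fractions of total);
#'   the switches are sharp, so results are insensitive to the exact value.
#' @param record if `TRUE`, also return a dense trajectory with the
#'   algebraic layer on a grid of `n_grid` points.
#' @param n_grid number of trajectory grid points when `record = TRUE`.
#' @return An object of class `phyto_cycle`: a list with `events` (one-row
#'   tibble: `t_birth`, `V_birth`, `t_g1s`, `V_g1s`, `t_g2m`, `V_g2m`,
#'   `t_div`, `V_div`, `completed`), `state_div` (state at division, or
#'   `NULL`), and `trajectory` (tibble or `NULL`).
#' @examples
#' \donttest{
#' p <- default_parameters()
#' cyc <- run_cycle(make_founder(p), p, horizon = 5000)
#' cyc$events
#' }
#' @export
run_cycle <- function(state, params, flags = hypothesis_flags(),
                      horizon = 5000, t0 = 0,
                      theta_e2fa = 0.5, theta_myb4 = 0.5,
                      record = FALSE, n_grid = 400) {
  validate_parameters(params)
  validate_state(state)
  ev <- .cycle_events(state, params, flags, t0, horizon,
                      theta_e2fa, theta_myb4)
  completed <- !is.null(ev)
  events <- tibble::tibble(
    t_birth = t0, V_birth = state[["V"]],
    t_g1s = if (completed) ev$t_g1s else NA_real_,
    V_g1s = if (completed) ev$V_g1s else NA_real_,
    t_g2m = if (completed) ev$t_g2m else NA_real_,
    V_g2m = if (completed) ev$V_g2m else NA_real_,
    t_div = if (completed) ev$t_div else NA_real_,
    V_div = if (completed) ev$state_div[["V"]] else NA_real_,
    completed = completed
  )
  trajectory <- NULL
  if (record) {
    tmax <- if (completed) ev$t_div else t0 + horizon
    times <- seq(t0, tmax, length.out = n_grid)
    trajectory <- .integrate_dense(state, params, flags, times)
  }
  structure(
    list(events = events,
         state_div = if (completed) ev$state_div else NULL,
         trajectory = trajectory,
         params = params, flags = flags),
    class = "phyto_cycle"
  )
}

#' @export
print.phyto_cycle <- function(x, ...) {
  cat("<phyto_cycle>", if (x$events$completed) "completed" else "incomplete",
      "\n")
  print(x$events)
  invisible(x)
}

#' @export
tidy.phyto_cycle <- function(x, ...) {
  if (is.null(x$trajectory)) {
    stop("no trajectory recorded; rerun run_cycle() with record = TRUE")
  }
  x$trajectory
}

#' @export
glance.phyto_cycle <- function(x, ...) x$events

## First upward crossing time of y (on grid t) through theta, requiring the
## readout to have been below theta first; linear interpolation between grid
## points.  Returns NA if there is no such crossing.
.first_up_crossing <- function(t, y, theta, after = -Inf) {
  ok <- t >= after
  t <- t[ok]; y <- y[ok]
  below <- which(y < theta)
  if (!length(below)) return(NA_real_)
  i0 <- below[1]
  if (i0 >= length(y)) return(NA_real_)
  rest <- seq(i0 + 1L, length(y))
  up <- rest[y[rest] >= theta][1]
  if (is.na(up)) return(NA_real_)
  i <- up - 1L
  t[i] + (theta - y[i]) / (y[up] - y[i]) * (t[up] - t[i])
}

#' Detect the G1/S transition on a recorded trajectory
#'
#' Returns the first time the free-E2FA fraction crosses `theta` from below,
#' interpolated linearly between trajectory grid points.  This is the
#' grid-based counterpart of the root-located event used by [run_cycle()];
#' the two agree to within one grid step.
#'
#' @param trajectory tibble as returned in `run_cycle(record = TRUE)`.
#' @param theta threshold on the free-E2FA fraction (default 0.5).
#' @return Crossing time, or `NA` (with a warning) if no crossing occurs.
#' @export
detect_g1s <- function(trajectory, theta = 0.5) {
  frac <- ifelse(trajectory$E2FA > 0,
                 trajectory$E2FA_free / trajectory$E2FA, 0)
  t <- .first_up_crossing(trajectory$time, frac, theta)
  if (is.na(t)) warning("no G1/S event within the trajectory")
  t
}

#' Detect the G2/M transition on a recorded trajectory
#'
#' Returns the first time after `after` (typically the G1/S time) that the
#' phosphorylated-MYB3R4 fraction crosses `theta` from below.
#'
#' @param trajectory tibble as returned in `run_cycle(record = TRUE)`.
#' @param theta threshold on the phospho-MYB3R4 fraction (default 0.5).
#' @param after only consider crossings after this time.
#' @return Crossing time, or `NA` (with a warning) if no crossing occurs.
#' @export
detect_g2m <- function(trajectory, theta = 0.5, after = -Inf) {
  frac <- ifelse(trajectory$MYB3R4 > 0,
                 trajectory$MYB3R4_p / trajectory$MYB3R4, 0)
  t <- .first_up_crossing(trajectory$time, frac, theta, after = after)
  if (is.na(t)) warning("no G2/M event within the trajectory")
  t
}

#' Divide a cell into two daughters
#'
#' Volume splits as `d` : `1 - d`.  Every protein mass splits in the same
#' proportion (rapid diffusion homogenises concentration before division),
#' except proteins flagged as equally inherited, whose mass is split exactly
#' in half regardless of `d` (the chromatin-bound-inhibitor assumption).
#' Volume and every protein mass are conserved exactly.
#'
#' @param state mother state at division.
#' @param d fraction of the mother volume given to the first daughter,
#'   strictly in (0, 1).
#' @param flags a `phyto_hypothesis` (supplies `equal_inheritance`).
#' @return A list with `daughters` (list of two `phyto_state`s) and
#'   `asymmetry` (`d`).
#' @examples
#' m <- cell_state(2, KRP = 1, RBR = 2)
#' divide_cell(m, 0.7, hypothesis_flags(equal_inheritance = "KRP"))
#' @export
divide_cell <- function(state, d, flags = hypothesis_flags()) {
  validate_state(state)
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d <= 0 || d >= 1) {
    stop("division fraction d must lie strictly in (0, 1)")
  }
  s1 <- state * d
  s2 <- state * (1 - d)
  for (prot in flags$equal_inheritance) {
    s1[[prot]] <- state[[prot]] / 2
    s2[[prot]] <- state[[prot]] / 2
  }
  cls <- c("phyto_state", "numeric")
  list(daughters = list(structure(s1, class = cls),
                        structure(s2, class = cls)),
       asymmetry = d)
}

#' Calibrate the volume growth rate to the cell-cycle period
#'
#' Chooses the exponential growth rate so that cells double in volume over
#' one cell cycle: `r_gr = ln(2) / T`, where the period `T` is itself
#' measured at the calibrated growth rate (the period depends weakly on
#' `r_gr` because growth dilutes every concentration).  The fixed point is
#' found by iteration, started from the period of the `r_gr = 0` limit cycle
#' detected via CDKA/B:CYCB peaks; each iteration simulates a symmetrically
#' dividing cell for a few cycles and measures the stabilised cycle length.
#'
#' @param params a `phyto_params` vector (the `r_gr` entry is ignored).
#' @param flags hypothesis flags under which to calibrate (default: all
#'   proteins size-dependent).
#' @param tol relative tolerance on the fixed point (default `1e-4`).
#' @param max_iter maximum fixed-point iterations.
#' @return The calibrated growth rate (1/time), with attributes `period`
#'   (the self-consistent cycle length) and `iterations`.
#' @examples
#' \donttest{
#' r <- calibrate_growth_rate(default_parameters())
#' exp(r * attr(r, "period"))  # == 2 by construction
#' }
#' @export
calibrate_growth_rate <- function(params, flags = hypothesis_flags(),
                                  tol = 1e-4, max_iter = 25) {
  validate_parameters(params)
  lc <- limit_cycle_detect(params, flags)
  if (!lc$cycling) {
    stop("calibration failed: no limit cycle at r_gr = 0")
  }
  rgr <- log(2) / lc$period
  start <- lc$state_end
  start[["V"]] <- 1
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    p <- params
    p[["r_gr"]] <- rgr
    y <- start
    tcur <- 0
    t_last <- NA_real_
    for (k in 1:4) {
      ev <- .cycle_events(y, p, flags, tcur, horizon = 6 * lc$period)
      if (is.null(ev)) stop("calibration failed: cycle did not complete")
      t_last <- ev$t_div - tcur
      tcur <- ev$t_div
      y <- ev$state_div / 2
      y[["V"]] <- ev$state_div[["V"]] / 2
      names(y) <- .phyto_state_names()
    }
    rnew <- log(2) / t_last
    converged <- abs(rnew - rgr) / rgr < tol
    rgr <- rnew
    if (converged) break
  }
  structure(rgr, period = log(2) / rgr, iterations = iterations)
}

#' Canonical founder cell
#'
#' Builds a birth state on the stable cycling attractor by burn-in: a single
#' cell is integrated through `cycles` full cycles under the given hypothesis
#' flags, dividing symmetrically each time, and the final post-division state
#' is returned.
#'
#' @param params a `phyto_params` vector with the growth rate to use in
#'   `r_gr` (see [calibrate_growth_rate()]).
#' @param flags a `phyto_hypothesis`.
#' @param cycles number of burn-in cycles (default 5).
#' @param horizon per-cycle time horizon.
#' @return A `phyto_state` at birth.
#' @export
make_founder <- function(params, flags = hypothesis_flags(), cycles = 5,
                         horizon = 6000) {
  validate_parameters(params)
  y <- cell_state(volume = 1,
                  masses = setNames(rep(0.1, 12), .phyto_proteins))
  tcur <- 0
  for (k in seq_len(cycles)) {
    ev <- .cycle_events(y, params, flags, tcur, horizon)
    if (is.null(ev)) {
      stop("founder burn-in failed: cycle ", k, " did not complete")
    }
    tcur <- ev$t_div
    y <- ev$state_div / 2
    names(y) <- .phyto_state_names()
  }
  structure(y, class = c("phyto_state", "numeric"))
}

#' Single-cycle sweep over birth volumes
#'
#' Runs one full cycle for founder cells of varying birth volume, with all
#' protein masses scaled in proportion to volume from a common reference
#' birth state -- except equally inherited proteins and size-independent
#' inhibitors, whose birth masses are held at the reference value (their
#' steady masses do not scale with size).  This reproduces the
#' single-cycle hypothesis tests relating birth volume to phase durations
#' and added volumes.
#'
#' @param volumes numeric vector of birth volumes.
#' @param params a `phyto_params` vector (with calibrated `r_gr`).
#' @param flags a `phyto_hypothesis`.
#' @param reference optional reference birth state; defaults to
#'   `make_founder(params, flags)`.
#' @param horizon per-cycle horizon.
#' @return A tibble with one row per founder: `V_birth`, `g1_duration`,
#'   `g2m_duration`, `cycle_duration`, `V_g1s`, `V_g2m`, `V_div`,
#'   `added_g1`, `added_g2m`, `completed`.
#' @export
sweep_birth_volume <- function(volumes, params, flags = hypothesis_flags(),
                               reference = NULL, horizon = 8000) {
  validate_parameters(params)
  if (is.null(reference)) reference <- make_founder(params, flags)
  fixed_mass <- union(flags$equal_inheritance,
                      intersect(flags$size_independent, .phyto_si_candidates))
  purrr::map_dfr(volumes, function(v) {
    y <- reference * (v / reference[["V"]])
    for (prot in fixed_mass) y[[prot]] <- reference[[prot]]
    y[["V"]] <- v
    names(y) <- .phyto_state_names()
    ev <- .cycle_events(y, params, flags, 0, horizon)
    if (is.null(ev)) {
      return(tibble::tibble(
        V_birth = v, g1_duration = NA_real_, g2m_duration = NA_real_,
        cycle_duration = NA_real_, V_g1s = NA_real_, V_g2m = NA_real_,
        V_div = NA_real_, added_g1 = NA_real_, added_g2m = NA_real_,
        completed = FALSE))
    }
    tibble::tibble(
      V_birth = v,
      g1_duration = ev$t_g1s,
      g2m_duration = ev$t_g2m - ev$t_g1s,
      cycle_duration = ev$t_div,
      V_g1s = ev$V_g1s, V_g2m = ev$V_g2m, V_div = ev$state_div[["V"]],
      added_g1 = ev$V_g1s - v, added_g2m = ev$V_g2m - ev$V_g1s,
      completed = TRUE
    )
  })
}
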