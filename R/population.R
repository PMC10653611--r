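## Multi-generation population engine: stochastic asymmetric division over a
## binary lineage tree, scheduled in continuous time.

#' Division-asymmetry sampler
#'
#' The fraction `d` of the mother volume given to the first daughter is drawn
#' from a normal distribution with mean 1/2, truncated to the open interval
#' (0, 1).  Truncation is by rejection (an exact truncated normal), not by
#' clipping, so no probability mass piles up at the boundaries.
#'
#' @param sd standard deviation of the underlying normal (default 0.05; see
#'   the vignette for how this default was fixed).
#' @param mean mean of the underlying normal (default 0.5).
#' @return An object of class `phyto_sampler`.
#' @export
division_sampler <- function(sd = 0.05, mean = 0.5) {
  stopifnot(is.numeric(sd), sd >= 0, mean > 0, mean < 1)
  structure(list(mean = mean, sd = sd), class = "phyto_sampler")
}

#' Draw division fractions
#'
#' @param sampler a `phyto_sampler`.
#' @param n number of draws.
#' @return `n` values strictly in (0, 1).
#' @export
draw_asymmetry <- function(sampler, n = 1) {
  stopifnot(inherits(sampler, "phyto_sampler"))
  if (sampler$sd == 0) return(rep(sampler$mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, sampler$mean, sampler$sd)
    out <- c(out, x[x > 0 & x < 1])
  }
  out[seq_len(n)]
}

#' Simulate a dividing cell population
#'
#' Starting from a founder cell, repeatedly: integrate the cell-cycle network
#' through one full cycle ([run_cycle()] semantics), divide at the end of
#' mitosis with a fresh asymmetry draw, and enqueue both daughters.  Cells
#' are processed in birth-time order (continuous-time event queue), so
#' divisions are asynchronous.  A cell whose division would fall beyond
#' `t_max`, or that fails to complete a cycle within its per-cell horizon, is
#' recorded as incomplete and not subdivided.  A fixed `seed` makes the run
#' exactly reproducible.
#'
#' @param params a `phyto_params` vector with calibrated `r_gr` (see
#'   [calibrate_growth_rate()]).
#' @param flags a `phyto_hypothesis`.
#' @param sampler a `phyto_sampler` for the division asymmetry.
#' @param founder birth state of the founding cell; defaults to the burn-in
#'   founder [make_founder()] under the same flags.
#' @param t_max simulated-time stop condition; default 8 mass-doubling times
#'   (`8 * log(2) / r_gr`).
#' @param max_cells hard cap on the number of simulated cells.
#' @param seed integer RNG seed; `NULL` leaves the RNG state alone.
#' @param horizon per-cell integration horizon; default 4 doubling times.
#' @param theta_e2fa,theta_myb4 transition thresholds.
#' @return A tibble of class `phyto_population`, one row per simulated cell:
#'   `cell`, `parent`, `generation`, `t_birth`, `V_birth`, `t_g1s`, `V_g1s`,
#'   `t_g2m`, `V_g2m`, `t_div`, `V_div`, `completed`.  Simulation settings
#'   (`params`, `flags`, `sampler`, `seed`, `t_max`) are attached as
#'   attributes.
#' @examples
#' \donttest{
#' p <- default_parameters()
#' h <- hypothesis_flags(size_independent = c("KRP", "SMR"))
#' pop <- simulate_population(p, h, seed = 1)
#' dispersion_summary(pop)
#' }
#' @export
simulate_population <- function(params, flags = hypothesis_flags(),
                                sampler = division_sampler(),
                                founder = NULL,
                                t_max = NULL, max_cells = 4096,
                                seed = NULL, horizon = NULL,
                                theta_e2fa = 0.5, theta_myb4 = 0.5) {
  validate_parameters(params)
  stopifnot(inherits(sampler, "phyto_sampler"))
  rgr <- params[["r_gr"]]
  if (rgr <= 0) stop("params[['r_gr']] must be positive; calibrate it first")
  doubling <- log(2) / rgr
  if (is.null(t_max)) t_max <- 8 * doubling
  if (is.null(horizon)) horizon <- 4 * doubling
  if (is.null(founder)) founder <- make_founder(params, flags)
  validate_state(founder)

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    }, add = TRUE)
    set.seed(seed)
  }

  queue <- list(list(state = founder, t = 0, id = 1L,
                     parent = NA_integer_, gen = 0L))
  records <- vector("list", 256L)
  n_rec <- 0L
  next_id <- 2L
  push_record <- function(rec) {
    n_rec <<- n_rec + 1L
    if (n_rec > length(records)) records[[2L * n_rec]] <<- NULL
    records[[n_rec]] <<- rec
  }

  while (length(queue) > 0 && next_id <= max_cells) {
    births <- vapply(queue, function(c) c$t, numeric(1))
    ids <- vapply(queue, function(c) c$id, integer(1))
    i <- order(births, ids)[1]  # deterministic: earliest birth, lowest id
    cell <- queue[[i]]
    queue[[i]] <- NULL

    ev <- .cycle_events(cell$state, params, flags, cell$t, horizon,
                        theta_e2fa, theta_myb4)
    if (is.null(ev) || ev$t_div > t_max) {
      push_record(list(cell = cell$id, parent = cell$parent,
                       generation = cell$gen,
                       t_birth = cell$t, V_birth = cell$state[["V"]],
                       t_g1s = NA_real_, V_g1s = NA_real_,
                       t_g2m = NA_real_, V_g2m = NA_real_,
                       t_div = NA_real_, V_div = NA_real_,
                       completed = FALSE))
      next
    }
    push_record(list(cell = cell$id, parent = cell$parent,
                     generation = cell$gen,
                     t_birth = cell$t, V_birth = cell$state[["V"]],
                     t_g1s = ev$t_g1s, V_g1s = ev$V_g1s,
                     t_g2m = ev$t_g2m, V_g2m = ev$V_g2m,
                     t_div = ev$t_div, V_div = ev$state_div[["V"]],
                     completed = TRUE))
    d <- draw_asymmetry(sampler, 1)
    daughters <- divide_cell(ev$state_div, d, flags)$daughters
    for (k in 1:2) {
      queue[[length(queue) + 1L]] <- list(state = daughters[[k]],
                                          t = ev$t_div,
                                          id = next_id,
                                          parent = cell$id,
                                          gen = cell$gen + 1L)
      next_id <- next_id + 1L
    }
  }

  out <- dplyr::bind_rows(lapply(records[seq_len(n_rec)], tibble::as_tibble))
  out <- dplyr::arrange(out, .data$cell)
  structure(out,
            class = c("phyto_population", class(tibble::tibble())),
            params = params, flags = flags, sampler = sampler,
            seed = seed, t_max = t_max)
}

#' Per-cell phase table of a population
#'
#' For every completed cell: birth volume, G1 duration and added volume
#' during G1, volume at G1/S, S/G2/M duration and added volume from G1/S to
#' the G2/M checkpoint.
#'
#' @param population a `phyto_population`.
#' @return A tibble with columns `cell`, `generation`, `V_birth`,
#'   `g1_duration`, `added_g1`, `V_g1s`, `g2m_duration`, `added_g2m`,
#'   `V_g2m`.  Empty (zero rows) if no cell completed.
#' @export
phase_scatter <- function(population) {
  cc <- dplyr::filter(tibble::as_tibble(population), .data$completed)
  tibble::tibble(
    cell = cc$cell,
    generation = cc$generation,
    V_birth = cc$V_birth,
    g1_duration = cc$t_g1s - cc$t_birth,
    added_g1 = cc$V_g1s - cc$V_birth,
    V_g1s = cc$V_g1s,
    g2m_duration = cc$t_g2m - cc$t_g1s,
    added_g2m = cc$V_g2m - cc$V_g1s,
    V_g2m = cc$V_g2m
  )
}

#' @export
glance.phyto_population <- function(x, ...) {
  cc <- dplyr::filter(tibble::as_tibble(x), .data$completed)
  tibble::tibble(
    n_cells = nrow(x),
    n_completed = nrow(cc),
    generations = max(x$generation),
    t_max = attr(x, "t_max"),
    seed = attr(x, "seed") %||% NA_integer_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write population records and run metadata to disk
#'
#' The lineage table goes to `file` as CSV (documented header identical to
#' the tibble columns); the run metadata (parameters, hypothesis flags,
#' sampler settings, seed, stop condition) goes to a JSON sidecar at
#' `<file>.json`.
#'
#' @param population a `phyto_population`.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_population <- function(population, file) {
  utils::write.csv(tibble::as_tibble(population), file, row.names = FALSE)
  flags <- attr(population, "flags")
  sampler <- attr(population, "sampler")
  meta <- list(
    package = "phytocycle",
    version = as.character(utils::packageVersion("phytocycle")),
    seed = attr(population, "seed"),
    t_max = attr(population, "t_max"),
    sampler = list(mean = sampler$mean, sd = sampler$sd),
    hypothesis = list(
      size_independent = flags$size_independent,
      equal_inheritance = flags$equal_inheritance,
      krp_phase_dependent = flags$krp_phase_dependent
    ),
    parameters = as.list(unclass(attr(population, "params")))
  )
  jsonlite::write_json(meta, paste0(file, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
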