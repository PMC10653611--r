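## Reference sizer / adder / timer population models with exponential growth.
## Division times are closed-form, so no ODE integration is involved.

#' Idealised division rule
#'
#' Phenomenological single-parameter division rules for exponentially growing
#' cells (`dV/dt = r_gr V`):
#' \describe{
#'   \item{sizer}{divide on reaching a fixed volume `V_S`; birth-to-division
#'     time is `log(V_S / V_b) / r_gr` (0 if born at or above `V_S`).}
#'   \item{adder}{divide after adding a fixed volume `V_A`; time is
#'     `log((V_b + V_A) / V_b) / r_gr`.}
#'   \item{timer}{divide a fixed time `t_c` after birth.}
#' }
#'
#' @param kind `"sizer"`, `"adder"` or `"timer"`.
#' @param parameter the rule parameter (`V_S`, `V_A` or `t_c`; > 0).
#' @param growth_rate exponential volume growth rate (> 0).
#' @return An object of class `phyto_ideal_rule`.
#' @examples
#' ideal_rule("sizer", 2, growth_rate = 0.001)
#' @export
ideal_rule <- function(kind = c("sizer", "adder", "timer"), parameter,
                       growth_rate) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(parameter), parameter > 0,
            is.numeric(growth_rate), growth_rate > 0)
  structure(list(kind = kind, parameter = parameter,
                 growth_rate = growth_rate),
            class = "phyto_ideal_rule")
}

## Closed-form birth-to-division time.
.ideal_division_time <- function(rule, v_birth) {
  switch(rule$kind,
    sizer = pmax(log(rule$parameter / v_birth), 0) / rule$growth_rate,
    adder = log((v_birth + rule$parameter) / v_birth) / rule$growth_rate,
    timer = rep(rule$parameter, length(v_birth))
  )
}

#' Simulate an idealised cell population
#'
#' Iterates growth and stochastic asymmetric division for one of the
#' phenomenological rules of [ideal_rule()].  The output has the same record
#' format as [simulate_population()], with the network-specific columns
#' (`t_g1s`, `V_g1s`, `t_g2m`, `V_g2m`) set to `NA`.  Timer cells with a
#' symmetric sampler divide simultaneously each generation; the shared
#' continuous-time event queue handles both synchronous and asynchronous
#' division.
#'
#' @param rule a `phyto_ideal_rule`.
#' @param founder_volume volume of the founding cell (> 0).
#' @param sampler a [division_sampler()].
#' @param t_max simulated-time stop condition; default 8 volume-doubling
#'   times.
#' @param max_cells cap on the number of simulated cells.
#' @param seed integer RNG seed.
#' @return A `phyto_population` tibble (see [simulate_population()]).
#' @examples
#' rule <- ideal_rule("sizer", 2, growth_rate = 0.001)
#' pop <- simulate_ideal(rule, 1, division_sampler(0.05), seed = 1)
#' max(abs(pop$V_div[pop$completed] - 2)) < 1e-9
#' @export
simulate_ideal <- function(rule, founder_volume = 1,
                           sampler = division_sampler(),
                           t_max = NULL, max_cells = 4096, seed = NULL) {
  stopifnot(inherits(rule, "phyto_ideal_rule"), founder_volume > 0)
  if (is.null(t_max)) t_max <- 8 * log(2) / rule$growth_rate

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    }, add = TRUE)
    set.seed(seed)
  }

  queue <- list(list(v = founder_volume, t = 0, id = 1L,
                     parent = NA_integer_, gen = 0L))
  recs <- list()
  next_id <- 2L
  while (length(queue) > 0 && next_id <= max_cells) {
    births <- vapply(queue, function(c) c$t, numeric(1))
    ids <- vapply(queue, function(c) c$id, integer(1))
    i <- order(births, ids)[1]
    cell <- queue[[i]]
    queue[[i]] <- NULL

    dt <- .ideal_division_time(rule, cell$v)
    t_div <- cell$t + dt
    id <- cell$id; parent <- cell$parent; gen <- cell$gen
    t_birth <- cell$t; v_birth <- cell$v
    if (t_div > t_max) {
      recs[[length(recs) + 1L]] <- tibble::tibble(
        cell = id, parent = parent, generation = gen,
        t_birth = t_birth, V_birth = v_birth,
        t_g1s = NA_real_, V_g1s = NA_real_,
        t_g2m = NA_real_, V_g2m = NA_real_,
        t_div = NA_real_, V_div = NA_real_, completed = FALSE)
      next
    }
    v_div <- cell$v * exp(rule$growth_rate * dt)
    recs[[length(recs) + 1L]] <- tibble::tibble(
      cell = id, parent = parent, generation = gen,
      t_birth = t_birth, V_birth = v_birth,
      t_g1s = NA_real_, V_g1s = NA_real_,
      t_g2m = NA_real_, V_g2m = NA_real_,
      t_div = t_div, V_div = v_div, completed = TRUE)
    d <- draw_asymmetry(sampler, 1)
    for (v_child in c(d * v_div, (1 - d) * v_div)) {
      queue[[length(queue) + 1L]] <- list(v = v_child, t = t_div,
                                          id = next_id, parent = cell$id,
                                          gen = cell$gen + 1L)
      next_id <- next_id + 1L
    }
  }
  out <- dplyr::arrange(dplyr::bind_rows(recs), .data$cell)
  structure(out,
            class = c("phyto_population", class(tibble::tibble())),
            params = NULL, flags = NULL, sampler = sampler,
            seed = seed, t_max = t_max, rule = rule)
}
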