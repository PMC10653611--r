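## Simulated over- and under-expression experiments for the two
## kinase-cyclin activators.

#' Over-/under-expression experiment for a kinase-cyclin complex
#'
#' Runs population simulations for wild-type, over-expressed (synthesis rate
#' x 1.5) and under-expressed (x 0.8) variants of one kinase-cyclin complex
#' and summarises the distributions of cell size at G1/S, G1 duration, size
#' at division and total cycle duration.  For CDKA:CYCD the scaled rate is
#' the basal synthesis rate `r_ca`; for CDKA/B:CYCB it is the E2FB-driven
#' rate `r_cb_e2fb` (the basal rate is zero).  Populations are simulated
#' under size-independent KRP and SMR, the configuration with the most
#' robust size control, so that expression changes show their full effect
#' on cell size.
#'
#' @param target `"CDKA:CYCD"` or `"CDKA/B:CYCB"`.
#' @param params baseline `phyto_params` with calibrated `r_gr` (the growth
#'   rate is NOT recalibrated per scenario; expression mutants leave growth
#'   unchanged).
#' @param scenarios subset of `c("WT", "OE", "UE")`.
#' @param flags hypothesis flags (default: KRP and SMR size-independent).
#' @param seed RNG seed (each scenario s uses `seed + its index - 1`).
#' @param ... passed to [simulate_population()].
#' @return A tibble with one row per scenario: `target`, `scenario`,
#'   `multiplier`, `n`, and quartiles (`q1_`, `median_`, `q3_`) of
#'   `V_g1s`, `g1_duration`, `V_div`, `cycle_duration`.
#' @export
mutant_experiment <- function(target = c("CDKA:CYCD", "CDKA/B:CYCB"),
                              params,
                              scenarios = c("WT", "OE", "UE"),
                              flags = hypothesis_flags(
                                size_independent = c("KRP", "SMR")),
                              seed = 1, ...) {
  target <- match.arg(target)
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  validate_parameters(params)
  rate_name <- if (target == "CDKA:CYCD") "r_ca" else "r_cb_e2fb"
  multipliers <- c(WT = 1, OE = 1.5, UE = 0.8)

  purrr::imap_dfr(setNames(scenarios, scenarios), function(sc, nm) {
    p <- params
    p[[rate_name]] <- p[[rate_name]] * multipliers[[sc]]
    pop <- simulate_population(p, flags,
                               seed = seed + which(scenarios == sc) - 1L,
                               ...)
    cc <- dplyr::filter(tibble::as_tibble(pop), .data$completed)
    qs <- function(x) quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    vq <- qs(cc$V_g1s)
    gq <- qs(cc$t_g1s - cc$t_birth)
    dq <- qs(cc$V_div)
    cq <- qs(cc$t_div - cc$t_birth)
    tibble::tibble(
      target = target, scenario = sc, multiplier = multipliers[[sc]],
      n = nrow(cc),
      q1_V_g1s = vq[1], median_V_g1s = vq[2], q3_V_g1s = vq[3],
      q1_g1_duration = gq[1], median_g1_duration = gq[2],
      q3_g1_duration = gq[3],
      q1_V_div = dq[1], median_V_div = dq[2], q3_V_div = dq[3],
      q1_cycle_duration = cq[1], median_cycle_duration = cq[2],
      q3_cycle_duration = cq[3]
    )
  })
}
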