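## Dispersion and regression statistics for size-control analysis.

#' Quartile coefficient of dispersion
#'
#' `(Q3 - Q1) / (Q3 + Q1)` with quartiles computed by linear interpolation of
#' order statistics (the default fractional-index convention of
#' [stats::quantile()], type 7).
#'
#' @param values numeric vector of at least 4 positive values.
#' @return The dispersion, in `[0, 1)`.  Scale-invariant: `qcd(c * x)` equals
#'   `qcd(x)` for any `c > 0`.
#' @examples
#' qcd(1:5)  # (4 - 2) / (4 + 2)
#' @export
qcd <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4) stop("qcd needs at least 4 values")
  if (anyNA(values) || any(values <= 0)) {
    stop("qcd needs positive, non-missing values")
  }
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  (q[2] - q[1]) / (q[2] + q[1])
}

#' Ordinary-least-squares slope
#'
#' The gradient of the line of best fit of `y` on `x`.
#'
#' @param x,y numeric vectors of equal length (>= 2), `x` non-constant.
#' @return The OLS slope.
#' @examples
#' fit_slope(c(1, 2, 3), c(0.5, 0.9, 1.2))
#' @export
fit_slope <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 points")
  if (diff(range(x)) == 0) stop("x is constant; slope undefined")
  unname(coef(lm(y ~ x))[2])
}

#' Cell-size dispersion at the cell-cycle checkpoints
#'
#' Quartile coefficients of dispersion of cell volume at birth, at the G1/S
#' transition and at the G2/M checkpoint, over all completed cells of a
#' population run, together with the stage-to-stage ratios.  Ratios below 1
#' indicate that the corresponding phase compresses size variation (size
#' control); a population with no size control leaves all three QCDs equal.
#'
#' @param population a `phyto_population` (full model or idealised; the
#'   idealised models only supply birth and division volumes, so the G1/S
#'   entries are `NA` there).
#' @param min_cells minimum number of completed cells required (default 4).
#' @return A one-row tibble: `n`, `qcd_birth`, `qcd_g1s`, `qcd_g2m`,
#'   `ratio_g1s_birth`, `ratio_g2m_g1s`, `ratio_g2m_birth`.
#' @export
dispersion_summary <- function(population, min_cells = 4) {
  cc <- dplyr::filter(tibble::as_tibble(population), .data$completed)
  if (nrow(cc) < min_cells) {
    stop("need at least ", min_cells, " completed cells; got ", nrow(cc))
  }
  has_g1s <- !all(is.na(cc$V_g1s))
  ## idealised populations carry no G1/S record; use division volume at G2/M
  v_g2m <- if (all(is.na(cc$V_g2m))) cc$V_div else cc$V_g2m
  qb <- qcd(cc$V_birth)
  qg <- if (has_g1s) qcd(cc$V_g1s) else NA_real_
  qm <- qcd(v_g2m)
  tibble::tibble(
    n = nrow(cc),
    qcd_birth = qb, qcd_g1s = qg, qcd_g2m = qm,
    ratio_g1s_birth = qg / qb,
    ratio_g2m_g1s = qm / qg,
    ratio_g2m_birth = qm / qb
  )
}

## The four standard hypothesis configurations for the dispersion table.
.dispersion_configs <- function() {
  list(
    "KRP SI, SMR SI" = hypothesis_flags(
      size_independent = c("KRP", "SMR")),
    "KRP Eq Inh, SMR SI" = hypothesis_flags(
      size_independent = "SMR", equal_inheritance = "KRP"),
    "KRP Eq Inh (PD), SMR SI" = hypothesis_flags(
      size_independent = "SMR", equal_inheritance = "KRP",
      krp_phase_dependent = TRUE),
    "KRP Eq Inh (PD), SMR SD" = hypothesis_flags(
      equal_inheritance = "KRP", krp_phase_dependent = TRUE)
  )
}

#' Dispersion table across the standard size-control hypotheses
#'
#' Runs [simulate_population()] for the four standard hypothesis
#' configurations (size-independent KRP and SMR; equally inherited KRP with
#' continual synthesis and size-independent SMR; equally inherited KRP with
#' phase-dependent synthesis and size-independent SMR; the same with fully
#' size-dependent SMR) and tabulates [dispersion_summary()] for each,
#' averaging over seeds.
#'
#' @param params a `phyto_params` vector with calibrated `r_gr`.
#' @param seeds integer vector of seeds; summaries are averaged across them.
#' @param sampler a [division_sampler()].
#' @param ... passed on to [simulate_population()].
#' @return A tibble with one row per hypothesis: `hypothesis`, `n`, the three
#'   QCDs and the three ratios (seed means).
#' @export
dispersion_panel <- function(params, seeds = 1:3,
                             sampler = division_sampler(), ...) {
  configs <- .dispersion_configs()
  purrr::imap_dfr(configs, function(flags, label) {
    per_seed <- purrr::map_dfr(seeds, function(s) {
      pop <- simulate_population(params, flags, sampler = sampler,
                                 seed = s, ...)
      dispersion_summary(pop)
    })
    dplyr::bind_cols(
      tibble::tibble(hypothesis = label),
      dplyr::summarise(per_seed,
                       n = sum(.data$n),
                       dplyr::across(dplyr::starts_with("qcd"), mean),
                       dplyr::across(dplyr::starts_with("ratio"), mean))
    )
  })
}
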