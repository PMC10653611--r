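## Limit-cycle detection at zero growth and one-at-a-time parameter
## robustness scanning.

#' Detect a limit cycle of the network at zero growth
#'
#' Integrates the network in a single non-growing compartment (`r_gr = 0`,
#' `V = 1`, so masses equal concentrations) from a generic positive state,
#' discards the first 40 % of the horizon as transient, and inspects the
#' CDKA/B:CYCB peaks: the system is declared cycling if at least three
#' successive peaks exceed an absolute amplitude floor and their
#' peak-to-peak intervals agree to within 5 %.  The period is the mean
#' interval.
#'
#' @param params a `phyto_params` vector (`r_gr` is overridden to 0).
#' @param flags a `phyto_hypothesis`.
#' @param horizon integration horizon (default 8000 time units, roughly
#'   eight default periods).
#' @param dt output grid spacing for peak detection.
#' @param floor absolute CDKA/B:CYCB amplitude floor for a countable peak.
#' @return A list: `cycling` (logical), `period` (`NA` if not cycling),
#'   `peaks` (peak times), `state_end` (final state, a point on the
#'   attractor when cycling), `diagnostic` (character).
#' @examples
#' \donttest{
#' limit_cycle_detect(default_parameters())$period
#' }
#' @export
limit_cycle_detect <- function(params, flags = hypothesis_flags(),
                               horizon = 8000, dt = 2, floor = 0.05) {
  validate_parameters(params)
  p <- params
  p[["r_gr"]] <- 0
  y0 <- cell_state(volume = 1,
                   masses = setNames(rep(0.1, 12), .phyto_proteins))
  tr <- tryCatch(
    .integrate_dense(y0, p, flags, seq(0, horizon, by = dt)),
    error = function(e) NULL
  )
  fail <- function(msg) list(cycling = FALSE, period = NA_real_,
                             peaks = numeric(0), state_end = NULL,
                             diagnostic = msg)
  if (is.null(tr) || !all(is.finite(tr$CDKB_CYCB))) {
    return(fail("integration failure"))
  }
  keep <- tr$time > 0.4 * horizon
  cb <- tr$CDKB_CYCB[keep]
  tt <- tr$time[keep]
  pk <- which(diff(sign(diff(cb))) == -2) + 1L
  pk <- pk[cb[pk] > floor]
  if (length(pk) < 3) return(fail("fewer than 3 peaks above floor"))
  gaps <- diff(tt[pk])
  if (max(gaps) / min(gaps) - 1 > 0.05) {
    return(fail("peak intervals not periodic within 5%"))
  }
  state_end <- setNames(as.numeric(tr[nrow(tr), 1 + seq_len(13)]),
                        .phyto_state_names())
  list(cycling = TRUE, period = mean(gaps), peaks = tt[pk],
       state_end = state_end, diagnostic = "ok")
}

#' One-at-a-time parameter robustness scan for limit cycles
#'
#' Varies each selected parameter over a log-spaced grid spanning
#' `[default / factor, default * factor]` while holding all others at their
#' defaults, and records whether [limit_cycle_detect()] still finds a limit
#' cycle at each grid point.
#'
#' @param params baseline `phyto_params` (must itself admit a limit cycle).
#' @param parameters character vector of parameter names to scan; defaults
#'   to every nonzero rate/affinity constant except `r_gr`.
#' @param factor fold-range of the scan (default 10).
#' @param n_grid grid points per parameter (odd values place the default on
#'   the grid; default 9).
#' @param ... passed to [limit_cycle_detect()].
#' @return A tibble of class `phyto_robustness`: `parameter`, `value`,
#'   `rel_value` (value / default), `cycling`, `period`.
#' @seealso [robustness_intervals()] for the per-parameter cycling interval
#'   containing the default.
#' @export
robustness_scan <- function(params, parameters = NULL, factor = 10,
                            n_grid = 9, ...) {
  validate_parameters(params)
  if (is.null(parameters)) {
    parameters <- setdiff(.phyto_param_order, "r_gr")
    parameters <- parameters[params[parameters] > 0]
  }
  bad <- setdiff(parameters, .phyto_param_order)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  out <- purrr::map_dfr(parameters, function(nm) {
    default <- params[[nm]]
    grid <- default * exp(seq(-log(factor), log(factor),
                              length.out = n_grid))
    purrr::map_dfr(grid, function(v) {
      p <- params
      p[[nm]] <- v
      lc <- limit_cycle_detect(p, ...)
      tibble::tibble(parameter = nm, value = v, rel_value = v / default,
                     cycling = lc$cycling, period = lc$period)
    })
  })
  structure(out, class = c("phyto_robustness", class(tibble::tibble())))
}

#' Cycling interval per parameter from a robustness scan
#'
#' For each scanned parameter, the contiguous run of grid points containing
#' the default value on which limit cycles persist.
#'
#' @param scan result of [robustness_scan()].
#' @return A tibble: `parameter`, `lower`, `upper` (interval endpoints in
#'   parameter units), `rel_lower`, `rel_upper` (relative to the default),
#'   `bounded_below`, `bounded_above` (whether cycling is lost inside the
#'   scanned range on either side).
#' @export
robustness_intervals <- function(scan) {
  scan |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$parameter) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$value)
      i0 <- which.min(abs(df$rel_value - 1))
      if (!df$cycling[i0]) {
        return(tibble::tibble(lower = NA_real_, upper = NA_real_,
                              rel_lower = NA_real_, rel_upper = NA_real_,
                              bounded_below = NA, bounded_above = NA))
      }
      lo <- i0
      while (lo > 1 && df$cycling[lo - 1]) lo <- lo - 1
      hi <- i0
      while (hi < nrow(df) && df$cycling[hi + 1]) hi <- hi + 1
      tibble::tibble(
        lower = df$value[lo], upper = df$value[hi],
        rel_lower = df$rel_value[lo], rel_upper = df$rel_value[hi],
        bounded_below = lo > 1, bounded_above = hi < nrow(df)
      )
    }) |>
    dplyr::ungroup()
}
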