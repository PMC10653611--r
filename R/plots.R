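## ggplot2 convenience layers.  Plotting is never on any analysis path.

#' Plot cell volumes of a population over time
#'
#' One horizontal segment per cell from birth to division (or to the stop
#' time for incomplete cells), on a log volume axis.
#'
#' @param population a `phyto_population`.
#' @return A ggplot object.
#' @export
plot_population <- function(population) {
  df <- tibble::as_tibble(population)
  df$t_end <- ifelse(df$completed, df$t_div, attr(population, "t_max"))
  df$V_end <- ifelse(df$completed, df$V_div,
                     df$V_birth)  # unknown growth end for incomplete cells
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$t_birth, xend = .data$t_end,
                   y = .data$V_birth, yend = .data$V_end,
                   colour = factor(.data$generation)),
      linewidth = 0.4, show.legend = FALSE
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (a.u.)", y = "cell volume (a.u.)")
}

#' @export
autoplot.phyto_population <- function(object, ...) plot_population(object)

#' Birth-volume versus added-volume scatter
#'
#' The classic size-control diagnostic: added volume over one cycle (or one
#' phase) against volume at the start.  A gradient of -1 is a perfect sizer,
#' 0 an adder; positive gradients imply no size control.
#'
#' @param population a `phyto_population`.
#' @param phase `"cycle"` (birth to division), `"g1"` (birth to G1/S) or
#'   `"g2m"` (G1/S to the G2/M checkpoint).
#' @return A ggplot object with an OLS trend line.
#' @export
plot_added_volume <- function(population,
                              phase = c("cycle", "g1", "g2m")) {
  phase <- match.arg(phase)
  cc <- dplyr::filter(tibble::as_tibble(population), .data$completed)
  df <- switch(phase,
    cycle = tibble::tibble(x = cc$V_birth, y = cc$V_div - cc$V_birth),
    g1 = tibble::tibble(x = cc$V_birth, y = cc$V_g1s - cc$V_birth),
    g2m = tibble::tibble(x = cc$V_g1s, y = cc$V_g2m - cc$V_g1s)
  )
  xlab <- if (phase == "g2m") "volume at G1/S (a.u.)" else
    "volume at birth (a.u.)"
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = xlab, y = "added volume (a.u.)")
}

#' Plot a recorded single-cell trajectory
#'
#' Concentration time courses (mass / volume) of selected species.
#'
#' @param cycle a `phyto_cycle` from `run_cycle(record = TRUE)`.
#' @param species character vector of state or algebraic-layer columns.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(cycle,
                            species = c("CDKA_CYCD", "KRP", "CDKB_CYCB",
                                        "SMR", "MYB3R4_p", "E2FA_free")) {
  if (is.null(cycle$trajectory)) {
    stop("no trajectory recorded; rerun run_cycle() with record = TRUE")
  }
  tr <- cycle$trajectory
  bad <- setdiff(species, names(tr))
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  long <- tr |>
    dplyr::mutate(dplyr::across(dplyr::all_of(species), ~ .x / tr$V)) |>
    dplyr::select(dplyr::all_of(c("time", species))) |>
    tidyr::pivot_longer(-"time", names_to = "species",
                        values_to = "concentration")
  ggplot2::ggplot(long,
                  ggplot2::aes(.data$time, .data$concentration,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (a.u.)", y = "concentration (a.u.)")
}

#' @export
autoplot.phyto_cycle <- function(object, ...) plot_trajectory(object, ...)

#' Plot a bifurcation diagram
#'
#' Steady-state reporter value against the clamped control concentration;
#' stable branches as solid points, unstable as open; folds as dashed
#' vertical lines.
#'
#' @param scan a `phyto_bifurcation` from [bifurcation_scan()].
#' @return A ggplot object.
#' @export
plot_bifurcation <- function(scan) {
  df <- dplyr::filter(tibble::as_tibble(scan), !is.na(.data$value))
  folds <- attr(scan, "folds")
  gg <- ggplot2::ggplot(df,
                        ggplot2::aes(.data$control, .data$value,
                                     shape = .data$stable)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                labels = c(`TRUE` = "stable",
                                           `FALSE` = "unstable"),
                                name = NULL) +
    ggplot2::labs(x = "clamped kinase-cyclin concentration (a.u.)",
                  y = paste0(df$reporter[1], " steady state (a.u.)"))
  if (length(folds)) {
    gg <- gg + ggplot2::geom_vline(xintercept = folds, linetype = "dashed",
                                   linewidth = 0.3)
  }
  gg
}

#' @export
autoplot.phyto_bifurcation <- function(object, ...) plot_bifurcation(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
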