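## Steady-state analysis of the isolated checkpoint switches: multi-root
## location along a 1-D skeleton, stability by linearisation, and
## saddle-node (fold) localisation from branch-count changes.

## --- reduced right-hand sides (fixed volume, no growth) -------------------

## G1/S subsystem: CDKA:CYCD_T clamped; CYCB, MYB3R3/4, SMR, SCF, APC zeroed.
## States: KRP, E2FA, E2FB, RBR, FBL17 (masses at fixed V).
.g1s_rhs <- function(y, ca_total, params, V) {
  p <- params
  krp <- max(y[1], 0); e2fa_t <- max(y[2], 0); e2fb <- max(y[3], 0)
  rbr_t <- max(y[4], 0); fbl <- max(y[5], 0)
  ca <- ca_total - qss_complex(ca_total, krp, V, p[["kD_ca_krp"]])
  rbr_u <- rbr_t - phospho_fraction(ca, p[["kdp_ca"]], V) * rbr_t
  e2fa <- e2fa_t - qss_complex(e2fa_t, rbr_u, V, p[["kD_e2fa_rbr"]])
  c(
    (p[["r_krp"]]) * V -  # MYB3R4 is absent from this subsystem
      (p[["d_krp"]] + p[["d_krp_fbl17"]] * fbl / V) * krp,
    p[["r_e2fa"]] * V - p[["d_e2fa"]] * e2fa_t,
    regulated_synthesis(p[["r_e2fb"]], p[["r_e2fb_e2fa"]], e2fa,
                        p[["kat_e2fa"]], V) - p[["d_e2fb"]] * e2fb,
    p[["r_rbr"]] * V - p[["d_rbr"]] * rbr_t,
    regulated_synthesis(p[["r_fbl17"]], p[["r_fbl17_e2fa"]], e2fa,
                        p[["kat_e2fa"]], V) - p[["d_fbl17"]] * fbl
  )
}

## G2/M subsystem: CDKA/B:CYCB_T clamped; G1/S species and SCF/APC zeroed.
## States: MYB3R3, MYB3R4, SMR.
.g2m_rhs <- function(y, cb_total, params, V) {
  p <- params
  myb3 <- max(y[1], 0); myb4 <- max(y[2], 0); smr <- max(y[3], 0)
  cb <- cb_total - qss_complex(cb_total, smr, V, p[["kD_cb_smr"]])
  myb4_p <- phospho_fraction(cb, p[["kdp_cb1"]], V) * myb4
  smr_p <- phospho_fraction(cb, p[["kdp_cb2"]], V) * smr
  c(
    p[["r_myb3"]] * V - p[["d_myb3"]] * myb3,
    regulated_synthesis(p[["r_myb4"]], p[["r_myb4_myb4"]], myb4_p,
                        p[["kat_myb4"]], V) - p[["d_myb4"]] * myb4,
    p[["r_smr"]] * V - p[["d_smr"]] * (smr - smr_p) -
      p[["d_smr_cdkb"]] * smr_p
  )
}

## SMR-free G2/M submodel: only MYB3R3 interacting with clamped CYCB.
.g2m_nosmr_rhs <- function(y, cb_total, params, V) {
  p <- params
  myb3 <- max(y[1], 0)
  p[["r_myb3"]] * V - p[["d_myb3"]] * myb3
}

## --- 1-D root scanning helpers --------------------------------------------

## All sign-change roots of f over a log-spaced grid on [lo, hi],
## deduplicated at tol.
.scan_roots <- function(f, lo, hi, n = 400, tol = 1e-6) {
  xs <- exp(seq(log(lo), log(hi), length.out = n))
  fs <- vapply(xs, f, numeric(1))
  idx <- which(diff(sign(fs)) != 0 & is.finite(fs[-length(fs)]) &
                 is.finite(fs[-1]))
  roots <- vapply(idx, function(i) {
    uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-12)$root
  }, numeric(1))
  if (!length(roots)) return(numeric(0))
  roots <- sort(roots)
  roots[c(TRUE, diff(roots) > tol * pmax(roots[-length(roots)], 1))]
}

## Numeric Jacobian (central differences) of rhs(y) at y.
.num_jacobian <- function(rhs, y, eps = 1e-7) {
  n <- length(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- eps * max(abs(y[j]), 1)
    yp <- y; yp[j] <- yp[j] + h
    ym <- y; ym[j] <- ym[j] - h
    J[, j] <- (rhs(yp) - rhs(ym)) / (2 * h)
  }
  J
}

.is_stable <- function(J) max(Re(eigen(J, only.values = TRUE)$values)) < 0

## --- public scan -----------------------------------------------------------

#' Bifurcation scan of an isolated checkpoint subsystem
#'
#' Computes all steady states of a reduced checkpoint subsystem as a function
#' of a clamped total kinase-cyclin concentration, classifies their stability
#' by linearisation, and reports saddle-node folds where the number of
#' steady states changes.
#'
#' Subsystems (all other species clamped to zero, volume fixed at `volume`):
#' \describe{
#'   \item{`"g1s"`}{control = total CDKA:CYCD concentration; states KRP,
#'     E2FA, E2FB, RBR, FBL17; reporter = KRP.  The KRP-high branch is
#'     eliminated in a saddle-node as the control rises: the G1/S switch.}
#'   \item{`"g2m"`}{control = total CDKA/B:CYCB concentration; states
#'     MYB3R3, MYB3R4, SMR; reporter = SMR.  Bistable through the
#'     SMR-phosphorylation/degradation feedback.}
#'   \item{`"g2m_nosmr"`}{the SMR-free submodel (SMR synthesis prohibited):
#'     MYB3R3 against clamped CDKA/B:CYCB; reporter = unphosphorylated
#'     MYB3R3.  Monostable: mutual inhibition alone does not make a switch.}
#' }
#'
#' Steady states are found by scanning the 1-D self-consistency residual of
#' the feedback variable on a log-spaced grid (the remaining states are
#' explicit functions of it at steady state) and refining each sign change
#' with [stats::uniroot()]; the full reduced Jacobian determines stability.
#' The clamped control is the total, not the free, kinase concentration:
#' clamping the free form would sever the inhibitor-sequestration feedback
#' that creates the bistability.
#'
#' @param subsystem `"g1s"`, `"g2m"` or `"g2m_nosmr"`.
#' @param control numeric vector of clamped total kinase concentrations.
#' @param params a `phyto_params` vector.
#' @param volume fixed cell volume (default 1, so mass equals concentration).
#' @return A tibble of class `phyto_bifurcation` with columns `control`,
#'   `reporter` (name), `value` (steady-state reporter mass), `stable`,
#'   and one column per reduced state; attribute `folds` holds the control
#'   values (interval midpoints) where the branch count changes.
#' @examples
#' \donttest{
#' scan <- bifurcation_scan("g2m", seq(0.1, 1.5, by = 0.05),
#'                          default_parameters())
#' attr(scan, "folds")
#' }
#' @export
bifurcation_scan <- function(subsystem = c("g1s", "g2m", "g2m_nosmr"),
                             control, params, volume = 1) {
  subsystem <- match.arg(subsystem)
  validate_parameters(params)
  stopifnot(is.numeric(control), all(control >= 0), volume > 0)
  p <- params
  V <- volume

  states_of <- switch(subsystem,
    g1s = function(c_tot) {
      ca_total <- c_tot * V
      e2fa_t <- p[["r_e2fa"]] / p[["d_e2fa"]] * V
      rbr_t <- p[["r_rbr"]] / p[["d_rbr"]] * V
      resid <- function(K) {
        ca <- ca_total - qss_complex(ca_total, K, V, p[["kD_ca_krp"]])
        rbr_u <- rbr_t - phospho_fraction(ca, p[["kdp_ca"]], V) * rbr_t
        e2fa <- e2fa_t - qss_complex(e2fa_t, rbr_u, V, p[["kD_e2fa_rbr"]])
        fbl <- regulated_synthesis(p[["r_fbl17"]], p[["r_fbl17_e2fa"]],
                                   e2fa, p[["kat_e2fa"]], V) / p[["d_fbl17"]]
        p[["r_krp"]] * V -
          (p[["d_krp"]] + p[["d_krp_fbl17"]] * fbl / V) * K
      }
      roots <- .scan_roots(resid, 1e-5 * V, 50 * V)
      lapply(roots, function(K) {
        ca <- ca_total - qss_complex(ca_total, K, V, p[["kD_ca_krp"]])
        rbr_u <- rbr_t - phospho_fraction(ca, p[["kdp_ca"]], V) * rbr_t
        e2fa <- e2fa_t - qss_complex(e2fa_t, rbr_u, V, p[["kD_e2fa_rbr"]])
        fbl <- regulated_synthesis(p[["r_fbl17"]], p[["r_fbl17_e2fa"]],
                                   e2fa, p[["kat_e2fa"]], V) / p[["d_fbl17"]]
        e2fb <- regulated_synthesis(p[["r_e2fb"]], p[["r_e2fb_e2fa"]],
                                    e2fa, p[["kat_e2fa"]], V) / p[["d_e2fb"]]
        y <- c(KRP = K, E2FA = e2fa_t, E2FB = e2fb, RBR = rbr_t,
               FBL17 = fbl)
        J <- .num_jacobian(function(z) .g1s_rhs(z, ca_total, p, V), y)
        list(y = y, reporter = K, stable = .is_stable(J))
      })
    },
    g2m = function(c_tot) {
      cb_total <- c_tot * V
      myb3 <- p[["r_myb3"]] / p[["d_myb3"]] * V
      smr_resid <- function(S) {
        cb <- cb_total - qss_complex(cb_total, S, V, p[["kD_cb_smr"]])
        sp <- phospho_fraction(cb, p[["kdp_cb2"]], V) * S
        p[["r_smr"]] * V - p[["d_smr"]] * (S - sp) - p[["d_smr_cdkb"]] * sp
      }
      s_roots <- .scan_roots(smr_resid, 1e-5 * V, 50 * V)
      out <- list()
      for (S in s_roots) {
        cb <- cb_total - qss_complex(cb_total, S, V, p[["kD_cb_smr"]])
        frac4 <- phospho_fraction(cb, p[["kdp_cb1"]], V)
        m_resid <- function(m) {
          regulated_synthesis(p[["r_myb4"]], p[["r_myb4_myb4"]],
                              frac4 * m, p[["kat_myb4"]], V) -
            p[["d_myb4"]] * m
        }
        m_roots <- .scan_roots(m_resid, 1e-4 * V, 1e4 * V)
        for (m in m_roots) {
          y <- c(MYB3R3 = myb3, MYB3R4 = m, SMR = S)
          J <- .num_jacobian(function(z) .g2m_rhs(z, cb_total, p, V), y)
          out[[length(out) + 1L]] <-
            list(y = y, reporter = S, stable = .is_stable(J))
        }
      }
      out
    },
    g2m_nosmr = function(c_tot) {
      cb_total <- c_tot * V
      myb3 <- p[["r_myb3"]] / p[["d_myb3"]] * V
      myb3_u <- myb3 - phospho_fraction(cb_total, p[["kdp_cb"]], V) * myb3
      y <- c(MYB3R3 = myb3)
      J <- .num_jacobian(function(z) .g2m_nosmr_rhs(z, cb_total, p, V), y)
      list(list(y = c(y, MYB3R3_u = myb3_u), reporter = myb3_u,
                stable = .is_stable(J)))
    }
  )

  reporter_name <- switch(subsystem, g1s = "KRP", g2m = "SMR",
                          g2m_nosmr = "MYB3R3_u")
  rows <- purrr::map_dfr(control, function(c_tot) {
    sts <- states_of(c_tot)
    if (!length(sts)) {
      return(tibble::tibble(control = c_tot, reporter = reporter_name,
                            value = NA_real_, stable = NA))
    }
    purrr::map_dfr(sts, function(st) {
      dplyr::bind_cols(
        tibble::tibble(control = c_tot, reporter = reporter_name,
                       value = st$reporter, stable = st$stable),
        tibble::as_tibble(as.list(st$y))
      )
    })
  })

  counts <- vapply(control, function(c_tot) {
    sum(!is.na(rows$value[rows$control == c_tot]))
  }, numeric(1))
  change <- which(diff(counts) != 0)
  folds <- (control[change] + control[change + 1]) / 2

  structure(rows,
            class = c("phyto_bifurcation", class(tibble::tibble())),
            subsystem = subsystem, volume = V, folds = folds,
            n_states = setNames(counts, control))
}

#' Count of coexisting stable states per control value
#'
#' @param scan a `phyto_bifurcation` from [bifurcation_scan()].
#' @return A tibble: `control`, `n_steady`, `n_stable`.
#' @export
branch_counts <- function(scan) {
  tibble::as_tibble(scan) |>
    dplyr::group_by(.data$control) |>
    dplyr::summarise(
      n_steady = sum(!is.na(.data$value)),
      n_stable = sum(.data$stable %in% TRUE)
    )
}
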