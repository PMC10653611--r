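## The network core: state constructor, quasi-steady-state algebra, and a
## reference R implementation of the ODE right-hand side.  Production
## integration uses the identical compiled version in src/cycle.c.

#' Construct a cell state
#'
#' A cell state is the cell volume plus the total mass of each of the twelve
#' tracked proteins.  All equations of the model are written in terms of
#' protein *mass* (not concentration) because volume itself is dynamic;
#' concentrations are mass / volume.
#'
#' @param volume cell volume (> 0).
#' @param ... named protein masses (>= 0).  Unnamed proteins default to 0.
#'   Valid names: `CDKA_CYCD`, `KRP`, `E2FA`, `E2FB`, `RBR`, `FBL17`,
#'   `CDKB_CYCB`, `MYB3R3`, `MYB3R4`, `SMR`, `SCF`, `APC`.
#' @param masses optionally, a full named vector of the twelve masses
#'   (overridden by `...`).
#' @return A named numeric vector of class `phyto_state`:
#'   `c(V, <12 protein masses>)`.
#' @examples
#' cell_state(volume = 1, KRP = 0.2, RBR = 1)
#' @export
cell_state <- function(volume = 1, ..., masses = NULL) {
  m <- setNames(numeric(length(.phyto_proteins)), .phyto_proteins)
  if (!is.null(masses)) {
    bad <- setdiff(names(masses), .phyto_proteins)
    if (length(bad)) stop("unknown protein(s): ", paste(bad, collapse = ", "))
    m[names(masses)] <- as.numeric(masses)
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .phyto_proteins)
    if (length(bad)) stop("unknown protein(s): ", paste(bad, collapse = ", "))
    m[names(dots)] <- as.numeric(unlist(dots))
  }
  s <- c(V = as.numeric(volume), m)
  validate_state(s)
  structure(s, class = c("phyto_state", "numeric"))
}

#' Validate a cell state
#'
#' @param state named numeric vector `c(V, <protein masses>)`.
#' @return `state`, invisibly.
#' @export
validate_state <- function(state) {
  need <- c("V", .phyto_proteins)
  missing <- setdiff(need, names(state))
  if (length(missing)) {
    stop("state is missing: ", paste(missing, collapse = ", "))
  }
  if (!all(is.finite(state[need]))) stop("state must be finite")
  if (state[["V"]] <= 0) stop("volume must be positive")
  if (any(state[.phyto_proteins] < 0)) {
    stop("negative mass for: ",
         paste(.phyto_proteins[state[.phyto_proteins] < 0], collapse = ", "))
  }
  invisible(state)
}

#' Mass of a reversible binding complex at quasi-steady state
#'
#' For two proteins with total masses `A_total` and `B_total` binding
#' reversibly in a cell of volume `volume` with dissociation constant `kD`
#' (dissociation rate over association rate), the complex mass at equilibrium
#' is the smaller root of the mass-action quadratic
#' \deqn{C^2 - (A_T + B_T + k_D V) C + A_T B_T = 0,}
#' evaluated here in the cancellation-free form
#' `2 A_T B_T / (s + sqrt(s^2 - 4 A_T B_T))` with `s = A_T + B_T + kD V`.
#'
#' @param A_total,B_total total masses of the two partners (>= 0).
#' @param volume cell volume (> 0).
#' @param kD dissociation constant (>= 0); `kD = 0` binds everything.
#' @return Complex mass, in `[0, min(A_total, B_total)]`.  Vectorised.
#' @examples
#' qss_complex(1, 1, 1, 1)  # (3 - sqrt(5)) / 2
#' @export
qss_complex <- function(A_total, B_total, volume, kD) {
  n <- max(length(A_total), length(B_total), length(volume), length(kD))
  A <- rep_len(A_total, n); B <- rep_len(B_total, n)
  V <- rep_len(volume, n); k <- rep_len(kD, n)
  if (any(A < 0) || any(B < 0) || any(k < 0)) {
    stop("qss_complex: masses and kD must be non-negative")
  }
  if (any(V <= 0)) stop("qss_complex: volume must be positive")
  s <- A + B + k * V
  disc <- pmax(s * s - 4 * A * B, 0)
  out <- ifelse(A * B > 0, 2 * A * B / (s + sqrt(disc)), 0)
  pmin(out, pmin(A, B))
}

#' Phosphorylated fraction of a substrate at quasi-steady state
#'
#' With kinase mass `kinase` acting on a substrate in a cell of volume
#' `volume`, the phosphorylated share of the substrate is
#' `A / (A + kdp * volume)`, i.e. a saturating function of the kinase
#' *concentration* with half-saturation constant `kdp`.
#'
#' @param kinase kinase mass (>= 0).
#' @param kdp phosphatase/kinase balance constant (>= 0).
#' @param volume cell volume (> 0).
#' @return Fraction in `[0, 1]`; monotone increasing in `kinase`, decreasing
#'   in `volume`.  Vectorised.
#' @examples
#' phospho_fraction(1, kdp = 0.25, volume = 4)  # half saturation
#' @export
phospho_fraction <- function(kinase, kdp, volume) {
  n <- max(length(kinase), length(kdp), length(volume))
  A <- rep_len(kinase, n); k <- rep_len(kdp, n); V <- rep_len(volume, n)
  if (any(A < 0) || any(k < 0)) {
    stop("phospho_fraction: kinase and kdp must be non-negative")
  }
  if (any(V <= 0)) stop("phospho_fraction: volume must be positive")
  ifelse(A > 0, A / (A + k * V), 0)
}

#' Transcriptionally regulated synthesis rate
#'
#' Synthesis with a basal term plus a saturating activator-driven term,
#' multiplied by the size-dependence indicator: the rate is
#' `(base_rate + induced_rate * A / (kat * A + V)) * 1(V)` with
#' `1(V) = V` for a size-dependent gene and `1` for a size-independent one.
#' Note the saturating term uses the activator *mass* with the volume in the
#' denominator, so it saturates in the activator concentration.
#'
#' @param base_rate,induced_rate basal and activator-driven rate constants.
#' @param activator activator mass (>= 0).
#' @param kat saturation constant (>= 0).
#' @param volume cell volume (> 0).
#' @param size_dependent logical; if `TRUE` the rate scales with volume.
#' @return Synthesis rate (mass/time).  Vectorised.
#' @examples
#' regulated_synthesis(0.01, 0, 0, 0.001, volume = 2, size_dependent = TRUE)
#' @export
regulated_synthesis <- function(base_rate, induced_rate, activator, kat,
                                volume, size_dependent = TRUE) {
  if (any(base_rate < 0) || any(induced_rate < 0) || any(activator < 0) ||
      any(kat < 0)) {
    stop("regulated_synthesis: inputs must be non-negative")
  }
  if (any(volume <= 0)) stop("regulated_synthesis: volume must be positive")
  sat <- ifelse(activator > 0, activator / (kat * activator + volume), 0)
  (base_rate + induced_rate * sat) * ifelse(size_dependent, volume, 1)
}

## Algebraic layer for one state vector (numeric, unclassed); returns the 13
## quasi-steady-state quantities in .phyto_algebraic order.
.algebraic_one <- function(s, p) {
  V <- s[["V"]]
  pos <- function(x) max(x, 0)
  ca_krp <- qss_complex(pos(s[["CDKA_CYCD"]]), pos(s[["KRP"]]), V, p[["kD_ca_krp"]])
  ca <- pos(s[["CDKA_CYCD"]]) - ca_krp
  rbr_p <- phospho_fraction(ca, p[["kdp_ca"]], V) * pos(s[["RBR"]])
  rbr_u <- pos(s[["RBR"]]) - rbr_p
  e2fa_rbr <- qss_complex(pos(s[["E2FA"]]), rbr_u, V, p[["kD_e2fa_rbr"]])
  e2fa <- pos(s[["E2FA"]]) - e2fa_rbr
  cb_smr <- qss_complex(pos(s[["CDKB_CYCB"]]), pos(s[["SMR"]]), V, p[["kD_cb_smr"]])
  cb <- pos(s[["CDKB_CYCB"]]) - cb_smr
  myb3_p <- phospho_fraction(cb, p[["kdp_cb"]], V) * pos(s[["MYB3R3"]])
  myb3_u <- pos(s[["MYB3R3"]]) - myb3_p
  myb4_p <- phospho_fraction(cb, p[["kdp_cb1"]], V) * pos(s[["MYB3R4"]])
  smr_p <- phospho_fraction(cb, p[["kdp_cb2"]], V) * pos(s[["SMR"]])
  smr_u <- pos(s[["SMR"]]) - smr_p
  setNames(
    c(ca_krp, ca, rbr_p, rbr_u, e2fa_rbr, e2fa, cb_smr, cb,
      myb3_p, myb3_u, myb4_p, smr_p, smr_u),
    .phyto_algebraic
  )
}

#' Quasi-steady-state algebraic layer
#'
#' Resolves the fast binding and phosphorylation reactions at a given state:
#' the CDKA:CYCD-KRP and CDKA/B:CYCB-SMR inhibitory complexes, the E2FA-RBR
#' repressor complex (with unphosphorylated RBR), and the phosphorylated and
#' unphosphorylated shares of RBR, MYB3R3, MYB3R4 and SMR.  Conservation
#' holds exactly: every complex is bounded by both partner totals, and
#' free + complexed (or phospho + unphospho) equals the total.
#'
#' @param state a `phyto_state`, or a data frame / matrix with columns
#'   `V` and the twelve protein masses (one row per state).
#' @param params a `phyto_params` vector.
#' @return A tibble with one row per state and the 13 algebraic quantities:
#'   `CDKA_CYCD_KRP`, `CDKA_CYCD_free`, `RBR_p`, `RBR_u`, `E2FA_RBR`,
#'   `E2FA_free`, `CDKB_CYCB_SMR`, `CDKB_CYCB_free`, `MYB3R3_p`, `MYB3R3_u`,
#'   `MYB3R4_p`, `SMR_p`, `SMR_u`.
#' @examples
#' algebraic_state(cell_state(1, CDKA_CYCD = 1, KRP = 1), default_parameters())
#' @export
algebraic_state <- function(state, params) {
  validate_parameters(params)
  if (is.numeric(state) && !is.matrix(state)) {
    validate_state(state)
    return(tibble::as_tibble(as.list(.algebraic_one(state, params))))
  }
  df <- as.data.frame(state)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    s <- setNames(as.numeric(df[i, c("V", .phyto_proteins)]),
                  c("V", .phyto_proteins))
    .algebraic_one(s, params)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Right-hand side of the cell-cycle ODE system (reference implementation)
#'
#' Time derivatives of volume and the twelve protein masses.  Volume grows
#' exponentially at rate `r_gr`; size-dependent synthesis scales with `V`;
#' mediated degradation terms use mass/volume concentrations of the mediator
#' and act on the total mass of the target; SMR loses unphosphorylated mass
#' at `d_smr` and phosphorylated mass at `d_smr_cdkb`; CDKA/B:CYCB synthesis
#' is repressed by unphosphorylated MYB3R3 through the `kI_myb3` term in the
#' saturating denominator.
#'
#' This R implementation defines the model; the compiled version used for
#' integration is checked against it in the test suite.  The signature is
#' deSolve-compatible.
#'
#' @param time time (unused; the system is autonomous).
#' @param state a `phyto_state` (or plain named numeric vector).
#' @param params a `phyto_params` vector.
#' @param flags a `phyto_hypothesis` (size-independence and phase-dependent
#'   KRP are applied here; inheritance flags only matter at division).
#' @return A list whose first element is the derivative vector (same order as
#'   the state) and whose second element is the named algebraic layer.
#' @export
cycle_rhs <- function(time, state, params, flags = hypothesis_flags()) {
  if (!all(is.finite(state))) stop("cycle_rhs: non-finite state")
  p <- .apply_hypothesis_params(params, flags)
  s <- setNames(as.numeric(state[c("V", .phyto_proteins)]),
                c("V", .phyto_proteins))
  V <- s[["V"]]
  a <- .algebraic_one(s, p)
  si <- flags$size_independent
  ind <- function(prot) if (prot %in% si) 1 else V
  conc <- function(x) x / V

  d <- c(
    V = p[["r_gr"]] * V,
    CDKA_CYCD = p[["r_ca"]] * V -
      (p[["d_ca"]] + p[["d_ca_scf"]] * conc(s[["SCF"]]) +
         p[["d_ca_apc"]] * conc(s[["APC"]])) * s[["CDKA_CYCD"]],
    KRP = regulated_synthesis(p[["r_krp"]], p[["r_krp_myb4"]],
                              a[["MYB3R4_p"]], p[["kat_myb4"]], V,
                              size_dependent = FALSE) * ind("KRP") -
      (p[["d_krp"]] + p[["d_krp_fbl17"]] * conc(s[["FBL17"]])) * s[["KRP"]],
    E2FA = p[["r_e2fa"]] * V - p[["d_e2fa"]] * s[["E2FA"]],
    E2FB = regulated_synthesis(p[["r_e2fb"]], p[["r_e2fb_e2fa"]],
                               a[["E2FA_free"]], p[["kat_e2fa"]], V) -
      p[["d_e2fb"]] * s[["E2FB"]],
    RBR = p[["r_rbr"]] * ind("RBR") - p[["d_rbr"]] * s[["RBR"]],
    FBL17 = regulated_synthesis(p[["r_fbl17"]], p[["r_fbl17_e2fa"]],
                                a[["E2FA_free"]], p[["kat_e2fa"]], V) -
      p[["d_fbl17"]] * s[["FBL17"]],
    CDKB_CYCB = (p[["r_cb"]] + p[["r_cb_e2fb"]] * s[["E2FB"]] /
                   (p[["kat_e2fb"]] * s[["E2FB"]] + V +
                      p[["kI_myb3"]] * a[["MYB3R3_u"]])) * V -
      (p[["d_cb"]] + p[["d_cb_apc"]] * conc(s[["APC"]])) * s[["CDKB_CYCB"]],
    MYB3R3 = p[["r_myb3"]] * ind("MYB3R3") - p[["d_myb3"]] * s[["MYB3R3"]],
    MYB3R4 = regulated_synthesis(p[["r_myb4"]], p[["r_myb4_myb4"]],
                                 a[["MYB3R4_p"]], p[["kat_myb4"]], V) -
      p[["d_myb4"]] * s[["MYB3R4"]],
    SMR = p[["r_smr"]] * ind("SMR") - p[["d_smr"]] * a[["SMR_u"]] -
      p[["d_smr_cdkb"]] * a[["SMR_p"]],
    SCF = regulated_synthesis(p[["r_scf"]], p[["r_scf_e2fb"]],
                              s[["E2FB"]], p[["kat_e2fb"]], V) -
      p[["d_scf"]] * s[["SCF"]],
    APC = regulated_synthesis(p[["r_apc"]], p[["r_apc_myb4"]],
                              a[["MYB3R4_p"]], p[["kat_myb4"]], V) -
      p[["d_apc"]] * s[["APC"]]
  )
  list(unname(d), a)
}
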