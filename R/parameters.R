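## Parameter-set handling: defaults, validation, hypothesis flags, file I/O.

## Order must match the compiled right-hand side (src/cycle.c) exactly.
.phyto_param_order <- c(
  "r_gr",
  "r_ca", "d_ca", "d_ca_scf", "d_ca_apc", "kD_ca_krp",
  "r_krp", "r_krp_myb4", "d_krp", "d_krp_fbl17",
  "r_e2fa", "d_e2fa", "kD_e2fa_rbr", "kat_e2fa",
  "r_e2fb", "r_e2fb_e2fa", "d_e2fb",
  "r_rbr", "d_rbr", "kdp_ca",
  "r_fbl17", "r_fbl17_e2fa", "d_fbl17",
  "r_cb", "r_cb_e2fb", "kI_myb3", "kat_e2fb", "d_cb", "d_cb_apc", "kD_cb_smr",
  "r_myb3", "d_myb3", "kdp_cb",
  "r_myb4", "r_myb4_myb4", "kat_myb4", "d_myb4", "kdp_cb1",
  "r_smr", "d_smr", "d_smr_cdkb", "kdp_cb2",
  "r_scf", "r_scf_e2fb", "d_scf",
  "r_apc", "r_apc_myb4", "d_apc"
)

## Proteins whose synthesis may be switched to size-independent mode.
.phyto_si_candidates <- c("KRP", "RBR", "MYB3R3", "SMR")

#' Default parameter set of the cell-cycle network
#'
#' Returns the rate, affinity and phosphorylation constants of the network
#' model, together with the relative volume growth rate `r_gr`.  Time, volume
#' and protein mass are all in arbitrary units; first-order rates have unit
#' 1/time.
#'
#' The shipped `r_gr` is the value produced by [calibrate_growth_rate()] for
#' this parameter set (cells double in volume over one limit-cycle period);
#' it can be recomputed at any time.  See the package vignette for the
#' provenance of every constant, including the two saturation constants and
#' one phosphorylation constant that are filled in by analogy, and the E2FA
#' synthesis rate, which is set so that total E2FA stays sub-stoichiometric
#' to its inhibitor RBR -- the regime in which both checkpoint switches are
#' bistable and size control operates.
#'
#' @param ... named overrides, e.g. `default_parameters(r_ca = 0.02)`.
#' @return A named numeric vector of class `phyto_params`.
#' @examples
#' p <- default_parameters()
#' p[["r_ca"]]
#' @export
default_parameters <- function(...) {
  p <- c(
    r_gr = 6.5e-04,
    ## CDKA:CYCD: basal synthesis, basal/SCF/APC-mediated decay, KRP affinity
    r_ca = 0.01, d_ca = 0.01, d_ca_scf = 0.0, d_ca_apc = 0.5, kD_ca_krp = 0.01,
    ## KRP: basal + MYB3R4-driven synthesis, basal + FBL17-mediated decay
    r_krp = 0.01, r_krp_myb4 = 0.01, d_krp = 0.01, d_krp_fbl17 = 1,
    ## E2FA (sub-stoichiometric to RBR; see vignette) and its RBR affinity
    r_e2fa = 0.006, d_e2fa = 0.01, kD_e2fa_rbr = 0.001, kat_e2fa = 0.001,
    ## E2FB, induced by free E2FA
    r_e2fb = 0, r_e2fb_e2fa = 0.01, d_e2fb = 0.01,
    ## RBR and its phosphorylation constant (by free CDKA:CYCD)
    r_rbr = 0.01, d_rbr = 0.01, kdp_ca = 0.25,
    ## FBL17, induced by free E2FA
    r_fbl17 = 0, r_fbl17_e2fa = 0.1, d_fbl17 = 0.1,
    ## CDKA/B:CYCB: E2FB-driven synthesis repressed by MYB3R3, APC decay
    r_cb = 0, r_cb_e2fb = 0.3, kI_myb3 = 10, kat_e2fb = 0.001,
    d_cb = 0.01, d_cb_apc = 0.1, kD_cb_smr = 0.001,
    ## MYB3R3 and its phosphorylation constant (by free CDKA/B:CYCB)
    r_myb3 = 0.01, d_myb3 = 0.01, kdp_cb = 0.125,
    ## MYB3R4: autoactivating, phosphorylation constant kdp_cb1
    r_myb4 = 0.01, r_myb4_myb4 = 0.11, kat_myb4 = 0.001, d_myb4 = 0.1,
    kdp_cb1 = 0.125,
    ## SMR: unphosphorylated decays slowly, phosphorylated quickly
    r_smr = 0.01, d_smr = 0.01, d_smr_cdkb = 0.1, kdp_cb2 = 0.25,
    ## ubiquitin ligases
    r_scf = 0, r_scf_e2fb = 0.01, d_scf = 0.01,
    r_apc = 0, r_apc_myb4 = 0.01, d_apc = 0.01
  )
  stopifnot(identical(names(p), .phyto_param_order))
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    }
    p[names(ov)] <- as.numeric(unlist(ov))
  }
  validate_parameters(p)
  structure(p, class = c("phyto_params", "numeric"))
}

#' Validate a parameter vector
#'
#' Checks completeness, ordering and non-negativity of every rate and
#' affinity constant.
#'
#' @param params named numeric vector as returned by [default_parameters()].
#' @return `params`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_parameters <- function(params) {
  if (!is.numeric(params)) stop("parameters must be numeric")
  missing <- setdiff(.phyto_param_order, names(params))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  }
  vals <- params[.phyto_param_order]
  if (any(!is.finite(vals))) stop("parameters must be finite")
  if (any(vals < 0)) {
    stop("negative parameter(s): ",
         paste(.phyto_param_order[vals < 0], collapse = ", "))
  }
  invisible(params)
}

#' @export
print.phyto_params <- function(x, ...) {
  cat("<phyto_params> ", length(x), " constants (time/volume/mass in a.u.)\n",
      sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
tidy.phyto_params <- function(x, ...) {
  tibble::tibble(parameter = names(x), value = as.numeric(x))
}

#' Size-control hypothesis configuration
#'
#' Bundles the switches that distinguish the competing size-control
#' hypotheses: which inhibitor proteins are synthesised at a size-independent
#' (constant) rate rather than in proportion to cell volume; which proteins
#' are split equally (rather than in proportion to volume) between daughters
#' at division; and whether KRP synthesis is phase-dependent (driven purely
#' by phosphorylated MYB3R4, with zero basal synthesis and degradation).
#'
#' @param size_independent character vector of proteins whose synthesis does
#'   not scale with volume; allowed values: `"KRP"`, `"RBR"`, `"MYB3R3"`,
#'   `"SMR"`.  All other proteins are always size-dependent.
#' @param equal_inheritance character vector of proteins whose mass is split
#'   equally between the daughters at division (any tracked protein).
#' @param krp_phase_dependent if `TRUE`, the KRP parameters are replaced by
#'   `r_krp = 0`, `d_krp = 0`, `r_krp_myb4 = 0.05` so that KRP is produced
#'   only while MYB3R4 is active (late G2/M) and is removed only by
#'   FBL17-mediated degradation.
#' @return An object of class `phyto_hypothesis`.
#' @examples
#' hypothesis_flags(size_independent = c("KRP", "SMR"))
#' hypothesis_flags(equal_inheritance = "KRP", krp_phase_dependent = TRUE)
#' @export
hypothesis_flags <- function(size_independent = character(),
                             equal_inheritance = character(),
                             krp_phase_dependent = FALSE) {
  size_independent <- as.character(size_independent)
  equal_inheritance <- as.character(equal_inheritance)
  bad <- setdiff(size_independent, .phyto_si_candidates)
  if (length(bad)) {
    stop("size-independent synthesis is only modelled for ",
         paste(.phyto_si_candidates, collapse = ", "),
         "; got: ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(equal_inheritance, .phyto_proteins)
  if (length(bad)) {
    stop("unknown protein(s) in equal_inheritance: ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(size_independent = size_independent,
         equal_inheritance = equal_inheritance,
         krp_phase_dependent = isTRUE(krp_phase_dependent)),
    class = "phyto_hypothesis"
  )
}

#' @export
print.phyto_hypothesis <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "none"
  cat("<phyto_hypothesis>\n",
      "  size-independent synthesis: ", fmt(x$size_independent), "\n",
      "  equal inheritance:          ", fmt(x$equal_inheritance), "\n",
      "  phase-dependent KRP:        ", x$krp_phase_dependent, "\n", sep = "")
  invisible(x)
}

## Apply the phase-dependent KRP switch to a parameter vector.
.apply_hypothesis_params <- function(params, flags) {
  if (isTRUE(flags$krp_phase_dependent)) {
    params[["r_krp"]] <- 0
    params[["d_krp"]] <- 0
    params[["r_krp_myb4"]] <- 0.05
  }
  params
}

## Full parameter vector for the compiled rhs: model constants, the four 0/1
## size-dependence indicators, then two root-control slots (variable, theta).
.ode_parms <- function(params, flags = hypothesis_flags(),
                       root_var = 1, theta = 0.5) {
  params <- .apply_hypothesis_params(params, flags)
  sd_ind <- as.numeric(!(.phyto_si_candidates %in% flags$size_independent))
  unname(c(params[.phyto_param_order], sd_ind, root_var, theta))
}

#' Read a parameter set from a flat key = value file
#'
#' The configuration dialect is one `name = value` pair per line; blank lines
#' and lines starting with `#` are ignored.  Unknown keys are an error.  Keys
#' omitted from the file keep their default value.
#'
#' @param file path to the configuration file.
#' @return A `phyto_params` vector.
#' @seealso [write_parameters()]; the packaged defaults are at
#'   `system.file("extdata", "default_parameters.conf", package = "phytocycle")`.
#' @export
read_parameters <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!all(grepl("=", lines, fixed = TRUE))) {
    stop("malformed line (expected 'name = value'): ",
         lines[!grepl("=", lines, fixed = TRUE)][1])
  }
  keys <- trimws(sub("=.*$", "", lines))
  vals <- suppressWarnings(as.numeric(trimws(sub("^[^=]*=", "", lines))))
  if (anyNA(vals)) stop("non-numeric value for key: ", keys[is.na(vals)][1])
  if (anyDuplicated(keys)) stop("duplicated key: ", keys[duplicated(keys)][1])
  do.call(default_parameters, as.list(setNames(vals, keys)))
}

#' Write a parameter set to a flat key = value file
#'
#' @param params a `phyto_params` vector.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_parameters <- function(params, file) {
  validate_parameters(params)
  writeLines(
    c("# phytocycle parameter set (arbitrary units; rates in 1/time)",
      sprintf("%s = %.17g", .phyto_param_order,
              as.numeric(params[.phyto_param_order]))),
    file
  )
  invisible(file)
}
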