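#' Names of the 18 analysed kinetic parameters
#'
#' The four first-order disintegration/hydrolysis constants plus the seven
#' Monod (k_m, K_S) pairs, in canonical order. This is the set screened by
#' the Monte-Carlo sensitivity analysis.
#'
#' @return Character vector of length 18.
#' @export
kinetic_param_names <- function() {
  c("k_dis", "k_hyd_ch", "k_hyd_pr", "k_hyd_li",
    "k_m_su", "K_S_su", "k_m_aa", "K_S_aa", "k_m_fa", "K_S_fa",
    "k_m_c4", "K_S_c4", "k_m_pro", "K_S_pro", "k_m_ac", "K_S_ac",
    "k_m_h2", "K_S_h2")
}

#' Names of the six field-calibrated sensitive parameters
#' @return Character vector of length 6.
#' @export
sensitive_param_names <- function() {
  c("k_m_pro", "K_S_pro", "k_m_ac", "K_S_ac", "k_m_h2", "K_S_h2")
}

.registry_file <- function(name) {
  f <- system.file("params", name, package = "adplant")
  if (!nzchar(f)) stop("parameter registry not found: ", name)
  f
}

#' Read a parameter registry
#'
#' Registries are shipped as YAML under `inst/params/`. The stoichiometric
#' registry is versioned: its md5 is checked against the recorded sidecar
#' checksum and a mismatch is an error (a silently edited constant table is
#' worse than a missing one).
#'
#' @param name registry file name, e.g. `"iwa_recommended.yaml"`.
#' @return Named list of numeric values.
#' @export
read_registry <- function(name) {
  f <- .registry_file(name)
  if (identical(name, "stoichiometry.yaml")) {
    want <- readLines(paste0(f, ".md5"), warn = FALSE)[1]
    got <- unname(tools::md5sum(f))
    if (!identical(got, want))
      stop("stoichiometry registry checksum mismatch: ", got, " != ", want)
  }
  x <- yaml::read_yaml(f)
  x$version <- NULL
  lapply(x, as.numeric)
}

#' Assemble the full ADM1 parameter set
#'
#' Merges the versioned stoichiometric/physico-chemical registry with a
#' kinetic registry. `registry = "iwa"` gives the IWA-recommended
#' mesophilic high-rate kinetics; `"estimated"` overlays the six
#' field-calibrated propionate/acetate/hydrogen constants on that set.
#'
#' @param registry `"iwa"` or `"estimated"`, or a named numeric vector /
#'   list of kinetic overrides applied on top of the recommended set.
#' @return Named list: the full `ParameterSet` (stoichiometric fractions,
#'   yields, the 18 kinetic constants, decay, inhibition, acid-base and
#'   Henry constants, transfer coefficient `k_L_a`, temperature `T_op`).
#' @export
#' @examples
#' p <- adm1_params()
#' p$k_m_ac                       # 8.0, recommended
#' adm1_params("estimated")$k_m_ac  # 4.26, calibrated
adm1_params <- function(registry = "iwa") {
  p <- c(read_registry("stoichiometry.yaml"),
         read_registry("iwa_recommended.yaml"))
  if (is.character(registry) && length(registry) == 1L) {
    if (registry == "estimated") {
      est <- read_registry("paper_estimated.yaml")
      p[names(est)] <- est
    } else if (registry != "iwa") {
      stop("unknown registry: ", registry)
    }
  } else {
    ov <- as.list(registry)
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- lapply(ov, as.numeric)
  }
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' All rates and constants must be strictly positive and the 18-member
#' analysed kinetic set must be present in full.
#'
#' @param params parameter list as returned by [adm1_params()].
#' @return The parameter list, invisibly.
#' @export
validate_params <- function(params) {
  need <- kinetic_param_names()
  miss <- setdiff(need, names(params))
  if (length(miss)) stop("missing kinetic parameter(s): ", paste(miss, collapse = ", "))
  num <- unlist(params[vapply(params, is.numeric, logical(1))])
  pos <- setdiff(names(num), c("dH_K_H_h2", "dH_K_H_ch4", "dH_K_H_co2"))
  if (any(!is.finite(num))) stop("non-finite parameter value")
  if (any(num[pos] <= 0)) {
    bad <- names(num[pos])[num[pos] <= 0]
    stop("non-positive parameter(s): ", paste(bad, collapse = ", "))
  }
  invisible(params)
}

.vant_hoff <- function(k_base, dH, T) {
  # van 't Hoff correction from 298.15 K to T (J mol^-1, K)
  k_base * exp((dH / 8.314) * (1 / 298.15 - 1 / T))
}

#' Temperature-corrected equilibrium constants
#'
#' Acid dissociation constants (molar), the water ion product and Henry
#' constants (M bar^-1) at the operating temperature `params$T_op`, plus
#' the saturation water vapour pressure of the headspace (bar).
#'
#' @param params parameter list.
#' @return Named list `K_a_*`, `K_w`, `K_H_*`, `p_h2o`, `R_gas`
#'   (bar M^-1 K^-1).
#' @export
equilibrium_constants <- function(params) {
  T <- params$T_op
  list(
    K_a_va  = 10^-params$pK_a_va,
    K_a_bu  = 10^-params$pK_a_bu,
    K_a_pro = 10^-params$pK_a_pro,
    K_a_ac  = 10^-params$pK_a_ac,
    K_a_co2 = .vant_hoff(10^-params$pK_a_co2, params$dH_K_a_co2, T),
    K_a_IN  = .vant_hoff(10^-params$pK_a_IN, params$dH_K_a_IN, T),
    K_w     = .vant_hoff(1e-14, params$dH_K_w, T),
    K_H_h2  = .vant_hoff(params$K_H_h2_base, params$dH_K_H_h2, T),
    K_H_ch4 = .vant_hoff(params$K_H_ch4_base, params$dH_K_H_ch4, T),
    K_H_co2 = .vant_hoff(params$K_H_co2_base, params$dH_K_H_co2, T),
    p_h2o   = 0.0313 * exp(5290 * (1 / 298.15 - 1 / T)),
    R_gas   = 0.083145
  )
}
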