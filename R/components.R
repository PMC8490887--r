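#' Canonical ADM1 component names
#'
#' The 26 dynamic liquid-phase components of the model, in the fixed order
#' used throughout the package (state vectors, stoichiometry columns, the
#' compiled right-hand side). Soluble species first (kgCOD m^-3 except
#' `S_IC` in kmolC m^-3 and `S_IN` in kmolN m^-3), then particulates
#' (kgCOD m^-3), then the strong-ion pools `S_cat`/`S_an` (kmol m^-3).
#'
#' Ionised forms (VFA anions, bicarbonate, free ammonia) and pH are not
#' dynamic states: acid-base chemistry is resolved algebraically from the
#' total pools at every evaluation, see [solve_ph()].
#'
#' @return Character vector of length 26.
#' @export
state_names <- function() {
  c("S_su", "S_aa", "S_fa", "S_va", "S_bu", "S_pro", "S_ac", "S_h2",
    "S_ch4", "S_IC", "S_IN", "S_I",
    "X_c", "X_ch", "X_pr", "X_li", "X_su", "X_aa", "X_fa", "X_c4",
    "X_pro", "X_ac", "X_h2", "X_I",
    "S_cat", "S_an")
}

#' @rdname state_names
#' @export
particulate_names <- function() state_names()[13:24]

#' @rdname state_names
#' @export
soluble_names <- function() state_names()[1:12]

#' Names of the headspace state
#'
#' `S_gas_h2` and `S_gas_ch4` are headspace concentrations on a COD basis
#' (kgCOD m^-3), `S_gas_co2` on a molar basis (kmolC m^-3), matching the
#' units of the dissolved species they exchange with.
#'
#' @return Character vector of length 3.
#' @export
gas_names <- function() c("S_gas_h2", "S_gas_ch4", "S_gas_co2")

#' The 19 ADM1 biochemical processes, in IWA order
#'
#' Disintegration, three hydrolyses, eight uptakes (valerate and butyrate
#' share the C4-degrader biomass), and seven biomass decays.
#'
#' @return Character vector of length 19.
#' @export
process_names <- function() {
  c("dis", "hyd_ch", "hyd_pr", "hyd_li",
    "upt_su", "upt_aa", "upt_fa", "upt_va", "upt_bu", "upt_pro",
    "upt_ac", "upt_h2",
    "dec_Xsu", "dec_Xaa", "dec_Xfa", "dec_Xc4", "dec_Xpro", "dec_Xac",
    "dec_Xh2")
}

#' Build an ADM1 state vector
#'
#' @param ... named component concentrations; anything not supplied is 0.
#' @return Named numeric vector over [state_names()].
#' @export
#' @examples
#' new_state(S_ac = 0.2, X_ac = 0.5)
new_state <- function(...) {
  s <- stats::setNames(numeric(26L), state_names())
  args <- list(...)
  if (length(args)) {
    nm <- names(args)
    bad <- setdiff(nm, state_names())
    if (length(bad)) stop("unknown state component(s): ", paste(bad, collapse = ", "))
    s[nm] <- vapply(args, as.numeric, numeric(1))
  }
  s
}

#' Validate an ADM1 state vector
#'
#' Checks length, names, finiteness and nonnegativity. Negative
#' concentrations are rejected rather than clipped.
#'
#' @param state numeric vector over [state_names()].
#' @return The state, invisibly, if valid; otherwise an error.
#' @export
validate_state <- function(state) {
  if (length(state) != 26L || is.null(names(state)) ||
      !identical(names(state), state_names()))
    stop("state must be a named numeric vector over state_names()")
  if (any(!is.finite(state))) stop("non-finite state component")
  if (any(state < 0)) {
    bad <- names(state)[state < 0]
    stop("negative concentration in state: ", paste(bad, collapse = ", "))
  }
  invisible(state)
}

#' COD weight of each component
#'
#' 1 for COD-carrying species, 0 for the inorganic carbon/nitrogen pools
#' and the strong-ion states. Used by the COD-conservation checks and by
#' [effluent_cod()].
#'
#' @return Named numeric vector of length 26.
#' @export
cod_weights <- function() {
  w <- stats::setNames(rep(1, 26L), state_names())
  w[c("S_IC", "S_IN", "S_cat", "S_an")] <- 0
  w
}

#' Carbon content of each component (kmolC per kgCOD)
#'
#' `S_IC` carries 1 kmolC per kmol by definition. Values follow the IWA
#' benchmark parameterisation of ADM1.
#'
#' @return Named numeric vector of length 26.
#' @export
carbon_content <- function() {
  stats::setNames(c(
    0.0313, 0.03, 0.0217, 0.024, 0.025, 0.0268, 0.0313, 0, 0.0156,
    1, 0, 0.03,
    0.02786, 0.0313, 0.03, 0.022, rep(0.0313, 7), 0.03,
    0, 0), state_names())
}

#' Nitrogen content of each component (kmolN per kgCOD)
#' @return Named numeric vector of length 26.
#' @export
nitrogen_content <- function() {
  n <- stats::setNames(numeric(26L), state_names())
  n["S_IN"] <- 1
  n["S_aa"] <- 0.007
  n["X_pr"] <- 0.007
  n["S_I"] <- 0.06 / 14
  n["X_I"] <- 0.06 / 14
  n["X_c"] <- 0.0376 / 14
  n[c("X_su", "X_aa", "X_fa", "X_c4", "X_pro", "X_ac", "X_h2")] <- 0.08 / 14
  n
}
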