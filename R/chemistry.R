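# Algebraic acid-base chemistry. Ion speciation and pH are resolved from
# the total pools by a charge-balance root solve at every evaluation; the
# fast dissociation equilibria are never integrated as ODEs, which removes
# the stiffest timescales from the system.

.charge_balance <- function(S_H, state, eq) {
  # net charge (kmol m^-3) as a function of the proton concentration;
  # strictly increasing in S_H, so the root is unique
  va  <- eq$K_a_va  * state[["S_va"]]  / 208 / (eq$K_a_va  + S_H)
  bu  <- eq$K_a_bu  * state[["S_bu"]]  / 160 / (eq$K_a_bu  + S_H)
  pro <- eq$K_a_pro * state[["S_pro"]] / 112 / (eq$K_a_pro + S_H)
  ac  <- eq$K_a_ac  * state[["S_ac"]]  / 64  / (eq$K_a_ac  + S_H)
  hco3 <- eq$K_a_co2 * state[["S_IC"]] / (eq$K_a_co2 + S_H)
  nh4 <- S_H * state[["S_IN"]] / (eq$K_a_IN + S_H)
  state[["S_cat"]] + nh4 + S_H - hco3 - ac - pro - bu - va -
    state[["S_an"]] - eq$K_w / S_H
}

#' Solve pH and ion speciation for a state
#'
#' Finds the unique proton concentration that closes the charge balance
#' over the VFA acid/base pairs (on a molar basis: 208, 160, 112 and
#' 64 gCOD per mol for valerate...acetate), the carbonate and ammonia
#' systems, water, and the strong-ion pools, then reports the consistent
#' speciation. The balance residual at the returned root is below
#' 1e-12 kmol m^-3.
#'
#' @param state ADM1 state vector.
#' @param params parameter list.
#' @return List with `pH`, `S_H` (kmol m^-3), `residual`, and `speciation`:
#'   named vector `S_va_ion`, `S_bu_ion`, `S_pro_ion`, `S_ac_ion` (kgCOD
#'   m^-3), `S_hco3`, `S_co2`, `S_nh3`, `S_nh4` (kmol m^-3).
#' @export
#' @examples
#' s <- new_state(S_cat = 1e-4, S_an = 1e-4)
#' p <- adm1_params()
#' p$T_op <- 298.15
#' solve_ph(s, p)$pH  # neutral: 7 at 25 degC
solve_ph <- function(state, params) {
  validate_state(state)
  eq <- equilibrium_constants(params)
  f <- function(pH) .charge_balance(10^-pH, state, eq)
  lo <- f(0); hi <- f(14)
  if (is.na(lo) || is.na(hi) || lo * hi > 0)
    stop("infeasible chemistry: no charge-balance root for pH in (0, 14)")
  r <- stats::uniroot(f, c(0, 14), tol = 1e-12)
  S_H <- 10^-r$root
  # Newton polish on S_H to drive the residual to machine level
  for (i in 1:30) {
    fx <- .charge_balance(S_H, state, eq)
    if (abs(fx) < 1e-13) break
    h <- max(S_H * 1e-7, 1e-20)
    dfx <- (.charge_balance(S_H + h, state, eq) - fx) / h
    step <- fx / dfx
    if (!is.finite(step)) break
    S_H <- max(S_H - step, S_H * 0.1)
  }
  spec <- c(
    S_va_ion  = eq$K_a_va  * state[["S_va"]]  / (eq$K_a_va  + S_H),
    S_bu_ion  = eq$K_a_bu  * state[["S_bu"]]  / (eq$K_a_bu  + S_H),
    S_pro_ion = eq$K_a_pro * state[["S_pro"]] / (eq$K_a_pro + S_H),
    S_ac_ion  = eq$K_a_ac  * state[["S_ac"]]  / (eq$K_a_ac  + S_H),
    S_hco3    = eq$K_a_co2 * state[["S_IC"]]  / (eq$K_a_co2 + S_H),
    S_co2     = S_H * state[["S_IC"]] / (eq$K_a_co2 + S_H),
    S_nh3     = eq$K_a_IN * state[["S_IN"]] / (eq$K_a_IN + S_H),
    S_nh4     = S_H * state[["S_IN"]] / (eq$K_a_IN + S_H)
  )
  list(pH = -log10(S_H), S_H = S_H,
       residual = .charge_balance(S_H, state, eq), speciation = spec)
}

.ph_inhibition <- function(pH, pH_UL, pH_LL) {
  # lower-pH inhibition switch: 1 at/above the upper limit, Gaussian
  # roll-off below it
  if (pH >= pH_UL) 1 else exp(-3 * ((pH - pH_UL) / (pH_UL - pH_LL))^2)
}

#' Inhibition multipliers
#'
#' The regulatory factors of the uptake rates: lower-pH inhibition per
#' trophic group (acidogens/acetogens, aceticlastic methanogens,
#' hydrogenotrophic methanogens), inorganic-nitrogen limitation, hydrogen
#' inhibition of the three acetogenic uptakes, and free-ammonia inhibition
#' of aceticlastic methanogenesis. All factors lie in [0, 1] and tend to 1
#' as the inhibitor vanishes (or, for nitrogen, as `S_IN >> K_S_IN`).
#'
#' @param state ADM1 state vector.
#' @param params parameter list.
#' @param ph resolved pH for the state; solved from the state if `NULL`.
#' @return Named vector `I_pH_aa`, `I_pH_ac`, `I_pH_h2`, `I_IN_lim`,
#'   `I_h2_fa`, `I_h2_c4`, `I_h2_pro`, `I_nh3`.
#' @export
inhibition_factors <- function(state, params, ph = NULL) {
  validate_state(state)
  if (is.null(ph)) {
    sol <- solve_ph(state, params)
    ph <- sol$pH
    S_nh3 <- sol$speciation[["S_nh3"]]
  } else {
    eq <- equilibrium_constants(params)
    S_nh3 <- eq$K_a_IN * state[["S_IN"]] / (eq$K_a_IN + 10^-ph)
  }
  h2 <- state[["S_h2"]]
  c(I_pH_aa = .ph_inhibition(ph, params$pH_UL_aa, params$pH_LL_aa),
    I_pH_ac = .ph_inhibition(ph, params$pH_UL_ac, params$pH_LL_ac),
    I_pH_h2 = .ph_inhibition(ph, params$pH_UL_h2, params$pH_LL_h2),
    I_IN_lim = 1 / (1 + params$K_S_IN / max(state[["S_IN"]], 1e-16)),
    I_h2_fa = 1 / (1 + h2 / params$K_I_h2_fa),
    I_h2_c4 = 1 / (1 + h2 / params$K_I_h2_c4),
    I_h2_pro = 1 / (1 + h2 / params$K_I_h2_pro),
    I_nh3 = 1 / (1 + S_nh3 / params$K_I_nh3))
}

#' Gas-liquid transfer rates
#'
#' Two-film transfer for hydrogen, methane and carbon dioxide:
#' `rho_T_i = k_L_a * (S_liq_i - K_H_i * p_gas_i)`, with the Henry term
#' expressed in the liquid species' own units (16 and 64 gCOD per mol for
#' H2 and CH4; molar CO2 is the unionised fraction of `S_IC`). Positive
#' rates strip gas out of the liquid; the rate is zero at Henry
#' equilibrium.
#'
#' @param state ADM1 liquid state vector.
#' @param gas headspace state over [gas_names()].
#' @param params parameter list.
#' @param S_co2 unionised CO2 (kmol m^-3); solved from the state if `NULL`.
#' @return Named vector `h2`, `ch4` (kgCOD m^-3 d^-1), `co2`
#'   (kmolC m^-3 d^-1).
#' @export
gas_transfer_rates <- function(state, gas, params, S_co2 = NULL) {
  validate_state(state)
  eq <- equilibrium_constants(params)
  if (is.null(S_co2)) S_co2 <- solve_ph(state, params)$speciation[["S_co2"]]
  pp <- gas_partial_pressures(gas, params)
  kLa <- params$k_L_a
  c(h2  = kLa * (state[["S_h2"]]  - 16 * eq$K_H_h2  * pp[["p_h2"]]),
    ch4 = kLa * (state[["S_ch4"]] - 64 * eq$K_H_ch4 * pp[["p_ch4"]]),
    co2 = kLa * (S_co2 - eq$K_H_co2 * pp[["p_co2"]]))
}

#' Headspace partial pressures
#'
#' Ideal-gas partial pressures of the three biogas species plus water
#' vapour at the operating temperature, and their total.
#'
#' @param gas headspace state over [gas_names()].
#' @param params parameter list.
#' @return Named vector `p_h2`, `p_ch4`, `p_co2`, `p_h2o`, `P` (bar).
#' @export
gas_partial_pressures <- function(gas, params) {
  eq <- equilibrium_constants(params)
  RT <- eq$R_gas * params$T_op
  p <- c(p_h2 = gas[["S_gas_h2"]] * RT / 16,
         p_ch4 = gas[["S_gas_ch4"]] * RT / 64,
         p_co2 = gas[["S_gas_co2"]] * RT,
         p_h2o = eq$p_h2o)
  c(p, P = sum(p))
}
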