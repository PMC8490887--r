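#' Plant geometry and operating configuration
#'
#' Defaults describe the modelled treatment train: a 750 m^3
#' pre-acidification tank, an internal-circulation reactor represented as
#' three 750 m^3 CSTRs in series (2250 m^3 active volume) with a solids
#' retention constant of 40 d, and one shared 250 m^3 gas headspace. The
#' default flow of 4500 m^3 d^-1 gives a tank HRT of 4 h and a reactor HRT
#' of 8 h (1:2, as the volume ratio).
#'
#' @param V_a pre-acidification tank volume (m^3).
#' @param V_c volume of each reactor CSTR (m^3); there are exactly three.
#' @param V_gas headspace volume (m^3).
#' @param t_res_X extended solids retention constant (d) applied in each
#'   reactor CSTR.
#' @param Q_inf default inflow rate (m^3 d^-1), used when no series is
#'   supplied.
#' @param k_p overpressure-relief coefficient of the headspace
#'   (m^3 d^-1 bar^-1); large, so the headspace is near-isobaric.
#' @param P_atm atmospheric pressure (bar).
#' @param tank_mask,reactor_mask 0/1 process-activity vectors of length 19.
#' @return Named list (`PlantConfig`).
#' @export
plant_config <- function(V_a = 750, V_c = 750, V_gas = 250, t_res_X = 40,
                         Q_inf = 4500, k_p = 5e4, P_atm = 1.013,
                         tank_mask = process_mask("tank"),
                         reactor_mask = process_mask("reactor")) {
  stopifnot(V_a > 0, V_c > 0, V_gas > 0, t_res_X >= 0, Q_inf > 0,
            length(tank_mask) == 19L, length(reactor_mask) == 19L)
  list(V_a = V_a, V_c = V_c, n_cstr = 3L, V_gas = V_gas, t_res_X = t_res_X,
       Q_inf = Q_inf, k_p = k_p, P_atm = P_atm,
       tank_mask = tank_mask, reactor_mask = reactor_mask)
}

#' Pre-acidification tank time derivative
#'
#' Plain CSTR mass balance for every component (solubles and particulates
#' wash out hydraulically; there is no solids retention in the tank) plus
#' the masked biochemical source. With the tank's 15-process mask the
#' methane source term is exactly zero.
#'
#' @param state tank state vector.
#' @param influent influent state vector.
#' @param Q_inf inflow (m^3 d^-1).
#' @param params parameter list.
#' @param config plant configuration.
#' @return Named derivative vector (per day).
#' @export
preacid_rhs <- function(state, influent, Q_inf, params,
                        config = plant_config()) {
  if (Q_inf <= 0 || config$V_a <= 0) stop("nonpositive flow or volume")
  rates <- biochemical_rates(state, params)
  src <- stoichiometric_source(rates, stoichiometry_matrix(params),
                               config$tank_mask)
  Q_inf / config$V_a * (influent - state) + src
}

#' Effluent particulate concentrations of a retaining CSTR
#'
#' The extended-retention washout term implies that particulates leave at
#' a lower concentration than held in the vessel:
#' `X_out = X * (V_c/Q) / (t_res_X + V_c/Q)`, so that `X_out * Q` equals
#' the washout flux `X * V_c / (t_res_X + V_c/Q)`. Used as the particulate
#' feed of the next CSTR and in effluent COD.
#'
#' @param state CSTR state vector.
#' @param Q_inf flow (m^3 d^-1).
#' @param config plant configuration.
#' @return State vector with particulate components scaled; solubles
#'   unchanged.
#' @export
effluent_particulates <- function(state, Q_inf, config = plant_config()) {
  hrt <- config$V_c / Q_inf
  out <- state
  out[particulate_names()] <- state[particulate_names()] *
    hrt / (config$t_res_X + hrt)
  out
}

#' Reactor CSTR time derivative
#'
#' Soluble species use the plain dilution balance plus (for dissolved H2,
#' CH4 and CO2) the gas-transfer sink; particulates use the
#' extended-retention washout denominator `t_res_X + V_c/Q`. The upstream
#' effluent must already be expressed as what actually leaves the upstream
#' vessel (see [effluent_particulates()]).
#'
#' @param state CSTR state vector.
#' @param upstream_effluent feed state (upstream vessel effluent).
#' @param Q_inf flow (m^3 d^-1).
#' @param gas shared headspace state over [gas_names()].
#' @param params parameter list.
#' @param config plant configuration.
#' @return List: `deriv` (named derivative vector), `transfer` (the three
#'   gas-transfer rates, kg/kmol m^-3 d^-1).
#' @export
cstr_rhs <- function(state, upstream_effluent, Q_inf, gas, params,
                     config = plant_config()) {
  if (Q_inf <= 0 || config$V_c <= 0) stop("nonpositive flow or volume")
  sol <- solve_ph(state, params)
  inh <- inhibition_factors(state, params, ph = sol$pH)
  rates <- biochemical_rates(state, params, inhibition = inh)
  src <- stoichiometric_source(rates, stoichiometry_matrix(params),
                               config$reactor_mask)
  rho_T <- gas_transfer_rates(state, gas, params,
                              S_co2 = sol$speciation[["S_co2"]])
  d <- Q_inf / config$V_c * (upstream_effluent - state) + src
  xp <- particulate_names()
  d[xp] <- Q_inf / config$V_c * upstream_effluent[xp] -
    state[xp] / (config$t_res_X + config$V_c / Q_inf) + src[xp]
  d["S_h2"] <- d["S_h2"] - rho_T[["h2"]]
  d["S_ch4"] <- d["S_ch4"] - rho_T[["ch4"]]
  d["S_IC"] <- d["S_IC"] - rho_T[["co2"]]
  list(deriv = d, transfer = rho_T)
}

#' Shared headspace time derivative and gas outflow
#'
#' One gas collection tank serves the whole reactor: it receives the
#' summed transfer `sum over CSTRs of rho_T_i * V_c` and vents through an
#' overpressure-relief law `Q_gas = k_p * max(P - P_atm, 0)`, which for
#' large `k_p` keeps the headspace near-isobaric. Each species obeys
#' `dS_gas_i/dt = -S_gas_i * Q_gas / V_gas + transfer_i / V_gas`.
#'
#' @param gas headspace state over [gas_names()].
#' @param transfer_totals named vector `h2`, `ch4`, `co2`: transfer rates
#'   already multiplied by `V_c` and summed over the three CSTRs
#'   (kgCOD d^-1 / kmolC d^-1).
#' @param config plant configuration.
#' @param params parameter list.
#' @return List: `deriv` (length 3), `Q_gas` (raw volumetric outflow at
#'   headspace conditions, m^3 d^-1), `Q_gas_N` (dry flow normalised to
#'   0 degC and 1.013 bar, Nm^3 d^-1), `P` (bar).
#' @export
gas_phase_rhs <- function(gas, transfer_totals, config = plant_config(),
                          params = adm1_params()) {
  pp <- gas_partial_pressures(gas, params)
  Q_gas <- config$k_p * max(pp[["P"]] - config$P_atm, 0)
  d <- stats::setNames(
    -gas[gas_names()] * Q_gas / config$V_gas +
      transfer_totals[c("h2", "ch4", "co2")] / config$V_gas,
    gas_names())
  Q_gas_N <- Q_gas * (pp[["P"]] - pp[["p_h2o"]]) / 1.013 *
    273.15 / params$T_op
  list(deriv = d, Q_gas = Q_gas, Q_gas_N = Q_gas_N, P = pp[["P"]])
}

#' Total effluent COD of a vessel
#'
#' Sum of every COD-carrying soluble species (including inert `S_I` and
#' the dissolved gases `S_h2`, `S_ch4`) plus the particulate COD actually
#' leaving the vessel. For a retaining reactor CSTR the particulate part
#' is attenuated by the washout fraction; for the tank it leaves at the
#' in-vessel concentration.
#'
#' @param state vessel state vector.
#' @param Q_inf flow (m^3 d^-1).
#' @param config plant configuration.
#' @param retained `TRUE` for a reactor CSTR with solids retention,
#'   `FALSE` for the plain tank.
#' @return Effluent COD (kgCOD m^-3).
#' @export
effluent_cod <- function(state, Q_inf = plant_config()$Q_inf,
                         config = plant_config(), retained = TRUE) {
  out <- if (retained) effluent_particulates(state, Q_inf, config) else state
  sum(out * cod_weights())
}

#' Default initial plant state
#'
#' Liquid phases start at the influent composition with uniform seeded
#' biomass (0.5 kgCOD m^-3 per trophic group per vessel; the tank's two
#' methanogen pools start empty, consistent with its process mask). The
#' headspace starts near atmospheric pressure at a typical biogas
#' composition.
#'
#' @param influent influent state vector.
#' @param config plant configuration.
#' @param params parameter list.
#' @param seed_biomass seeded concentration per trophic group
#'   (kgCOD m^-3).
#' @return Named numeric vector of length 107: tank, CSTR1..3, headspace.
#' @export
initial_plant_state <- function(influent, config = plant_config(),
                                params = adm1_params(),
                                seed_biomass = 0.5) {
  groups <- c("X_su", "X_aa", "X_fa", "X_c4", "X_pro", "X_ac", "X_h2")
  vessel <- influent
  vessel[groups] <- seed_biomass
  vessel["S_h2"] <- 1e-8
  vessel["S_ch4"] <- 1e-5
  tank <- vessel
  tank[c("X_ac", "X_h2")] <- 0
  tank["S_ch4"] <- 0
  eq <- equilibrium_constants(params)
  RT <- eq$R_gas * params$T_op
  # positions 11/12 are uptake of acetate / hydrogen (masks may be unnamed)
  methanogenic <- config$reactor_mask[11] > 0 || config$reactor_mask[12] > 0
  if (methanogenic) {
    gas <- c(S_gas_h2 = 1e-5 * 16 / RT, S_gas_ch4 = 0.60 * 64 / RT,
             S_gas_co2 = 0.35 / RT)
  } else {
    # a plant that cannot methanise starts with no biogas blanket
    vessel["S_ch4"] <- 0
    gas <- c(S_gas_h2 = 0, S_gas_ch4 = 0, S_gas_co2 = 0)
  }
  y <- c(tank, vessel, vessel, vessel, gas)
  names(y) <- plant_state_names()
  y
}

#' Names of the full plant state vector
#'
#' Vessel ordering is fixed: tank, then the three reactor CSTRs bottom to
#' top, then the shared headspace.
#'
#' @return Character vector of length 107.
#' @export
plant_state_names <- function() {
  c(paste0("tank.", state_names()),
    paste0("c1.", state_names()),
    paste0("c2.", state_names()),
    paste0("c3.", state_names()),
    gas_names())
}

#' Full plant time derivative (reference implementation)
#'
#' Pure-R assembly of the whole-plant right-hand side from the module
#' operations ([preacid_rhs()], [cstr_rhs()], [gas_phase_rhs()]). The
#' production integrator uses the compiled equivalent; this function is
#' the readable specification and the cross-check target.
#'
#' @param y full plant state (length 107, [plant_state_names()]).
#' @param influent influent state vector.
#' @param Q_inf flow (m^3 d^-1).
#' @param params parameter list.
#' @param config plant configuration.
#' @return List: `deriv` (length 107), `Q_gas`, `Q_gas_N`, `pH` (4).
#' @export
plant_rhs <- function(y, influent, Q_inf, params, config = plant_config()) {
  sv <- function(i) stats::setNames(y[(i - 1) * 26 + 1:26], state_names())
  tank <- sv(1); c1 <- sv(2); c2 <- sv(3); c3 <- sv(4)
  gas <- y[105:107]; names(gas) <- gas_names()

  d_tank <- preacid_rhs(tank, influent, Q_inf, params, config)
  r1 <- cstr_rhs(c1, tank, Q_inf, gas, params, config)
  r2 <- cstr_rhs(c2, effluent_particulates(c1, Q_inf, config), Q_inf, gas,
                 params, config)
  r3 <- cstr_rhs(c3, effluent_particulates(c2, Q_inf, config), Q_inf, gas,
                 params, config)
  totals <- (r1$transfer + r2$transfer + r3$transfer) * config$V_c
  g <- gas_phase_rhs(gas, totals, config, params)
  ph <- c(tank = solve_ph(tank, params)$pH, c1 = solve_ph(c1, params)$pH,
          c2 = solve_ph(c2, params)$pH, c3 = solve_ph(c3, params)$pH)
  list(deriv = stats::setNames(
         c(d_tank, r1$deriv, r2$deriv, r3$deriv, g$deriv),
         plant_state_names()),
       Q_gas = g$Q_gas, Q_gas_N = g$Q_gas_N, pH = ph)
}
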