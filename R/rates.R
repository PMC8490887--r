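#' ADM1 biochemical process rates
#'
#' The 19 process rates at a given state: first-order disintegration and
#' hydrolysis, Monod substrate uptake with inhibition
#' (`rho = k_m * S / (K_S + S) * X * I`), and first-order biomass decay.
#' Valerate and butyrate compete for the shared C4-degrading biomass via
#' the usual cross-competition factor `S / (S_va + S_bu)`.
#'
#' @param state ADM1 state vector (validated; negative concentrations are
#'   rejected).
#' @param params parameter list from [adm1_params()].
#' @param inhibition optional precomputed [inhibition_factors()] vector;
#'   solved from the state when `NULL`.
#' @return Named nonnegative vector of length 19 over [process_names()]
#'   (kgCOD m^-3 d^-1).
#' @export
#' @examples
#' s <- new_state(S_ac = 0.15, X_ac = 1, S_IN = 0.01,
#'                S_IC = 0.05, S_cat = 0.04, S_an = 0.02)
#' biochemical_rates(s, adm1_params())[["upt_ac"]]
biochemical_rates <- function(state, params, inhibition = NULL) {
  validate_state(state)
  p <- params
  if (is.null(inhibition)) inhibition <- inhibition_factors(state, params)
  I <- inhibition

  monod <- function(k_m, S, K_S, X, Ifac) k_m * S / (K_S + S) * X * Ifac

  I5  <- I[["I_pH_aa"]] * I[["I_IN_lim"]]                      # su, aa
  I6  <- I5 * I[["I_h2_fa"]]                                   # fa
  I7  <- I5 * I[["I_h2_c4"]]                                   # va, bu
  I8  <- I5 * I[["I_h2_pro"]]                                  # pro
  I9  <- I[["I_pH_ac"]] * I[["I_IN_lim"]] * I[["I_nh3"]]       # ac
  I10 <- I[["I_pH_h2"]] * I[["I_IN_lim"]]                      # h2

  S_va <- state[["S_va"]]; S_bu <- state[["S_bu"]]
  c4_tot <- S_va + S_bu
  f_va <- if (c4_tot > 0) S_va / c4_tot else 0
  f_bu <- if (c4_tot > 0) S_bu / c4_tot else 0

  r <- c(
    dis     = p$k_dis * state[["X_c"]],
    hyd_ch  = p$k_hyd_ch * state[["X_ch"]],
    hyd_pr  = p$k_hyd_pr * state[["X_pr"]],
    hyd_li  = p$k_hyd_li * state[["X_li"]],
    upt_su  = monod(p$k_m_su, state[["S_su"]], p$K_S_su, state[["X_su"]], I5),
    upt_aa  = monod(p$k_m_aa, state[["S_aa"]], p$K_S_aa, state[["X_aa"]], I5),
    upt_fa  = monod(p$k_m_fa, state[["S_fa"]], p$K_S_fa, state[["X_fa"]], I6),
    upt_va  = monod(p$k_m_c4, S_va, p$K_S_c4, state[["X_c4"]], I7) * f_va,
    upt_bu  = monod(p$k_m_c4, S_bu, p$K_S_c4, state[["X_c4"]], I7) * f_bu,
    upt_pro = monod(p$k_m_pro, state[["S_pro"]], p$K_S_pro, state[["X_pro"]], I8),
    upt_ac  = monod(p$k_m_ac, state[["S_ac"]], p$K_S_ac, state[["X_ac"]], I9),
    upt_h2  = monod(p$k_m_h2, state[["S_h2"]], p$K_S_h2, state[["X_h2"]], I10),
    dec_Xsu  = p$k_dec_X_su * state[["X_su"]],
    dec_Xaa  = p$k_dec_X_aa * state[["X_aa"]],
    dec_Xfa  = p$k_dec_X_fa * state[["X_fa"]],
    dec_Xc4  = p$k_dec_X_c4 * state[["X_c4"]],
    dec_Xpro = p$k_dec_X_pro * state[["X_pro"]],
    dec_Xac  = p$k_dec_X_ac * state[["X_ac"]],
    dec_Xh2  = p$k_dec_X_h2 * state[["X_h2"]]
  )
  r
}
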