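# Packing of the compiled model's parameter vector. The layout must match
# src/adm1.c exactly; the stoichiometry matrix travels inside the vector
# so R and C share a single Petersen table.
.pack_plant_parms <- function(params, config, influent, Q_inf) {
  eq <- equilibrium_constants(params)
  kin <- unlist(params[kinetic_param_names()])
  dec <- unlist(params[c("k_dec_X_su", "k_dec_X_aa", "k_dec_X_fa",
                         "k_dec_X_c4", "k_dec_X_pro", "k_dec_X_ac",
                         "k_dec_X_h2")])
  inh <- unlist(params[c("K_S_IN", "K_I_h2_fa", "K_I_h2_c4", "K_I_h2_pro",
                         "K_I_nh3", "pH_UL_aa", "pH_LL_aa", "pH_UL_ac",
                         "pH_LL_ac", "pH_UL_h2", "pH_LL_h2")])
  nu <- stoichiometry_matrix(params)
  c(config$V_a, config$V_c, config$V_gas, config$t_res_X, params$T_op,
    params$k_L_a, config$k_p, config$P_atm, Q_inf,
    as.numeric(influent[state_names()]),
    kin, dec, inh,
    eq$K_a_va, eq$K_a_bu, eq$K_a_pro, eq$K_a_ac, eq$K_a_co2, eq$K_a_IN,
    eq$K_w,
    eq$K_H_h2, eq$K_H_ch4, eq$K_H_co2, eq$p_h2o,
    as.numeric(config$tank_mask), as.numeric(config$reactor_mask),
    as.numeric(nu))
}

.diag_names <- c("pH_tank", "pH_c1", "pH_c2", "pH_c3", "P_gas",
                 "Q_gas_raw", "Q_gas_N")

#' Evaluate the compiled plant right-hand side once
#'
#' Mostly useful for verification against [plant_rhs()]; the integrator
#' calls the compiled code directly.
#'
#' @param y full plant state (length 107).
#' @param influent influent state vector.
#' @param Q_inf flow (m^3 d^-1).
#' @param params parameter list.
#' @param config plant configuration.
#' @return List `deriv` (length 107) and `diagnostics` (pH per vessel,
#'   headspace pressure, raw and normalised gas flow).
#' @export
plant_rhs_compiled <- function(y, influent, Q_inf, params,
                               config = plant_config()) {
  pp <- .pack_plant_parms(params, config, influent, Q_inf)
  d <- deSolve::DLLfunc(func = "plant_deriv", times = 0, y = as.numeric(y),
                        parms = pp, dllname = "adplant",
                        initfunc = "plant_init", nout = 7)
  list(deriv = stats::setNames(as.numeric(d$dy), plant_state_names()),
       diagnostics = stats::setNames(as.numeric(d$var), .diag_names))
}

#' Simulate the full plant
#'
#' Integrates the whole anaerobic train (tank, three CSTRs, shared
#' headspace) over a daily influent record with a stiff implicit
#' multistep solver over the compiled right-hand side. Influent forcing
#' is piecewise-constant per day; outputs are reported at day boundaries
#' (midnight).
#'
#' @param influent_series data frame with columns `day`, `Q_inf`, and the
#'   26 influent components ([state_names()]); one row per day. A single
#'   influent state plus `horizon` may be given instead via
#'   [constant_influent_series()].
#' @param params parameter list.
#' @param config plant configuration.
#' @param init initial plant state (length 107); default
#'   [initial_plant_state()] from the first influent row.
#' @param rtol,atol solver tolerances.
#' @param states if `TRUE`, also return the full daily state matrix.
#' @return Data frame with `day`, `COD_eff_kg_m3`, `Q_gas_Nm3_d`,
#'   `COD_preacid_kg_m3`, `Q_ch4_Nm3_d`, pH diagnostics and headspace
#'   pressure; with `states = TRUE` an attribute `"states"` holds the
#'   107-column daily state matrix.
#' @export
simulate_plant <- function(influent_series, params = adm1_params(),
                           config = plant_config(), init = NULL,
                           rtol = 1e-6, atol = 1e-10, states = FALSE,
                           method = "vode") {
  req <- c("day", "Q_inf", state_names())
  miss <- setdiff(req, names(influent_series))
  if (length(miss))
    stop("influent series lacks column(s): ", paste(miss, collapse = ", "))
  n <- nrow(influent_series)
  inf1 <- stats::setNames(as.numeric(influent_series[1, state_names()]),
                          state_names())
  if (is.null(init)) init <- initial_plant_state(inf1, config, params)
  pp <- .pack_plant_parms(params, config, inf1, influent_series$Q_inf[1])

  # influent forcing, piecewise-constant per day: row k holds over
  # (k-1, k]
  tf <- seq_len(n) - 1
  forcings <- c(
    list(cbind(tf, influent_series$Q_inf)),
    lapply(state_names(),
           function(nm) cbind(tf, influent_series[[nm]])))
  sol <- deSolve::ode(
    y = as.numeric(init), times = 0:n, func = "plant_deriv_forc",
    parms = pp, dllname = "adplant", initfunc = "plant_init",
    initforc = "plant_forc", forcings = forcings,
    fcontrol = list(method = "constant", rule = 2, f = 0),
    nout = 7, rtol = rtol, atol = atol, maxsteps = 50000,
    method = method)
  istate <- attr(sol, "istate")
  if ((!is.null(istate) && istate[1] < 0) || nrow(sol) < n + 1)
    stop(sprintf(
      "stiff solver failure at t=%.3f d; state snapshot: %s",
      sol[nrow(sol), 1],
      paste(signif(c(sol[nrow(sol), -1])[1:107], 4), collapse = ",")))

  Y <- sol[-1, 2:108, drop = FALSE]          # states at day boundaries
  D <- sol[-1, 109:115, drop = FALSE]        # diagnostics
  Q <- influent_series$Q_inf
  w <- cod_weights()
  att <- (config$V_c / Q) / (config$t_res_X + config$V_c / Q)
  c3 <- Y[, 79:104, drop = FALSE]
  colnames(c3) <- state_names()
  c3_eff <- c3
  c3_eff[, particulate_names()] <- c3[, particulate_names()] * att
  cod_eff <- as.numeric(c3_eff %*% w)
  tank <- Y[, 1:26, drop = FALSE]
  cod_tank <- as.numeric(tank %*% w)
  out <- data.frame(
    day = influent_series$day,
    COD_eff_kg_m3 = cod_eff,
    Q_gas_Nm3_d = D[, 7],
    COD_preacid_kg_m3 = cod_tank,
    Q_ch4_Nm3_d = D[, 6] * Y[, 106] / 64 * 22.414,
    S_I_eff = c3_eff[, "S_I"])
  out[.diag_names] <- D
  if (states) {
    colnames(Y) <- plant_state_names()
    attr(out, "states") <- Y
  }
  out
}

#' Constant-influent series helper
#'
#' @param influent influent state vector.
#' @param horizon number of days.
#' @param Q_inf flow (m^3 d^-1).
#' @return Influent series data frame for [simulate_plant()].
#' @export
constant_influent_series <- function(influent, horizon,
                                     Q_inf = plant_config()$Q_inf) {
  df <- data.frame(day = seq_len(horizon), Q_inf = Q_inf)
  for (nm in state_names()) df[[nm]] <- influent[[nm]]
  df
}
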