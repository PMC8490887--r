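# Plant hydrodynamics: vessel balances, gas phase, whole-plant runs.

test_that("tank at equilibrium with its influent has zero dilution derivative", {
  p <- adm1_params()
  cfg <- plant_config(tank_mask = rep(0, 19))   # biochemistry off
  s <- populated_state()
  d <- preacid_rhs(s, influent = s, Q_inf = 4500, params = p, config = cfg)
  expect_equal(unname(d), rep(0, 26))

  # with influent = state the dilution cancels and only the source remains
  cfg2 <- plant_config()
  d2 <- preacid_rhs(s, influent = s, Q_inf = 4500, params = p, config = cfg2)
  src <- stoichiometric_source(biochemical_rates(s, p),
                               stoichiometry_matrix(p), cfg2$tank_mask)
  expect_equal(unname(d2), unname(src), tolerance = 1e-12)
  expect_error(preacid_rhs(s, s, Q_inf = 0, p), "nonpositive")
})

test_that("effluent particulates follow the retention washout fraction", {
  cfg0 <- plant_config(t_res_X = 0)
  s <- populated_state()
  expect_equal(effluent_particulates(s, 4500, cfg0), s)

  cfg_inf <- plant_config(t_res_X = 1e12)
  expect_lt(max(effluent_particulates(s, 4500, cfg_inf)[particulate_names()]),
            1e-12)

  # V_c/Q equal to t_res_X halves the outgoing particulates
  cfg <- plant_config(t_res_X = 750 / 4500)
  out <- effluent_particulates(s, 4500, cfg)
  expect_equal(unname(out[particulate_names()]),
               unname(s[particulate_names()] / 2))
  expect_equal(out[soluble_names()], s[soluble_names()])
})

test_that("with zero retention the CSTR balance reduces to the plain form", {
  p <- adm1_params()
  cfg <- plant_config(t_res_X = 0)
  s <- populated_state()
  up <- random_states(1, seed = 8)[[1]]
  gas <- stats::setNames(c(1e-5, 1.0, 0.01), gas_names())
  r <- cstr_rhs(s, up, 4500, gas, p, cfg)
  src <- stoichiometric_source(biochemical_rates(s, p),
                               stoichiometry_matrix(p), cfg$reactor_mask)
  plain <- 4500 / cfg$V_c * (up - s) + src
  rho <- gas_transfer_rates(s, gas, p)
  plain["S_h2"] <- plain["S_h2"] - rho[["h2"]]
  plain["S_ch4"] <- plain["S_ch4"] - rho[["ch4"]]
  plain["S_IC"] <- plain["S_IC"] - rho[["co2"]]
  expect_equal(unname(r$deriv), unname(plain), tolerance = 1e-10)
})

test_that("compiled and reference right-hand sides agree", {
  p <- adm1_params("estimated")
  cfg <- plant_config()
  inf <- table1_influent()
  y0 <- initial_plant_state(inf, cfg, p)
  set.seed(21)
  for (i in 1:5) {
    y <- y0 * stats::runif(107, 0.5, 1.5)
    rc <- plant_rhs_compiled(y, inf, 4500, p, cfg)
    rr <- plant_rhs(y, inf, 4500, p, cfg)
    scale <- max(abs(rr$deriv))
    expect_lt(max(abs(rc$deriv - rr$deriv)) / scale, 1e-10)
    expect_equal(unname(rc$diagnostics[["Q_gas_N"]]), rr$Q_gas_N,
                 tolerance = 1e-8)
  }
})

test_that("a rate-free soluble species approaches steady state on the closed form", {
  # abiotic, transfer-free plant: each soluble species in the tank obeys
  # dS/dt = Q/V (S_in - S)  =>  S(t) = S_in + (S0 - S_in) exp(-Q t/V)
  p <- adm1_params()
  p$k_L_a <- 1e-12
  cfg <- plant_config(tank_mask = rep(0, 19), reactor_mask = rep(0, 19))
  inf <- table1_influent()
  y0 <- initial_plant_state(inf, cfg, p, seed_biomass = 0)
  y0[1:26] <- 0                       # tank starts empty
  y0[c(25, 26)] <- inf[c("S_cat", "S_an")]  # keep chemistry feasible
  ser <- constant_influent_series(inf, 3, Q_inf = 4500)
  res <- simulate_plant(ser, params = p, config = cfg, init = y0,
                        states = TRUE)
  S <- attr(res, "states")
  k <- 4500 / 750
  for (t in 1:3) {
    closed <- inf[["S_su"]] * (1 - exp(-k * t))
    expect_equal(S[t, "tank.S_su"], closed, tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("gas phase balances fluxes and is silent when empty", {
  p <- adm1_params()
  cfg <- plant_config()
  empty <- stats::setNames(c(0, 0, 0), gas_names())
  g0 <- gas_phase_rhs(empty, c(h2 = 0, ch4 = 0, co2 = 0), cfg, p)
  expect_equal(g0$Q_gas, 0)
  expect_equal(unname(g0$deriv), c(0, 0, 0))

  # steady state: outflow of each species equals its transfer inflow
  gas <- stats::setNames(c(2e-5, 1.8, 0.014), gas_names())
  pp <- gas_partial_pressures(gas, p)
  expect_gt(pp[["P"]], cfg$P_atm)
  Q <- cfg$k_p * (pp[["P"]] - cfg$P_atm)
  totals <- c(h2 = gas[[1]] * Q, ch4 = gas[[2]] * Q, co2 = gas[[3]] * Q)
  g <- gas_phase_rhs(gas, totals, cfg, p)
  expect_equal(unname(g$deriv), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(g$Q_gas, Q)
})

test_that("effluent COD equals the enumerated hand sum", {
  cfg <- plant_config()
  s <- populated_state()
  hand_sol <- s[["S_su"]] + s[["S_aa"]] + s[["S_fa"]] + s[["S_va"]] +
    s[["S_bu"]] + s[["S_pro"]] + s[["S_ac"]] + s[["S_h2"]] +
    s[["S_ch4"]] + s[["S_I"]]
  att <- (750 / 4500) / (40 + 750 / 4500)
  hand_part <- att * (s[["X_c"]] + s[["X_ch"]] + s[["X_pr"]] + s[["X_li"]] +
    s[["X_su"]] + s[["X_aa"]] + s[["X_fa"]] + s[["X_c4"]] + s[["X_pro"]] +
    s[["X_ac"]] + s[["X_h2"]] + s[["X_I"]])
  expect_equal(effluent_cod(s, 4500, cfg), hand_sol + hand_part,
               tolerance = 1e-12)

  expect_equal(effluent_cod(new_state(), 4500, cfg), 0)
  expect_equal(effluent_cod(new_state(S_I = 0.198), 4500, cfg), 0.198)
})

test_that("zero-COD influent with no biomass passes through inert-free", {
  p <- adm1_params()
  inf <- new_state(S_IN = 0.01, S_IC = 0.03, S_cat = 0.04, S_an = 0.02)
  cfg <- plant_config()
  y0 <- initial_plant_state(inf, cfg, p, seed_biomass = 0)
  y0[105:107] <- 0                      # no initial biogas blanket
  y0[8:9 + rep(c(0, 26, 52, 78), each = 2)] <- 0   # no dissolved gas seed
  res <- simulate_plant(constant_influent_series(inf, 10), params = p,
                        config = cfg, init = y0)
  expect_lt(max(res$COD_eff_kg_m3), 1e-8)
  expect_lt(max(res$Q_gas_Nm3_d), 1e-10)
})

test_that("influent inert soluble COD passes through the reaction-free plant unchanged", {
  # with biochemistry off nothing can produce or consume S_I, so the
  # plant hydraulics must deliver the influent value exactly
  p <- adm1_params()
  inf <- table1_influent()
  cfg <- plant_config(tank_mask = rep(0, 19), reactor_mask = rep(0, 19))
  y0 <- initial_plant_state(inf, cfg, p, seed_biomass = 0)
  res <- simulate_plant(constant_influent_series(inf, 30), params = p,
                        config = cfg, init = y0)
  expect_equal(tail(res$S_I_eff, 1), inf[["S_I"]], tolerance = 1e-7)
  # and in the live plant the effluent S_I exceeds the influent only by
  # the small inert production from decayed-biomass composites
  live <- quick_run(60)
  expect_gt(tail(live$S_I_eff, 1), inf[["S_I"]] - 1e-9)
  expect_lt(tail(live$S_I_eff, 1), inf[["S_I"]] * 1.06)
})

test_that("steady-state COD closes: influent load = effluent + gas + accumulation", {
  p <- adm1_params("estimated")
  cfg <- plant_config()
  inf <- table1_influent()
  Q <- cfg$Q_inf
  res <- quick_run(150, params = p, config = cfg, states = TRUE)
  S <- attr(res, "states")
  w <- cod_weights()
  inventory <- function(k) {
    vs <- vapply(0:3, function(v) sum(S[k, v * 26 + 1:26] * w), numeric(1))
    sum(vs * c(cfg$V_a, cfg$V_c, cfg$V_c, cfg$V_c)) +
      (S[k, 105] + S[k, 106]) * cfg$V_gas
  }
  n <- nrow(S)
  in_load <- Q * sum(inf * w)
  out_load <- Q * res$COD_eff_kg_m3[n]
  gas_load <- res$Q_gas_raw[n] * (S[n, 105] + S[n, 106])
  accum <- inventory(n) - inventory(n - 1)
  closure <- (in_load - out_load - gas_load - accum) / in_load
  expect_lt(abs(closure), 0.005)
})

test_that("the stiff solution agrees with fixed-step RK4 integration", {
  # the fastest mode is hydrogen uptake (tau ~ K_S_h2/(k_m_h2 X_h2), a
  # few 1e-6 d), so the explicit step must sit below it
  p <- adm1_params("estimated")
  cfg <- plant_config()
  inf <- table1_influent()
  y0 <- initial_plant_state(inf, cfg, p)
  pp <- adplant:::.pack_plant_parms(p, cfg, inf, cfg$Q_inf)
  t_end <- 0.05
  stiff <- deSolve::vode(y = as.numeric(y0), times = c(0, t_end),
                         func = "plant_deriv", parms = pp,
                         dllname = "adplant", initfunc = "plant_init",
                         nout = 7, rtol = 1e-8, atol = 1e-12)
  rk <- deSolve::rk4(y = as.numeric(y0), times = seq(0, t_end, by = 2e-6),
                     func = "plant_deriv", parms = pp, dllname = "adplant",
                     initfunc = "plant_init", nout = 7)
  a <- stiff[nrow(stiff), 2:108]
  b <- rk[nrow(rk), 2:108]
  expect_lt(max(abs(a - b) / pmax(abs(b), 1e-6)), 1e-4)
})

test_that("a fully tank-masked plant produces no methane at all", {
  p <- adm1_params("estimated")
  cfg <- plant_config(reactor_mask = process_mask("tank"))
  res <- quick_run(30, params = p, config = cfg, states = TRUE)
  S <- attr(res, "states")
  # methane stays at numerical zero everywhere (integrator noise only),
  # nine orders below the methanogenic plant's ~1.6 kgCOD m^-3 headspace
  expect_lt(max(abs(S[, "tank.S_ch4"])), 1e-9)
  expect_lt(max(abs(S[, "S_gas_ch4"])), 1e-6)
  expect_lt(max(res$Q_ch4_Nm3_d), 1e-6)
})

test_that("trajectories keep every concentration nonnegative", {
  res <- quick_run(40, states = TRUE)
  S <- attr(res, "states")
  expect_gt(min(S), -1e-9)   # checked, not clipped
  expect_true(all(res$P_gas > 0))
  expect_true(all(res$Q_gas_Nm3_d >= 0))
  expect_true(all(res[, c("pH_tank", "pH_c1", "pH_c2", "pH_c3")] > 0 &
                  res[, c("pH_tank", "pH_c1", "pH_c2", "pH_c3")] < 14))
})
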