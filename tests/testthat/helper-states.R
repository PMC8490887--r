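# Shared fixtures: all built in code, no stored data.

# a fully populated, chemically plausible digester state
populated_state <- function() {
  new_state(
    S_su = 0.12, S_aa = 0.005, S_fa = 0.10, S_va = 0.012, S_bu = 0.014,
    S_pro = 0.018, S_ac = 0.20, S_h2 = 2.4e-7, S_ch4 = 0.055,
    S_IC = 0.08, S_IN = 0.01, S_I = 0.198,
    X_c = 0.3, X_ch = 0.03, X_pr = 0.02, X_li = 0.03, X_su = 0.42,
    X_aa = 1.18, X_fa = 0.24, X_c4 = 0.43, X_pro = 0.14, X_ac = 0.76,
    X_h2 = 0.32, X_I = 2.0, S_cat = 0.04, S_an = 0.02)
}

# random feasible states for property sweeps
random_states <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    s <- new_state()
    s[soluble_names()] <- stats::runif(12, 0, 2)
    s["S_h2"] <- stats::runif(1, 0, 1e-5)
    s["S_IC"] <- stats::runif(1, 1e-3, 0.15)
    s["S_IN"] <- stats::runif(1, 1e-4, 0.05)
    s[particulate_names()] <- stats::runif(12, 0, 3)
    s["S_cat"] <- stats::runif(1, 0, 0.08)
    s["S_an"] <- stats::runif(1, 0, 0.08)
    s
  })
}

# inhibition vector representing "no inhibition"
no_inhibition <- function() {
  c(I_pH_aa = 1, I_pH_ac = 1, I_pH_h2 = 1, I_IN_lim = 1,
    I_h2_fa = 1, I_h2_c4 = 1, I_h2_pro = 1, I_nh3 = 1)
}

table1_influent <- function(...) fractionate(fixture_table1(), ...)

# small constant-influent plant run shared across tests
quick_run <- function(days, params = adm1_params("estimated"),
                      config = plant_config(), ...) {
  simulate_plant(constant_influent_series(table1_influent(), days,
                                          config$Q_inf),
                 params = params, config = config, ...)
}
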