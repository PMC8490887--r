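#!/usr/bin/env Rscript
# Baseline plant simulation: 150 days on the constant assay-mean influent
# with the field-calibrated kinetics.
#
# Finding: the train settles near effluent COD ~0.35 kg m^-3 (63% removal
# against the 0.935 influent), biogas ~1.26e3 Nm^3 d^-1 at ~73% CH4, with
# reactor pH ~6.9 and tank pH ~7.2; the pre-acidification tank conserves
# COD (effluent 0.935) and produces no methane. The day-150 COD balance
# (influent = effluent + gas + inventory change) closes within 0.5%.

suppressMessages(library(adplant))
dir.create("results", showWarnings = FALSE)

params <- adm1_params("estimated")
config <- plant_config()
influent <- fractionate(fixture_table1())
series <- constant_influent_series(influent, 150)
res <- simulate_plant(series, params = params, config = config,
                      states = TRUE)

n <- nrow(res)
cat("day-150 operating point:\n")
print(round(res[n, c("COD_eff_kg_m3", "Q_gas_Nm3_d", "Q_ch4_Nm3_d",
                     "COD_preacid_kg_m3", "pH_tank", "pH_c3", "P_gas")], 4))
cat(sprintf("COD removal: %.1f%%\n",
            100 * (1 - res$COD_eff_kg_m3[n] / sum(influent * cod_weights()))))
cat(sprintf("CH4 share of biogas: %.1f%%\n",
            100 * res$Q_ch4_Nm3_d[n] / res$Q_gas_Nm3_d[n]))

# COD closure audit at the end of the run
S <- attr(res, "states")
w <- cod_weights()
inv <- function(k) {
  vs <- vapply(0:3, function(v) sum(S[k, v * 26 + 1:26] * w), numeric(1))
  sum(vs * c(config$V_a, rep(config$V_c, 3))) +
    (S[k, 105] + S[k, 106]) * config$V_gas
}
in_load <- config$Q_inf * sum(influent * w)
out_load <- config$Q_inf * res$COD_eff_kg_m3[n]
gas_load <- res$Q_gas_raw[n] * (S[n, 105] + S[n, 106])
closure <- (in_load - out_load - gas_load - (inv(n) - inv(n - 1))) / in_load
cat(sprintf("steady-state COD closure residual: %.3f%% of influent load\n",
            100 * closure))

write_series_csv(res[, 1:12], "results/simulation_daily.csv")
write_state_snapshot(S[n, ], "results/simulation_final_state.txt")
write_manifest("results/02_simulate_plant.manifest.yaml",
               command = "simulate",
               outputs = c("results/simulation_daily.csv",
                           "results/simulation_final_state.txt"),
               extra = list(horizon = 150,
                            cod_closure_residual = as.numeric(closure)))
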