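# adplant

Full-plant anaerobic digestion modelling for deinking-pulp (DIP)
wastewater, built on a modified Anaerobic Digestion Model No. 1 (ADM1).

Recycled-paper mills treat their high-COD deinking wastewater in
anaerobic trains: a short-retention **pre-acidification tank** followed
by an **internal-circulation (IC) high-rate reactor**. This package is
for process modellers and plant engineers who want to simulate such a
train at full scale, screen which kinetic constants actually matter,
and calibrate them against routine plant records (daily effluent COD
and biogas flow).

## The model

- **Biochemistry** — ADM1: 19 processes (disintegration, three
  first-order hydrolyses, eight Monod uptakes
  `rho = k_m * S/(K_S + S) * X * I` with pH/H2/NH3/N regulation, seven
  biomass decays) over 24 COD and inorganic species plus two strong-ion
  pools per vessel. Acid-base/pH is solved algebraically from the
  charge balance at every evaluation; H2, CH4 and CO2 exchange with the
  headspace by two-film transfer `rho_T = k_L a (S_liq − K_H p_gas)`.
- **Hydrodynamics** — the tank is a plain CSTR
  (`dS/dt = Q/V_a (S_in − S) + Σ ν ρ`, V_a = 750 m³, HRT ≈ 4 h) running
  15 of the 19 processes: methanogenic uptakes and methanogen decays
  are masked off, so the tank can produce no methane — a structural
  property the simulation preserves exactly. The IC reactor is three
  CSTRs in series (750 m³ each, HRT ≈ 8 h) with extended solids
  retention: particulates wash out through the denominator
  `t_res,X + V_c/Q` (t_res,X = 40 d, so SRT ≈ 40 d), all 19 processes
  active, one shared 250 m³ headspace vented through a near-isobaric
  overpressure relief.
- **Influent** — a routine wastewater assay (total/soluble COD,
  monosaccharide, VFA, surfactant, inert) is fractionated into the
  ADM1 state; the packaged plant assay splits its soluble COD ~49%
  monosaccharide, ~23% VFA (as acetate), ~23% inert, ~6% surfactant,
  with the suspended-solids COD as particulate carbohydrate.
- **Sensitivity & calibration** — Monte-Carlo screening of the 18
  kinetic constants (partial correlation, standardized regression,
  Pearson correlation against effluent COD and biogas flow), then
  bounded Levenberg–Marquardt calibration of the six sensitive
  propionate/acetate/hydrogen constants on a relative
  sum-of-squares objective, with a start-centred lognormal prior that
  stabilises the ratio-unidentifiable Monod pairs (see the methods
  vignette).
- **Synthetic records** — the plant's field record is not public, so a
  seeded generator produces statistically matched 250-day records
  (AR(1) influent around the assay means/SDs, 150-day calibration +
  100-day validation windows, multiplicative lognormal observation
  noise) on which the whole pipeline is exercised end-to-end.

## Worked example

```r
library(adplant)

# influent from the packaged plant assay
influent <- fractionate(fixture_table1())
round(influent[influent > 0], 4)
#>   S_su   S_ac   S_IC   S_IN    S_I   X_ch   X_li  S_cat   S_an
#> 0.4154 0.1978 0.0300 0.0100 0.1979 0.0721 0.0518 0.0400 0.0200

# 150 days of the full train under the calibrated kinetics
res <- simulate_plant(constant_influent_series(influent, 150),
                      params = adm1_params("estimated"))
round(tail(res, 1)[, c("COD_eff_kg_m3", "Q_gas_Nm3_d", "Q_ch4_Nm3_d",
                       "COD_preacid_kg_m3", "pH_c3")], 3)
#>     COD_eff_kg_m3 Q_gas_Nm3_d Q_ch4_Nm3_d COD_preacid_kg_m3 pH_c3
#> 150         0.347    1258.527     921.498             0.935  6.92
```

Reading: from a 0.935 kgCOD m⁻³ influent at 4500 m³ d⁻¹ the reactor
settles near 0.35 kgCOD m⁻³ effluent (~63% COD removal — the remainder
is mostly the 0.198 inert plus dissolved methane), producing ~1.26 ×
10³ Nm³ d⁻¹ of biogas at ~73% CH₄; the pre-acidification tank passes
COD through unchanged (0.935) and makes no gas.

The study itself is laid out as numbered drivers under `analysis/`
(influent characterisation → baseline simulation → Monte-Carlo
sensitivity → calibration on a synthetic record → held-out
validation), each writing its tables to `results/`.

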