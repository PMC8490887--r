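# Stoichiometric, physico-chemical and regulatory constants of the ADM1
# build (IWA benchmark parameterisation, mesophilic). Versioned: the
# loader verifies this file against the md5 recorded in
# stoichiometry.yaml.md5 before use.
version: 1
# composite disintegration split (COD fractions of X_c)
f_sI_xc: 0.10
f_ch_xc: 0.20
f_pr_xc: 0.20
f_li_xc: 0.30
f_xI_xc: 0.20
# lipid hydrolysis split
f_fa_li: 0.95
# acidogenesis product splits (COD fractions)
f_h2_su: 0.19
f_bu_su: 0.13
f_pro_su: 0.27
f_ac_su: 0.41
f_h2_aa: 0.06
f_va_aa: 0.23
f_bu_aa: 0.26
f_pro_aa: 0.05
f_ac_aa: 0.40
# biomass yields (kgCOD X per kgCOD substrate)
Y_su: 0.10
Y_aa: 0.08
Y_fa: 0.06
Y_c4: 0.06
Y_pro: 0.04
Y_ac: 0.05
Y_h2: 0.06
# first-order decay rates (d^-1)
k_dec_X_su: 0.02
k_dec_X_aa: 0.02
k_dec_X_fa: 0.02
k_dec_X_c4: 0.02
k_dec_X_pro: 0.02
k_dec_X_ac: 0.02
k_dec_X_h2: 0.02
# regulation / inhibition
K_S_IN: 1.0e-04       # nitrogen limitation half constant, kmolN m^-3
K_I_h2_fa: 5.0e-06    # kgCOD m^-3
K_I_h2_c4: 1.0e-05
K_I_h2_pro: 3.5e-06
K_I_nh3: 1.8e-03      # kmolN m^-3
pH_UL_aa: 5.5
pH_LL_aa: 4.0
pH_UL_ac: 7.0
pH_LL_ac: 6.0
pH_UL_h2: 6.0
pH_LL_h2: 5.0
# acid-base: pKa at 298.15 K; co2/IN/w corrected to T by van 't Hoff
pK_a_va: 4.86
pK_a_bu: 4.82
pK_a_pro: 4.88
pK_a_ac: 4.76
pK_a_co2: 6.35
pK_a_IN: 9.25
dH_K_a_co2: 7646.0    # J mol^-1
dH_K_a_IN: 51965.0
dH_K_w: 55900.0
# Henry constants at 298.15 K (M bar^-1) with van 't Hoff enthalpies
K_H_h2_base: 7.8e-04
K_H_ch4_base: 1.4e-03
K_H_co2_base: 3.5e-02
dH_K_H_h2: -4180.0
dH_K_H_ch4: -14240.0
dH_K_H_co2: -19410.0
# gas-liquid transfer and operating temperature
k_L_a: 200.0          # d^-1
T_op: 308.15          # K
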