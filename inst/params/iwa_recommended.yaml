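# The 18 analysed kinetic parameters of the ADM1 build:
# 4 first-order disintegration/hydrolysis constants (d^-1) and the 7
# Monod pairs (k_m in kgCOD kgCOD^-1 d^-1, K_S in kgCOD m^-3).
# IWA-recommended values for a mesophilic (35 degC) high-rate reactor.
k_dis: 0.5
k_hyd_ch: 10.0
k_hyd_pr: 10.0
k_hyd_li: 10.0
k_m_su: 30.0
K_S_su: 0.5
k_m_aa: 50.0
K_S_aa: 0.3
k_m_fa: 6.0
K_S_fa: 0.4
k_m_c4: 20.0
K_S_c4: 0.2
k_m_pro: 13.0
K_S_pro: 0.3
k_m_ac: 8.0
K_S_ac: 0.15
k_m_h2: 35.0
K_S_h2: 2.5e-05
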