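# Field-calibrated values of the six sensitive kinetic parameters
# (propionate, acetate and hydrogen Monod pairs) for the deinking-pulp
# wastewater plant; all other kinetics stay at the recommended set.
k_m_pro: 12.02
K_S_pro: 0.35
k_m_ac: 4.26
K_S_ac: 0.26
k_m_h2: 16.62
K_S_h2: 3.21e-05
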