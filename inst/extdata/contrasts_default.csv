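key,value
v_chain,350
v_head_sds,60
v_head_c12e8,520
v_protein,22335.60278977084
b_chain,2.733402091e-11
b_head_sds,1.662584777e-11
b_head_c12e8,5.664060003e-11
b_protein,2.76101790594e-9
rho_solvent,94119206020.00002
protein_mass,18300
drho_m,20000000000
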