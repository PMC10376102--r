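angle	method	mae	pcc	mae_deg	mae_improvement	pcc_improvement	average_improvement
phi	baseline_nn	0.126	0.598	22.7	NA	NA	NA
phi	gbt_selected	0.114	0.746	NA	10.08	24.83	17.45
psi	baseline_nn	0.135	0.602	24.3	NA	NA	NA
psi	gbt_selected	0.123	0.737	NA	9.93	22.37	16.15
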