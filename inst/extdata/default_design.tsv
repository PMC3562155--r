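strain	condition	fruB_induced	r_fru
delta_fruB	CAA	FALSE	0
delta_ptsO	CAA	FALSE	0
delta_ptsP	CAA	FALSE	0
WT	CAA	FALSE	0
delta_fruB	CAA_fructose	TRUE	0
delta_ptsO	CAA_fructose	TRUE	0.05
delta_ptsP	CAA_fructose	TRUE	0.05
WT	CAA_fructose	TRUE	0.05
delta_fruB	CAA_glucose	TRUE	0
delta_ptsO	CAA_glucose	TRUE	0
delta_ptsP	CAA_glucose	TRUE	0
WT	CAA_glucose	TRUE	0
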