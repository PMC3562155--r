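# biomass=R_biomass
# ngam=R_ngam
# uptakes=R_fruPTS,R_glcED,EX_caa
id	equation	lb	ub
R_fruPTS	pep -> upper + pyr	0	10
R_glcED	-> upper	0	0
EX_caa	-> aa	0	10
R_aa_oaa	aa -> oaa	0	1000
R_oaa_pyr	oaa -> pyr	0	1000
R_emp	upper -> 2 pep	0	1000
R_gng	2 pep + atp -> upper	0	1000
R_pyk	pep -> pyr + atp	0	1000
R_pps	pyr + 2 atp -> pep	0	1000
R_pc	pep -> oaa	0	1000
R_pdh	pyr -> accoa	0	1000
R_tca	accoa -> 2 atp	0	1000
R_ngam	atp ->	0.5	1000
R_biomass	0.2 upper + 0.3 pep + 0.3 pyr + 0.2 oaa + 0.3 accoa + 1.5 atp ->	0	1000
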