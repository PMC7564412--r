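# 211At decay chain constants (ENSDF / MIRD decay schemes).
# One decay branch per row. alpha_energy_mev is 0 for branches that emit no
# alpha particle at that step (the EC branch to 211Po). 211Po alpha-decays to
# stable 207Pb; 207Bi (T1/2 31.6 y) is terminal on the pharmacokinetic scale.
# half_life_h is the PARENT half-life: 211At 7.214 h, 211Po 0.516 s.
parent	daughter	branch_fraction	alpha_energy_mev	half_life_h
At-211	Bi-207	0.4180	5.8695	7.214
At-211	Po-211	0.5820	0.0	7.214
Po-211	Pb-207	1.0000	7.4503	0.0001433
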