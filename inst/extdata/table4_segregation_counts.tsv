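# Observed regrowth (R) / non-regrowth (NR) segregation counts per population.
population	total	n_R	n_NR
B73-Zd_F2	134	81	53
B73-Zd_F3	72	52	20
Zd-RF_F2	160	92	68
Zd-RF_F3-3	15	12	3
Zd-RF_F3-5	16	9	7
Zd-RF_F3-9	16	13	3
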