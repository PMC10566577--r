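class	slope_maternal	intercept_maternal	slope_paternal	intercept_paternal
A>C	0.010	0.25	0.030	0.9
A>G	0.085	1.10	0.320	3.1
A>T	0.012	0.30	0.055	1.0
C>A	0.018	0.45	0.075	1.6
C>G	0.024	0.30	0.085	1.2
C>T	0.060	1.00	0.220	2.8
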