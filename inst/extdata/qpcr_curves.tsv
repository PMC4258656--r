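event	r_squared	slope
GTS-40-3-2	1.000	-3.411
TC1507	0.997	-3.246
MON1445	0.998	-3.329
OXY235	0.999	-3.409
KMD	0.999	-3.226
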