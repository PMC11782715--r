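# Scalar J-couplings (Hz) between proton groups of spin_systems.tsv.
# Symmetric; groups not listed are uncoupled. Negative values are geminal.
metabolite	group_a	group_b	j_hz
NAA	2	3	3.861
NAA	2	4	9.821
NAA	3	4	-15.592
Cho	2	3	5.000
Glu	1	2	7.331
Glu	1	3	4.651
Glu	2	3	-14.849
Glu	2	4	6.413
Glu	2	5	8.406
Glu	3	4	8.478
Glu	3	5	6.875
Glu	4	5	-15.915
Gln	1	2	5.847
Gln	1	3	6.500
Gln	2	3	-14.504
Gln	2	4	9.165
Gln	2	5	6.347
Gln	3	4	6.324
Gln	3	5	9.209
Gln	4	5	-15.371
Ins	1	2	2.889
Ins	2	3	3.006
Ins	3	4	9.997
Ins	4	5	9.485
Ins	5	6	9.482
Ins	1	6	9.998
Lac	1	2	6.933
GABA	1	2	7.300
GABA	2	3	7.900
Tau	1	2	6.742
Asp	1	2	3.647
Asp	1	3	9.107
Asp	2	3	-17.426
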