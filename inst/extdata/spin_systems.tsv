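# Proton spin-system catalog for common brain metabolites.
# Chemical shifts and J-couplings from standard published 1H metabolite tables
# (values in ppm and Hz). One row per proton group; groups of one metabolite
# are coupled according to j_couplings.tsv. t2_s is the mono-exponential decay
# constant applied at simulation time.
metabolite	group	shift_ppm	n_protons	t2_s
NAA	1	2.0080	3	0.18
NAA	2	4.3817	1	0.14
NAA	3	2.6727	1	0.14
NAA	4	2.4863	1	0.14
NAAG	1	2.0420	3	0.16
Cr	1	3.0270	3	0.15
Cr	2	3.9130	2	0.12
Cho	1	3.1850	9	0.18
Cho	2	4.0540	2	0.13
Cho	3	3.5010	2	0.13
Glu	1	3.7433	1	0.13
Glu	2	2.0375	1	0.13
Glu	3	2.1200	1	0.13
Glu	4	2.3378	1	0.13
Glu	5	2.3520	1	0.13
Gln	1	3.7530	1	0.13
Gln	2	2.1290	1	0.13
Gln	3	2.1090	1	0.13
Gln	4	2.4320	1	0.13
Gln	5	2.4540	1	0.13
Ins	1	3.5217	1	0.14
Ins	2	4.0538	1	0.14
Ins	3	3.5217	1	0.14
Ins	4	3.6144	1	0.14
Ins	5	3.2690	1	0.14
Ins	6	3.6144	1	0.14
Lac	1	4.0974	1	0.20
Lac	2	1.3142	3	0.20
GABA	1	2.2840	2	0.13
GABA	2	1.8890	2	0.13
GABA	3	3.0128	2	0.13
Tau	1	3.4206	2	0.15
Tau	2	3.2459	2	0.15
Gly	1	3.5480	2	0.16
Asp	1	3.8914	1	0.12
Asp	2	2.8011	1	0.12
Asp	3	2.6533	1	0.12
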