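name	family	degree	betweenness	closeness	rns
miR-203a-3p	miR-203	25	0.175	0.394	9.847
miR-200c-3p	miR-200	24	0.063	0.386	8.421
miR-200a-3p	miR-200	25	0.083	0.394	7.609
miR-141-3p	miR-200	28	0.110	0.400	7.127
miR-200b-3p	miR-200	23	0.058	0.390	6.522
miR-182-5p	miR-183	17	0.083	0.378	6.140
miR-429	miR-200	28	0.098	0.400	5.091
miR-183-5p	miR-183	15	0.063	0.361	4.426
H19	lncRNA	13	0.145	0.428	5.561
CLLU1	lncRNA	17	0.195	0.453	5.500
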