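# pnmrlipids shift library, version 1
# 31P chemical shifts, 324 MHz, modified CUBO solvent, PC referenced to 0.00 ppm
# columns: lipid_class, ppm_low, ppm_high, provenance, ambiguous
lipid_class	ppm_low	ppm_high	provenance	ambiguous
LPA	5.9	6.1	soy lecithin and mouse tissue survey, 324 MHz CUBO	FALSE
PA	5.2	5.4	soy lecithin and mouse tissue survey, 324 MHz CUBO	FALSE
LPI	1.55	1.65	soy lecithin and mouse tissue survey, 324 MHz CUBO	FALSE
PG	1.20	1.28	soy lecithin and mouse tissue survey, 324 MHz CUBO	FALSE
PG	0.95	1.15	soy lecithin and mouse tissue survey; adduct-scan caption assigns this interval to PI; alternate: PI	FALSE
SM	0.80	0.85	soy lecithin and mouse tissue survey, 324 MHz CUBO	FALSE
PE	0.57	0.60	busy region 0.45-0.60 ppm; alternates: PE-plasmalogen, PS, LPC	TRUE
PE	0.55	0.57	busy region 0.45-0.60 ppm; alternates: PE-plasmalogen, PS, LPC	TRUE
PE	0.51	0.55	busy region 0.45-0.60 ppm; alternates: PE-plasmalogen, PS, LPC	TRUE
PE	0.48	0.50	busy region 0.45-0.60 ppm; alternates: PE-plasmalogen, PS, LPC	TRUE
LPC	0.43	0.46	busy region 0.45-0.60 ppm; alternates: PE-plasmalogen, PS	TRUE
UNK1	0.25	0.30	unidentified resonance, soy lecithin	FALSE
UNK2	0.16	0.19	unidentified resonance, soy lecithin	FALSE
PC	0.00	0.00	calibration reference, pinned to 0.00 ppm	FALSE
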