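# Published qPCR primer efficiencies (percent) and amplicon melt temperatures
# (deg C) for the candidate reference genes in four Schistocerca species,
# estimated from 10-fold dilution series. Target-gene primers (piceifrons only)
# are included with species set to "piceifrons" and role "target".
gene	role	species	tm_c	efficiency_pct
Act5C	reference	piceifrons	82.5	102.13
Act5C	reference	americana	82.5	105.84
Act5C	reference	cubense	82.3	97.65
Act5C	reference	nitens	82.0	104.21
Tub	reference	piceifrons	81.5	103.15
Tub	reference	americana	81.5	100.30
Tub	reference	cubense	81.5	104.90
Tub	reference	nitens	82.0	96.18
Hsp70	reference	piceifrons	80.5	100.18
Hsp70	reference	americana	80.3	105.06
Hsp70	reference	cubense	80.3	102.16
Hsp70	reference	nitens	80.0	104.14
RIBL5	reference	piceifrons	83.7	99.83
RIBL5	reference	americana	83.7	101.20
RIBL5	reference	cubense	83.5	96.78
RIBL5	reference	nitens	84.0	102.11
EF2	reference	piceifrons	79.3	100.00
EF2	reference	americana	79.0	102.73
EF2	reference	cubense	79.3	101.33
EF2	reference	nitens	79.3	98.98
GAPDH	reference	piceifrons	84.0	102.28
GAPDH	reference	americana	84.0	97.74
GAPDH	reference	cubense	83.7	98.57
GAPDH	reference	nitens	83.3	98.53
Ann	reference	piceifrons	79.7	100.10
Ann	reference	americana	79.7	102.39
Ann	reference	cubense	79.5	99.47
Ann	reference	nitens	79.5	104.14
Arm	reference	piceifrons	82.3	109.85
Arm	reference	americana	82.7	101.41
Arm	reference	cubense	82.5	99.27
Arm	reference	nitens	82.5	92.12
ast	target	piceifrons	81.3	96.84
at	target	piceifrons	85.0	91.26
SPPP-4	target	piceifrons	83.5	91.19
SPPP-5	target	piceifrons	87.0	94.51
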