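gene	hgvs_p_pattern	recurrence_count	predefined
DNMT3A	p\.Arg882	2500	yes
DNMT3A		0	no
TET2		0	no
ASXL1	p\.Gly646	400	yes
ASXL1		0	no
PPM1D		0	no
TP53	p\.Arg175His	200	yes
TP53		0	no
JAK2	p\.Val617Phe	3000	yes
SF3B1	p\.Lys700Glu	450	yes
SRSF2	p\.Pro95	500	yes
CBL	p\.Arg420	60	no
GNB1	p\.Lys57Glu	40	yes
KRAS	p\.Gly12	10	no
IDH2	p\.Arg140Gln	150	yes
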