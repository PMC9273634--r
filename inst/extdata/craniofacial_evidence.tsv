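gene	mouse_ko	cnv_report	snv_report
ACTL6A	lethal	TRUE	FALSE
ARHGAP10	craniofacial	TRUE	FALSE
MINK1	craniofacial	TRUE	FALSE
TMEM5	craniofacial	TRUE	FALSE
TTN	craniofacial	TRUE	FALSE
ACAN	cleft	TRUE	FALSE
DHRS3	cleft	TRUE	FALSE
DLX6	craniofacial	TRUE	FALSE
EPHB2	craniofacial	TRUE	FALSE
FKBP10	none	TRUE	TRUE
KMT2D	cleft	TRUE	FALSE
RECQL4	cleft	TRUE	FALSE
SEMA3C	craniofacial	TRUE	FALSE
SEMA4D	craniofacial	TRUE	FALSE
SHH	cleft	TRUE	TRUE
TP63	cleft	TRUE	TRUE
TULP4	none	TRUE	TRUE
MMP9	none	FALSE	FALSE
JUNB	none	FALSE	FALSE
JUP	none	FALSE	FALSE
DNAJC3	none	FALSE	FALSE
PAX9	none	FALSE	FALSE
MSX1	none	FALSE	FALSE
IRF6	none	FALSE	FALSE
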