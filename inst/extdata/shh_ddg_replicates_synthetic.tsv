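variant	replicate	dg_folded	dg_unfolded
SHH_p.Ser362Leu	1	-100.237	-105.000
SHH_p.Ser362Leu	2	-100.016	-105.000
SHH_p.Ser362Leu	3	-99.795	-105.000
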