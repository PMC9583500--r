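from	to
Her2	EGFR
EGFR	cMet
cMet	MUC1
MUC1	ECad
ECad	EpCAM
EpCAM	CD44
CD44	CD24
CD44	Vim
PDL1	AXL
AXL	EGFR
Her2	cMet
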