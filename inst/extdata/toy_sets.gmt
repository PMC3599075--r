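prostate_markers	toy prostate gene set	AR	KLK3	ACPP	TMPRSS2
housekeeping	toy housekeeping set	ACTB	FKBP5
epithelial	toy epithelial set	EPCAM	KLK3
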