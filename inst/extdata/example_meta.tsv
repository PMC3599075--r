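sample_id	group	day	replicate	qc_excluded	qc_reason
c1_r01	1	1	1	FALSE	
c1_r02	1	2	2	FALSE	
c10_r01	10	1	1	FALSE	
c10_r02	10	2	2	FALSE	
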