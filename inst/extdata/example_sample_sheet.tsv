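individual	fwd_mid	rev_mid_rep1	rev_mid_rep2
ind_001	ATGACAGGCC	GCCTTCCACC	CCAGGTCGGT
ind_002	GGAAACCCCG	GCCTTCCACC	CCAGGTCGGT
ind_003	AGAAAACAAC	GCCTTCCACC	CCAGGTCGGT
ind_004	CCATGATGCC	GCCTTCCACC	CCAGGTCGGT
ind_005	CCGTTTCTAG	GCCTTCCACC	CCAGGTCGGT
ind_006	CATTAGTCCG	GCCTTCCACC	CCAGGTCGGT
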