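sample_id	condition	timepoint	fraction	replicate
condA_r1	condA	1	total	1
condA_r2	condA	1	total	2
condB_r1	condB	2	total	1
condB_r2	condB	2	total	2
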