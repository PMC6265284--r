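feature_id	condA_r1	condA_r2	condB_r1	condB_r2
TX_KNOWN	10	12	11	13
TX_LNC1	8	9	7	8
TX_SENSE	4	5	4	6
TX_SHORT	5	5	6	5
TX_CODING	20	22	19	21
TX_LNC2	3	4	3	5
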