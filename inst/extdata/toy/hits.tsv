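TX_CODING	SP_00001	80	100	0	0	1	300	1	100	1e-20	0	80	80
TX_LNC1	SP_00002	99	39	0	0	1	117	1	39	1e-50	0	99	99
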