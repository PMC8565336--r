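duplex_id	target	tm_c	tm_sd	parent_id	reference_id
D1	Hao1	66.5	0.0	NA	NA
D2	Hao1	58.6	0.0	D1	NA
D3	Hao1	61.1	0.0	D1	D2
D4	Ttr	66.0	0.0	NA	NA
D5	Ttr	59.0	0.0	D4	NA
D6	Ttr	62.3	0.0	D4	D5
D7	F12	79.3	0.4	NA	NA
D8	F12	71.3	0.4	D7	NA
D9	F12	73.3	0.4	D7	D8
D10	Ttr	70.0	0.7	NA	NA
D11	Ttr	64.0	0.7	D10	NA
D12	Ttr	67.3	0.4	D10	D11
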