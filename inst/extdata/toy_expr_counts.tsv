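gene_id	S1	S2
g_low	2	2
g_edge	5	0
g_high	10	20
g_percell	4	30
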