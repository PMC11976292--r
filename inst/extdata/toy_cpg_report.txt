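chr1	100	+	5	5	CG	CGA
chr1	150	+	3	0	CG	CGT
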