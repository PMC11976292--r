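chr1	10	11	50.0	5	5
chr1	20	21	100.0	10	0
chr1	30	31	0.0	0	10
chr1	40	41	25.0	2	6
chr1	100	101	50.0	3	3
chr1	200	201	50.0	4	4
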