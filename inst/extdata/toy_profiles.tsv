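elocus_id	sample_id	epipolymorphism	avg_methylation	depth
L1	S1	0.2	0.5	10
L1	S2	0.2	0.5	10
L1	S3	0.2	0.5	10
L1	S4	0.2	0.5	10
L1	S5	0.2	0.5	10
L1	S6	0.2	0.5	10
L1	S7	0.2	0.5	9
L1	S8	0.2	0.5	0
L2	S1	0.3	0.5	12
L2	S2	0.3	0.5	12
L2	S3	0.3	0.5	12
L2	S4	0.3	0.5	12
L2	S5	0.3	0.5	12
L2	S6	0.3	0.5	9
L2	S7	0.3	0.5	9
L2	S8	0.3	0.5	9
L3	S1	0.1	0.4	10
L3	S2	0.1	0.4	10
L3	S3	0.1	0.4	10
L3	S4	0.1	0.4	10
L3	S5	0.1	0.4	10
L3	S6	0.1	0.4	10
L3	S7	0.1	0.4	10
L3	S8	0.1	0.4	10
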