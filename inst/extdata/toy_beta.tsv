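feature	T1	T2	T3	N1
f01	0.10	0.90	0.50	0.5
f02	0.10	0.90	0.50	0.5
f03	0.48	0.52	0.50	0.5
f04	0.50	0.50	0.50	0.5
f05	0.50	0.50	0.50	0.5
f06	0.50	0.50	0.50	0.5
f07	0.50	0.50	0.50	0.5
f08	0.50	0.50	0.50	0.5
f09	0.50	0.50	0.50	0.5
f10	0.50	0.50	0.50	0.5
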