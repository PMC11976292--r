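chr1	99	100
chr1	100	101
chr1	201	202
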