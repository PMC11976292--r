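sample_id	patient_id	dnam_age	chrono_age	is_tumour
PA_T1	PA	50	50	TRUE
PA_T2	PA	65	50	TRUE
PB_T1	PB	50	50	TRUE
PB_T2	PB	62.5	50	TRUE
PC_T1	PC	80	50	TRUE
PA_N	PA	40	50	FALSE
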