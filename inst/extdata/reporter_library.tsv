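reporter	state	delta_HN_ppm	delta_N_ppm	delta_CB_ppm
I84	NAC_III	7.00	NA	NA
I84	NAC_III_t	7.17	NA	NA
P146-CB	cis	NA	NA	35.0
P146-CB	trans	NA	NA	32.0
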