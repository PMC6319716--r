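group	transfers	clinical_pregnancies	miscarriages	term
fish_ejaculated	222	49	30	18
fish_surgical	2	1	0	1
ngs_ejaculated	36	17	5	12
combined_ejaculated	3	0	0	0
combined_testicular	3	3	0	3
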