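chr1	99999	101999	gene001	0	+
chr1	198000	200000	gene002	0	-
chr1	299999	301999	gene003	0	+
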