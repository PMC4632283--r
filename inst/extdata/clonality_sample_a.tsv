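# toy 6-probe profile, sample A (gains at p000001, p000003)
chrom	start	end	probe_id	log2ratio
chr1	0	60	p000001	0.6
chr1	1000	1060	p000002	0.02
chr1	2000	2060	p000003	0.8
chr1	3000	3060	p000004	-0.05
chr1	4000	4060	p000005	0.1
chr1	5000	5060	p000006	-0.12
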