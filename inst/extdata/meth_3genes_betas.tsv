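# synthetic 3-gene methylation cohort, gene001 hypomethylated (seed 11)
probe_id	chrom	pos	tumor01	tumor02	tumor03	normal01	normal02	normal03
gene001_cg03	chr1	96364	0.42572157499652635	0.41126360519685223	0.41395593458977265	0.4202679396947415	0.4513697142245522	0.39371727692595593
gene001_cg02	chr1	98143	0.07522202013954213	0.14246322020794752	0.15661125688415434	0.3262209109606924	0.3915232841758193	0.35452473816973007
gene001_cg01	chr1	98920	0.10550205180075091	0.18522055168358575	0.13068408065594606	0.43104588604337263	0.4108584267803698	0.37009761332963026
gene002_cg03	chr1	196181	0.3625332604642767	0.39511091779946617	0.3602288254412037	0.3653947563502946	0.3546394593291594	0.3496916023376862
gene002_cg02	chr1	199083	0.39873304876880405	0.34304109004763145	0.38425277629692467	0.3499659534730232	0.30887484371654356	0.3115964435719524
gene002_cg01	chr1	199864	0.23998167889146127	0.32567495096505306	0.3624328244447739	0.304917733676025	0.34076953432267204	0.3284830724744118
gene003_cg02	chr1	298080	0.46549531727339694	0.46775696009992235	0.5261724880123406	0.5354119491562803	0.5493477185553778	0.4687006616459782
gene003_cg01	chr1	301173	0.5223000762308299	0.5002183817071552	0.4650898949881792	0.47162694980225717	0.4361309864121962	0.4967222654365387
gene003_cg03	chr1	303342	0.5392426479326791	0.45984287914433775	0.49165784474230073	0.4498520459247807	0.4773595266490504	0.4754125497862611
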