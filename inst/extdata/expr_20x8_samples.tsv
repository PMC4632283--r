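sample	class	group
s001	C1	tumor
s002	C1	tumor
s003	C1	tumor
s004	C1	tumor
s005	C2	normal
s006	C2	normal
s007	C2	normal
s008	C2	normal
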