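sample	group
tumor01	tumor
tumor02	tumor
tumor03	tumor
normal01	normal
normal02	normal
normal03	normal
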