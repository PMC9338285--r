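IDH	chr1p19q	ATRX	TERTp	group
positive	positive	negative	positive	Grp1
positive	positive	negative	negative	Grp2
positive	negative	positive	negative	Grp3
positive	negative	negative	negative	Grp4
positive	negative	positive	positive	Grp5
negative	positive	negative	positive	Grp6
negative	negative	negative	positive	Grp7
negative	negative	negative	negative	Grp8
negative	negative	positive	negative	Grp9
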