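species	sequence	age_mya
mouse	SGLE*VTVYGGGVQKGKT	87
tree_shrew	*GLELLRAYVGGVQRGCT	68
lemur	SGLELVRVCGGGAQRGET	61
tarsier	SGLEIMRLCSRDRADGS	58
rhesus	SGLELVRVCGGGVQKGKT	31
tibetan_macaque	SGLELVRVCGGGMQRDKT	31
baboon	SGLELVRVCGGGMQRDKT	31
orangutan	SGLELVRVCGGGMQRGKT	20
gorilla	SGLELVRVWWGYAEG*DR	10
chimpanzee	SGLELVRVCGGGMQRDKT	6
human	SGLELVRVCGGGMQRDKT	0
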