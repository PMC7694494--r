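group	type	match
photosystem_I	prefix	psa
photosystem_II	prefix	psb
cytochrome_b6f	prefix	pet
atp_synthase	prefix	atp
ndh_dehydrogenase	prefix	ndh
rubisco	exact	rbcL
rna_polymerase	prefix	rpo
ribosomal_protein	prefix	rps
ribosomal_protein	prefix	rpl
other	prefix	ycf
other	exact	matK
other	exact	clpP
other	exact	ccsA
other	exact	cemA
other	exact	accD
other	exact	infA
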