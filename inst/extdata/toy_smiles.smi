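benzene	c1ccccc1
toluene	Cc1ccccc1
phenol	Oc1ccccc1
pyridine	c1ccncc1
cyclohexane	C1CCCCC1
piperidine	C1CCNCC1
cyclohexanone	O=C1CCCCC1
naphthalene	c1ccc2ccccc2c1
quinoline	c1ccc2ncccc2c1
indane	C1Cc2ccccc2C1
biphenyl	c1ccc(-c2ccccc2)cc1
diphenylmethane	c1ccc(Cc2ccccc2)cc1
phenoxymethylpyridine	c1ccc(OCc2ccccn2)cc1
p_terphenyl	c1ccc(-c2ccc(-c3ccccc3)cc2)cc1
ibuprofen	CC(C)Cc1ccc(cc1)C(C)C(=O)O
aspirin	CC(=O)Oc1ccccc1C(=O)O
paracetamol	CC(=O)Nc1ccc(O)cc1
caffeine	Cn1cnc2c1c(=O)n(C)c(=O)n2C
fluorene	C1c2ccccc2-c2ccccc21
hexane	CCCCCC
ethanol	CCO
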