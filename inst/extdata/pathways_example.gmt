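pantothenate_coa_biosynthesis	synthetic example set: CoA biosynthesis	pantothenate	coa
pyruvate_metabolism	synthetic example set: pyruvate node	pyruvate	lactate	oxamate	akg
pentose_phosphate_pathway	synthetic example set: PPP / polyol	s7p	sorbitol
tca_amino	synthetic example set: TCA and amino acids	citrate	akg	glutamate	nacetylaspartate
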