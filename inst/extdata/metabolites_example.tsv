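id	name	formula	is_keto_acid	source
water	Water	H2O	FALSE	curated
pyruvate	Pyruvate	C3H4O3	TRUE	curated
lactate	L-Lactate	C3H6O3	FALSE	curated
pantothenate	Pantothenate	C9H17NO5	FALSE	curated
coa	Coenzyme A	C21H36N7O16P3S	FALSE	curated
atp	ATP	C10H16N5O13P3	FALSE	curated
s7p	Sedoheptulose 7-phosphate	C7H15O10P	FALSE	curated
sorbitol	Sorbitol	C6H14O6	FALSE	curated
nacetylaspartate	N-Acetylaspartate	C6H9NO5	FALSE	curated
oxamate	Oxamate	C2H3NO3	FALSE	curated
akg	2-Oxoglutarate	C5H6O5	TRUE	curated
citrate	Citrate	C6H8O7	FALSE	curated
glutamate	Glutamate	C5H9NO4	FALSE	curated
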