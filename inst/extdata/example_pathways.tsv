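set_id	set_name	members
tca	TCA cycle	citrate, cis-aconitate, succinate
glycolysis	Glycolysis / pyruvate metabolism	lactate, alanine, acetate
methylamines	Methylamine metabolism	methylamine, dimethylamine, trimethylamine, trimethylamine N-oxide, dimethylglycine
creatine	Creatine metabolism	creatine phosphate, creatinine
aromatics	Aromatic / microbial co-metabolites	hippurate, n-phenylacetylglycine, trigonelline, n-methylnicotinamide
osmolytes	Osmolytes	taurine, glycine, choline
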