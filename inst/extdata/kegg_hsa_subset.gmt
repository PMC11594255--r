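Citrate cycle (TCA cycle)	hsa00020	citrate	succinate	pyruvate
Alanine, aspartate and glutamate metabolism	hsa00250	alanine	glutamate	glutamine	succinate
Glyoxylate and dicarboxylate metabolism	hsa00630	citrate	glycine	formate	serine
Starch and sucrose metabolism	hsa00500	glucose
Neomycin, kanamycin and gentamicin biosynthesis	hsa00524	glucose
Primary bile acid biosynthesis	hsa00120	taurine	glycine
Galactose metabolism	hsa00052	glucose	myo-inositol
Cysteine and methionine metabolism	hsa00270	serine	pyruvate
Valine, leucine and isoleucine biosynthesis	hsa00290	valine	leucine	isoleucine	threonine
Lipoic acid metabolism	hsa00785	glycine	serine
Glutathione metabolism	hsa00480	glycine	glutamate
Porphyrin metabolism	hsa00860	glycine	succinate
Glycine, serine and threonine metabolism	hsa00260	glycine	serine	threonine	betaine	choline	creatine
Pyruvate metabolism	hsa00620	pyruvate	lactate	acetate
Glycolysis / Gluconeogenesis	hsa00010	glucose	pyruvate	lactate	acetate
Pantothenate and CoA biosynthesis	hsa00770	valine	alanine
Phenylalanine, tyrosine and tryptophan biosynthesis	hsa00400	phenylalanine	tyrosine
Phenylalanine metabolism	hsa00360	phenylalanine	tyrosine	hippurate
Arginine and proline metabolism	hsa00330	creatine	glutamate	creatinine
Butanoate metabolism	hsa00650	3-hydroxybutyrate	glutamate	acetate
Tyrosine metabolism	hsa00350	tyrosine	pyruvate	acetate
Valine, leucine and isoleucine degradation	hsa00280	valine	leucine	isoleucine	3-hydroxybutyrate	acetone
Glycerophospholipid metabolism	hsa00564	choline	serine
Histidine metabolism	hsa00340	histidine	glutamate
Taurine and hypotaurine metabolism	hsa00430	taurine	acetate
Methane metabolism	hsa00680	formate	serine	glycine
Nitrogen metabolism	hsa00910	glutamine	glutamate
Aminoacyl-tRNA biosynthesis	hsa00970	alanine	glycine	valine	leucine	isoleucine	threonine	serine	glutamine	glutamate	histidine	phenylalanine	tyrosine
Synthesis and degradation of ketone bodies	hsa00072	3-hydroxybutyrate	acetone	acetate
Caffeine metabolism	hsa00232	formate
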