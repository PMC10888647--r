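Glycine and serine metabolism	synthetic compound set	glycine	serine	alanine	methionine
Ammonia recycling	synthetic compound set	glycine	glutamine	glutamate	citrulline	ornithine	arginine
Urea cycle	synthetic compound set	arginine	ornithine	citrulline	argininosuccinic acid	glutamate
Methionine metabolism	synthetic compound set	methionine	glycine	serine
Carnitine synthesis	synthetic compound set	carnitine	lysine	methionine
Beta-oxidation of short-chain fatty acids	synthetic compound set	carnitine	acetylcarnitine	propionylcarnitine	butyrylcarnitine	valerylcarnitine	hexanoylcarnitine	octanoylcarnitine
Beta-oxidation of long-chain fatty acids	synthetic compound set	palmitoylcarnitine	oleoylcarnitine	octadecanoylcarnitine	arachidoylcarnitine	lignoceroylcarnitine	hexacosanoylcarnitine
Alanine metabolism	synthetic compound set	alanine	glutamate	pyruvate
Glutamate metabolism	synthetic compound set	glutamate	glutamine	glycine	alanine
Branched-chain amino acid degradation	synthetic compound set	leucine	isoleucine	valine	tiglylcarnitine	3-hydroxyisovalerylcarnitine
Phenylalanine and tyrosine metabolism	synthetic compound set	phenylalanine	tyrosine	succinylacetone
Purine metabolism	synthetic compound set	adenosine	deoxyadenosine	glycine	glutamine
Membrane lipid metabolism	synthetic compound set	lysophosphatidylcholine C20:0	lysophosphatidylcholine C22:0	lysophosphatidylcholine C24:0	lysophosphatidylcholine C26:0
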