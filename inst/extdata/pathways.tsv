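# Offline pathway fixture (KEGG-style ids). Users may substitute their own
# table with the same two columns.
pathway_id	name
map00522	Biosynthesis of 12-, 14- and 16-membered macrolides
map00860	Porphyrin and chlorophyll metabolism
map01057	Biosynthesis of type II polyketide products
map00903	Limonene and pinene degradation
map00902	Monoterpenoid biosynthesis
map00010	Glycolysis / Gluconeogenesis
map00020	Citrate cycle (TCA cycle)
map00230	Purine metabolism
map00240	Pyrimidine metabolism
map00260	Glycine, serine and threonine metabolism
map00290	Valine, leucine and isoleucine biosynthesis
map00330	Arginine and proline metabolism
map00500	Starch and sucrose metabolism
map00561	Glycerolipid metabolism
map00564	Glycerophospholipid metabolism
map00071	Fatty acid degradation
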