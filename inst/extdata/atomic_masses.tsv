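# Monoisotopic atomic masses (Da) of the most abundant isotope, IUPAC values.
# Pinned here so mass arithmetic is reproducible; tests assert against this table.
element	monoisotopic_mass	isotope
H	1.00782503207	1H
C	12.0	12C
N	14.0030740048	14N
O	15.9949146196	16O
P	30.97376163	31P
S	31.97207100	32S
Na	22.9897692809	23Na
K	38.96370668	39K
Cl	34.96885268	35Cl
F	18.99840322	19F
Mg	23.9850417	24Mg
Ca	39.96259098	40Ca
Fe	55.9349375	56Fe
Si	27.9769265325	28Si
Se	79.9165213	80Se
Br	78.9183371	79Br
I	126.904473	127I
Zn	63.9291422	64Zn
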