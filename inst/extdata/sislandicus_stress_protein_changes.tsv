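locus_tag	stress	phase	protein_log2fc	transcript_direction	annotation
SiRe_1208	acid	mid_log	2.08	NA	Ornithine carbamoyltransferase
SiRe_2064	acid	mid_log	-3.01	up	Conserved hypothetical protein
SiRe_0753	acid	mid_log	-2.29	NA	Ketol-acid reductoisomerase
SiRe_2623	acid	early_stationary	2.98	down	UDP-sulfoquinovose synthase, Agl3
SiRe_2451	acid	early_stationary	2.38	down	AMP-dependent synthetase and ligase
SiRe_2246	acid	early_stationary	1.94	NA	Mandelate racemase (MR) subfamily
SiRe_0032	acid	early_stationary	1.62	down	Aminotransferase class V
SiRe_2599	acid	early_stationary	1.17	down	Conserved hypothetical protein
SiRe_2391	acid	early_stationary	1.15	up	Conserved hypothetical protein
SiRe_2464	acid	early_stationary	-3.31	up	Formate dehydrogenase, alpha subunit
SiRe_1684	acid	early_stationary	-2.58	NA	Thioredoxin/glutaredoxin-like protein
SiRe_2601	acid	early_stationary	-2.19	down	Heat shock protein (Hsp20)
SiRe_1716	acid	early_stationary	-2.11	up	Thermosome
SiRe_1214	acid	early_stationary	-2.01	up	Thermosome
SiRe_1119	acid	early_stationary	-1.81	up	Deoxyhypusine synthase
SiRe_1633	acid	early_stationary	-1.70	NA	Glutamine synthetase, type I
SiRe_0989	acid	early_stationary	-1.61	down	CoA-binding domain protein
SiRe_2064	acid	early_stationary	-1.59	down	Conserved hypothetical protein
SiRe_1066	acid	early_stationary	-1.57	down	Extracellular solute-binding protein family 1
SiRe_1444	cold	mid_log	1.22	NA	A-type ATPase subunit, AtpI
SiRe_1371	cold	mid_log	-2.83	NA	Arginosuccinate lyase
SiRe_0753	cold	mid_log	-2.19	NA	Ketol-acid reductoisomerase
SiRe_0511	cold	mid_log	-1.44	NA	Glycerol kinase
SiRe_2202	cold	mid_log	-1.29	NA	Beta-glucosidase
SiRe_0643	cold	mid_log	-1.08	NA	Amidohydrolase
SiRe_0099	cold	early_stationary	1.85	NA	Short-chain dehydrogenase/reductase SDR
SiRe_2037	cold	early_stationary	-1.17	down	Oxidoreductase molybdopterin binding protein
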