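# Bundled controlled-vocabulary subset for offline resolution.
# Columns: source, accession, name, delta_monoisotopic_da (empty when the
# term has no single monoisotopic mass, e.g. glycan ontology entries).
# Delta masses transcribed from Unimod (2022 release), PSI-MOD (1.031.6)
# and XL-MOD; point pf_resolver() at a larger table in the same layout to
# widen coverage.
source	accession	name	delta_monoisotopic_da
UNIMOD	35	Oxidation	15.994915
UNIMOD	21	Phospho	79.966331
UNIMOD	1	Acetyl	42.010565
UNIMOD	214	iTRAQ4plex	144.102063
UNIMOD	4	Carbamidomethyl	57.021464
MOD	00719	L-methionine sulfoxide	15.994915
MOD	00046	O-phospho-L-serine	79.966331
MOD	00034	L-cystine (cross-link)	-2.015650
MOD	00093	residue cross-link (branch)	
MOD	01090	iodoacetamide derivatized residue	57.021464
XLMOD	02001	DSS	138.068080
GNO	G59626AS	G59626AS	
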