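# Canonical one-example-per-feature corpus for the ProForma 2.0 notation.
# One string per line; lines starting with '#' are comments.
# CV/ontology modification names
EM[Oxidation]EVEES[Phospho]PEK
# CV/ontology protein modification accession numbers
EM[MOD:00719]EVEES[MOD:00046]PEK
# Cross-link within the same peptide
EMEVTK[XLMOD:02001#XL1]SESPEK[#XL1]
# Inter-chain cross-links
SEK[XLMOD:02001#XL1]UENCE//EMEVTK[#XL1]SESPEK
# Disulfide linkages
EVTSEKC[MOD:00034#XL1]LEMSC[#XL1]EFD
# Branched peptides
ETFGD[MOD:00093#BRANCH]//R[#BRANCH]ATER
# Glycans using the GNO ontology as CV
NEEYN[GNO:G59626AS]K
# Delta mass notation for modifications
EM[+15.9949]EVEES[+79.9663]PEK
# Specifying a gap of known mass
RTAAX[+367.0537]WT
# Support for elemental formulas
SEQUEN[Formula:C12H20O2]CE
# Glycan composition
SEQUEN[Glycan:HexNAc1Hex2]CE
# N-terminal and C-terminal modifications
[iTRAQ4plex]-EMEVNESPEK
# Labile modifications
{Glycan:Hex}EMEVNESPEK
# Unknown modification position
[Phospho]?EMEVTSESPEK
# Possible set of modification positions
EMEVT[#g1]S[#g1]ES[Phospho#g1]PEK
# Ranges of positions for the modifications
PROT(ESFRMS)[+19.0523]ISK
# Modification position preference and localization scores
EMEVT[#g1(0.01)]S[#g1(0.09)]ES[Phospho#g1(0.90)]PEK
# Scoring for ranges of positions for a modification
PROT(ESFRMS)[+19.0523#g1(0.01)]ISK[#g1(0.99)]
# Isotopes
<13C>ATPEILTVNSIGQLK
# Fixed protein modifications
<[MOD:01090]@C>ATPEILTCNSIGCLK
# Ambiguity in the order of the amino acid sequence
(?DQ)NGTWEMESNENFEGYMK
# Information tag
ELVIS[Phospho|INFO:newly discovered]K
# Joint representation of experimental data and interpretation
ELVIS[Phospho|Obs:+79.978]K
# Representation of ion charges
EMEVEESPEK/2
# Multiple peptidoforms assigned to chimeric spectra
EMEVEESPEK/2+ELVISLIVER/3
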