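# proforma

An R implementation of **ProForma 2.0**, the community notation for
proteoforms and peptidoforms in mass spectrometry. A proteoform is one
exact molecular form of a protein — a primary sequence plus an exact set
of mass modifications — and ProForma encodes it in a single line:
residues in IUPAC one-letter code, each modification a bracketed tag,
e.g. `EM[Oxidation]EVEES[Phospho]PEK` or, with more of the notation in
play,

```
[iTRAQ4plex]-EM[Oxidation]EVEES[Phospho#g1(0.90)]PT[#g1(0.10)]EK/2
```

— an iTRAQ-labelled N-terminus, an oxidized methionine, a phosphorylation
localized to S7 with probability 0.90 (T9 with 0.10), observed as a 2+
ion. The package is aimed at developers of search engines, proteoform
registries and QC pipelines, and at analysts who need to parse, compare,
normalize or mass-check ProForma strings.

It provides, fully offline:

* **Parsing** (`pf_parse`) of the complete notation — CV names and
  accessions (Unimod, PSI-MOD, RESID, XL-MOD, GNO), delta masses,
  formulas, glycan compositions, terminal/labile/unknown-position/fixed
  modifications, global isotope labels, mass gaps, ranges, localization
  scores, order ambiguity, intra- and inter-chain cross-links,
  disulfides, branched peptides, charges and chimeric assignments — with
  position-annotated errors (`pf_parse_error`).
* **Serialization** (`pf_serialize`) verbatim (character-exact) or
  canonical (normalized case, names and element order), plus a JSON model
  dump (`pf_to_json`) and semantic comparison (`pf_equivalent`).
* **Masses** (`pf_mass`, `pf_mz`, `pf_formula_mass`, `pf_glycan_mass`):
  neutral monoisotopic mass as residue sum + water + one delta per tag,
  `M = Σ m(res_i) + m(H₂O) + Σ Δ_t`, from frozen NIST atomic masses;
  unresolvable tags are reported, never silently zero.
* **Compliance** (`pf_profile`, `pf_required_level`, `pf_validate`)
  against the five published configurations: base, level 2, and level 2
  with the top-down, cross-linking and glycan extensions.
* A pluggable offline **CV resolver** (`pf_resolver`,
  `pf_default_resolver`), a deterministic **fuzz generator** (`pf_fuzz`)
  and a **command-line interface** (`inst/cli/proforma`).

## Worked example

```r
library(proforma)

p <- pf_parse("[iTRAQ4plex]-EM[Oxidation]EVEES[Phospho#g1(0.90)]PT[#g1(0.10)]EK/2")
p
#> <ProForma set: 1 ion assignment>
#>   [1] EMEVEESPTEK  charge 2
#>   text: [iTRAQ4plex]-EM[Oxidation]EVEES[Phospho#g1(0.90)]PT[#g1(0.10)]EK/2

pf_profile(p)
#> [1] "charge"              "cv_name"             "localization_scores"
#> [4] "terminal_mods"

format(pf_required_level(pf_profile(p)))
#> [1] "level2"

pf_mass(p$members[[1]])
#> <neutral monoisotopic mass: 1546.623172 Da>
#>   residues 1288.549298 + water 18.010565
#>     +15.994915  [Oxidation]
#>     +79.966331  [Phospho#g1(0.90)]
#>    +144.102063  [iTRAQ4plex]

pf_mz(p)
#> [1] 774.3189
```

The backbone EMEVEESPTEK sums to 1288.549298 Da; water closes the termini;
the three resolvable tags add their CV deltas (the scored `#g1` references
carry no chemistry of their own — localization ambiguity never changes
composition); dividing the protonated mass by the charge gives m/z
774.3189. Canonicalization normalizes author formatting without touching
meaning:

```r
pf_serialize(pf_parse("em[oxidation]k"), canonical = TRUE,
             resolver = pf_default_resolver())
#> [1] "EM[Oxidation]K"
```

The CLI wraps the same functions:

```sh
inst/cli/proforma mass "EM[+15.9949]EVEES[+79.9663]PEK" --json
inst/cli/proforma validate --level base "NEEYN[GNO:G59626AS]K"
```

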