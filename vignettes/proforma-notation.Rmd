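---
title: "ProForma 2.0 in R: model, grammar, masses and compliance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ProForma 2.0 in R: model, grammar, masses and compliance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proforma)
```

## The notation

A proteoform (or, at the peptide level, a peptidoform) is one exact
molecular form of a protein: a primary sequence together with an exact set
of mass modifications. ProForma 2.0 encodes a proteoform in a single
human- and machine-readable line: residues run N- to C-terminus in IUPAC
one-letter code, and each modification is a bracketed tag attached where it
sits:

```{r}
pf_parse("EM[Oxidation]EVEES[Phospho]PEK")
```

The notation covers much more than residue-localized tags, and this package
implements all of it:

* **Tag vocabulary** — a tag names its modification by controlled-vocabulary
  (CV) term (`[Oxidation]`), by CV accession (`[MOD:00719]`,
  `[UNIMOD:35]`, `[RESID:…]`, `[XLMOD:…]`, `[GNO:…]`), by signed delta
  mass in daltons (`[+15.9949]`), by elemental formula
  (`[Formula:C12H20O2]`, with isotopes as `[Formula:[13C2]CH6N]`), or by
  glycan composition (`[Glycan:HexNAc1Hex2]`). Pipe-separated elements of
  one tag describe the *same* modification; `Obs:` records an observed
  (experimental) mass alongside the interpretation and `INFO:` carries
  free text; neither contributes to the theoretical mass.
* **Context** — N-/C-terminal tags (`[iTRAQ4plex]-SEQ`, `SEQ-[tag]`),
  labile modifications in braces (`{Glycan:Hex}SEQ`), unknown-position
  tags (`[Phospho]?SEQ`, multiplicity `[Phospho]^2?`), fixed-modification
  rules (`<[MOD:01090]@C>`), and global isotope labelling (`<13C>`).
* **Ambiguity** — position sets share a group label
  (`T[#g1]S[#g1]…S[Phospho#g1]`), optionally with localization scores
  (`[Phospho#g1(0.90)]`); ranges put a tag on an interval
  (`PROT(ESFRMS)[+19.0523]ISK`); `(?DQ)` marks residues of uncertain
  order; `X[+367.0537]` encodes a mass gap.
* **Linkage** — cross-links within or between chains
  (`K[XLMOD:02001#XL1]…K[#XL1]`, chains joined by `//`), disulfides
  (`C[MOD:00034#XL1]`), and branched peptides (reserved label `#BRANCH`).
* **Ions** — a trailing `/z` gives the charge, and `+` joins several
  peptidoforms assigned to one chimeric spectrum
  (`EMEVEESPEK/2+ELVISLIVER/3`).

The whole format is case-insensitive and must not contain line breaks.

## The object model

`pf_parse()` returns a `pf_set`: a list of ion assignments (`pf_ion`,
charge plus complex), each holding a `pf_complex` (chains plus a
`link_mode` of `none`, `cross_link` or `branch`), each chain a
`pf_peptidoform` whose residues carry `pf_tag` objects. Intervals
(ranges, unordered segments) are stored 0-based and half-open internally —
unambiguous interval arithmetic — while printed output and this vignette
speak of 1-based residue positions. Original numeric lexemes are retained
alongside parsed values, which is what makes verbatim round-trips
character-exact.

Equivalence (`pf_equivalent()`) compares models semantically: case of
names and group labels is ignored, numbers compare by parsed value
(`+15.9949` ≡ `+15.99490`), elements within one tag compare as a set, and
chimeric members compare order-insensitively (the format does not assign
meaning to their order; serialization still preserves it).

## Parsing decisions

The parser is a single-pass recursive descent over a token stream in which
bracketed payloads are atomic, so `+`, `/` and `//` are only structural at
the top nesting level — a delta mass's `+` or an `INFO:` text can never
split an ion. Decisions where the grammar leaves room:

* **Charges** are signed integers: `/2`, `/-2`, `/+4`. A trailing-sign
  style (`2+`) is not supported because `+` after a charge must remain the
  chimeric separator.
* **Parenthesis disambiguation**: `(?` opens an order-ambiguous segment;
  any other `(` opens a range and must be followed by `)[tag]`.
  Parentheses do not nest, and overlapping ranges are not representable.
* **Group semantics**: a tag that carries chemistry plus a `#label`
  defines the group; a bare `[#label]` (optionally scored) references it.
  Every referenced label must have exactly one defining occurrence per
  complex — a dangling or doubly-defined label is a parse error. A group
  is treated as a cross-link when its label starts with `XL` or its
  defining tag carries XLMOD chemistry or the disulfide term MOD:00034;
  other labels (`#g1`) are localization-ambiguity groups and do not make
  the complex cross-linked.
* **Unknown prefixes**: an element shaped like `Word:rest` with an
  unrecognized word is rejected rather than guessed. A consequence worth
  knowing: the few CV names that themselves contain a colon (Unimod's
  `Cation:Na`) cannot be used as bare names — use their accession.
* **Case-folding of formulas**: after lowercasing, `co2` is ambiguous
  (cobalt vs carbon + oxygen). A second letter joins an element symbol
  only when it is written in lowercase and the two-letter symbol is a
  known element; write `CO2` (or keep standard capitalization) for carbon
  monoxide-style compositions.
* **Residue alphabet**: the 20 canonical letters plus `B`, `J`, `O`, `U`,
  `Z` and `X`; `X` is the mass-gap carrier. Errors carry the 1-based
  character offset and the offending fragment
  (`tryCatch(..., pf_parse_error = …)`).

## Serialization

`pf_serialize()` is verbatim by default — a parsed model reproduces its
input character-for-character. With `canonical = TRUE` it normalizes:
residues uppercase, CV names rendered with the resolver's preferred
capitalization, group labels lowercase (`BRANCH` excepted), and tag
elements ordered chemistry, `Obs:`, `INFO:`, with the group reference on
the chemistry element. Numeric lexemes are *not* re-rounded: the decimal
places an author wrote are treated as intent. Canonicalization is
idempotent:

```{r}
res <- pf_default_resolver()
pf_serialize(pf_parse("em[oxidation]k"), canonical = TRUE, resolver = res)
```

## The CV resolver

Offline by design: `pf_default_resolver()` loads a bundled
tab-separated table (`source`, `accession`, `name`,
`delta_monoisotopic_da`) covering every term the examples use; richer
tables in the same layout plug in via `pf_resolver(path)`. Bare names are
searched Unimod first, then PSI-MOD, RESID, XL-MOD, GNO — which is why an
unqualified `Phospho` means the Unimod term. Terms without a single
monoisotopic mass (glycan ontology structures, one PSI-MOD cross-link
term in the bundled table) resolve *mass-absent*: the mass engine then
reports the tag as unresolved instead of silently adding zero.

## Masses

`pf_mass()` computes the neutral monoisotopic mass:

$$M = \sum_i m(\text{residue}_i) + m(\mathrm{H_2O}) + \sum_t \Delta_t$$

Residue masses come from elemental compositions and a frozen NIST/AME
atomic-mass table, so a global isotope rule like `<13C>` substitutes the
isotope's mass for every carbon in the residue-and-water accounting (tag
formulas keep their own explicit isotope annotations). Each tag
contributes one delta — the first of its elements that yields a number —
scaled by multiplicity for `[tag]^n?` and by the number of matching
residues for fixed rules. A cross-link's chemistry counts once, at its
defining tag; bare references, `Obs:` and `INFO:` contribute nothing; `X`
contributes only its gap tag. Localization ambiguity never changes
composition, so unknown-position, range and scored-group tags all count
exactly once.

```{r}
pf_mass("EM[+15.9949]EVEES[+79.9663]PEK")
```

Labile modifications are part of the intact molecule and are included by
default; `include_labile = FALSE` gives the fragmentation-level mass
instead. Charge is an ion property, not a molecule property, so m/z is a
separate convenience (`pf_mz()`, proton mass 1.00727646688 Da). B and Z
residues have no defined composition and are reported as unresolved.

## Compliance levels

Software need not support the whole notation, so usage is classified
against five published configurations: base, level 2, and level 2 plus
the top-down, cross-linking or glycan extension (extensions are
combinable). The base level grants CV names and Unimod/PSI-MOD
accessions, delta masses, terminal modifications and info tags; level 2
adds formulas, glycan compositions, gaps, labile/unknown/range/ambiguity
constructs, scores, fixed modifications, isotopes, charges and chimeric
sets; the extensions gate RESID, the cross-link family (XLMOD,
disulfides, branches) and GNO respectively. The published material names
the five levels without printing the full grant lists, so this mapping is
a package decision — every grant can be overridden via
`pf_validate(..., grants =)`.

```{r}
pf_validate(pf_parse("SEK[XLMOD:02001#XL1]UENCE//EMEVTK[#XL1]SESPEK"),
            "base")
```

Semantic rules hold at every level: group references must resolve, scores
must lie in [0, 1], and the scores of one ambiguity group should sum to 1
— deviations beyond 0.01 are reported as warnings rather than errors,
since rounded scores in the wild will rarely sum exactly.

## The fuzz generator

`pf_fuzz(n, seed)` emits syntactically valid strings over random 5–50
residue sequences, drawing every notation feature with at least 2%
incidence; structurally conflicting features (the interval constructs,
the linkage constructs) come from categorical draws so intervals never
overlap and group labels never collide. It is the property-testing
workhorse: parse → canonicalize → re-parse must return an equivalent
model, and case-folded input must parse equivalently, for every generated
string. The suite runs these properties on corpora of a few hundred to
10,000 strings (the larger runs complete in about a minute).

What the generator does *not* emulate, and what green properties therefore
do not show: real CV coverage (it draws from the bundled term subset, not
full ontologies), very long proteoform-scale sequences, non-ASCII names,
adversarially malformed input (covered separately by the rejection
tests), and chemically meaningful co-occurrence of features — it tests
the grammar and algebra of the notation, not proteome realism.

## Known limitations

* The bundled CV table is a small offline subset; one PSI-MOD term used
  by the branched-peptide example ships mass-absent, so that example is
  parseable and validatable but not mass-resolvable out of the box.
* Average masses, cyclic peptides, overlapping ranges, ambiguous
  cross-linker positions and isotope-distribution modelling are outside
  the notation version implemented here.
* PEFF, mzIdentML, mzTab and USI containers are not parsed; the package
  reads bare ProForma strings (one per line in file mode).
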