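Package: proforma
Title: Parse, Validate and Compute Masses for ProForma 2.0 Proteoform Notation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A complete implementation of the ProForma 2.0 notation for
    proteoforms and peptidoforms. Parses any compliant string into a
    structured object model, serializes back in verbatim or canonical
    form, classifies and validates strings against the five compliance
    levels (base, level 2, and the top-down, cross-linking and glycan
    extensions), and computes theoretical neutral monoisotopic masses
    from residue elemental compositions, delta masses, chemical
    formulas, glycan compositions and controlled-vocabulary terms.
    Includes an offline controlled-vocabulary resolver with a bundled
    term table, a deterministic fuzz-corpus generator for
    property-based testing, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
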