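test_that("backbone masses agree with an independent residue-table summation", {
  for (seq in c("PEPTIDE", "EMEVEESPEK", "ELVISLIVER", "ATPEILTVNSIGQLK")) {
    m <- pf_mass(seq)
    expect_length(m$unresolved, 0L)
    # the transcribed oracle table is printed to 5 decimals
    expect_lt(abs(m$mass - pf_oracle_backbone(seq)), 5e-4)
  }
  expect_lt(abs(pf_mass("PEPTIDE")$mass - 799.35996), 1e-4)
})

test_that("printed delta masses are strictly additive over the backbone", {
  full <- pf_mass("EM[+15.9949]EVEES[+79.9663]PEK")$mass
  backbone <- pf_mass("EMEVEESPEK")$mass
  expect_equal(full - backbone, 15.9949 + 79.9663, tolerance = 1e-9)

  # a mass gap: X contributes nothing but its tag
  gap <- pf_mass("RTAAX[+367.0537]WT")$mass
  expect_equal(gap - pf_mass("RTAAWT")$mass, 367.0537, tolerance = 1e-9)

  # empty modification set: mass is the backbone, nothing unresolved
  m <- pf_mass("EMEVEESPEK")
  expect_length(m$unresolved, 0L)
  expect_length(m$breakdown$deltas, 0L)
})

test_that("formula masses match independent atomic-mass arithmetic", {
  # 12 * 12 + 20 * 1.00782503207 + 2 * 15.9949146196
  expect_equal(pf_formula_mass("C12H20O2"), 196.1463299, tolerance = 1e-6)
  expect_identical(pf_formula_mass(
    data.frame(element = character(0L), isotope = integer(0L),
               count = integer(0L))), 0)
  expect_equal(pf_formula_mass("H2OH-2O-1"), 0, tolerance = 1e-12)
  # isotope-annotated atoms use the isotope mass
  expect_equal(pf_formula_mass("[13C2]C-2"),
               2 * (13.00335483507 - 12), tolerance = 1e-9)
  expect_error(pf_formula_mass("Qq2"), regexp = "unknown element")
})

test_that("glycan masses follow the monosaccharide residue formulas", {
  expect_equal(pf_glycan_mass("HexNAc1Hex2"),
               pf_formula_mass("C8H13NO5") + 2 * pf_formula_mass("C6H10O5"),
               tolerance = 1e-9)
  expect_equal(pf_glycan_mass("Hex1"), pf_glycan_mass("Hex"))
  expect_identical(pf_glycan_mass(
    data.frame(monosaccharide = character(0L), count = integer(0L))), 0)
  expect_equal(pf_glycan_mass("NeuAc1"), pf_formula_mass("C11H17NO8"),
               tolerance = 1e-9)
})

test_that("CV-resolved, fixed, unlocalized and labile tags all contribute", {
  res <- pf_default_resolver()
  # named and accession tags resolve through the CV table
  expect_equal(pf_mass("EM[Oxidation]EVEES[Phospho]PEK")$mass -
                 pf_mass("EMEVEESPEK")$mass,
               15.994915 + 79.966331, tolerance = 1e-9)
  expect_equal(pf_mass("EM[MOD:00719]EVEES[MOD:00046]PEK")$mass,
               pf_mass("EM[Oxidation]EVEES[Phospho]PEK")$mass,
               tolerance = 1e-12)
  # fixed rule applies once per matching residue (two cysteines)
  expect_equal(pf_mass("<[MOD:01090]@C>ATPEILTCNSIGCLK")$mass -
                 pf_mass("ATPEILTCNSIGCLK")$mass,
               2 * 57.021464, tolerance = 1e-9)
  # unknown-position multiplicity scales the contribution
  expect_equal(pf_mass("[Phospho]^2?EMEVTSESPEK")$mass -
                 pf_mass("EMEVTSESPEK")$mass,
               2 * 79.966331, tolerance = 1e-9)
  # labile modifications count in the neutral mass unless excluded
  expect_equal(pf_mass("{Glycan:Hex}EMEVNESPEK")$mass -
                 pf_mass("EMEVNESPEK")$mass,
               pf_glycan_mass("Hex"), tolerance = 1e-9)
  expect_equal(pf_mass("{Glycan:Hex}EMEVNESPEK",
                       include_labile = FALSE)$mass,
               pf_mass("EMEVNESPEK")$mass, tolerance = 1e-12)
  # a disulfide loses two hydrogens; the bare reference adds nothing
  expect_equal(pf_mass("EVTSEKC[MOD:00034#XL1]LEMSC[#XL1]EFD")$mass -
                 pf_mass("EVTSEKCLEMSCEFD")$mass,
               -2.015650, tolerance = 1e-9)
  # an inter-chain complex sums both chains plus the linker once
  m <- pf_mass("SEK[XLMOD:02001#XL1]UENCE//EMEVTK[#XL1]SESPEK")
  expect_equal(m$mass,
               pf_mass("SEKUENCE")$mass + pf_mass("EMEVTKSESPEK")$mass +
                 138.068080, tolerance = 1e-9)
})

test_that("global isotope rules substitute the isotope mass for every atom", {
  # glycine has 2 carbons; GG + water has 4 C
  shift <- pf_mass("<13C>GG")$mass - pf_mass("GG")$mass
  expect_equal(shift, 4 * (13.00335483507 - 12), tolerance = 1e-9)
  # 15N on GG: 2 nitrogens
  shift <- pf_mass("<15N>GG")$mass - pf_mass("GG")$mass
  expect_equal(shift, 2 * (15.00010889888 - 14.0030740048),
               tolerance = 1e-9)
  # 13C strictly increases the mass of any carbon-containing peptide
  for (seq in c("A", "PEPTIDE", "W")) {
    expect_gt(pf_mass(paste0("<13C>", seq))$mass, pf_mass(seq)$mass)
  }
})

test_that("unresolvable tags are reported, never silently zero", {
  m <- pf_mass("NEEYN[GNO:G59626AS]K")
  expect_true(is.na(m$mass))
  expect_match(m$unresolved, "GNO:G59626AS")
  m <- pf_mass("EM[NotAMod]K")
  expect_true(is.na(m$mass))
  expect_match(m$unresolved, "NotAMod")
  # observed-mass and info elements contribute nothing
  expect_equal(pf_mass("ELVIS[Phospho|Obs:+79.978]K")$mass,
               pf_mass("ELVIS[Phospho]K")$mass, tolerance = 1e-12)
  expect_equal(pf_mass("ELVIS[Phospho|INFO:newly discovered]K")$mass,
               pf_mass("ELVIS[Phospho]K")$mass, tolerance = 1e-12)
  # B/Z residues have no defined mass
  expect_true(is.na(pf_mass("PEBTIDE")$mass))
})

test_that("m/z uses the proton mass and the parsed charge", {
  m <- pf_mass("EMEVEESPEK")$mass
  expect_equal(pf_mz("EMEVEESPEK/2"), (m + 2 * 1.00727646688) / 2,
               tolerance = 1e-9)
  expect_equal(pf_mz("EMEVEESPEK/-2"), (m - 2 * 1.00727646688) / 2,
               tolerance = 1e-9)
  expect_error(pf_mz("EMEVEESPEK"), regexp = "charge")
})
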