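test_that("feature profiles flag exactly what each string uses", {
  expect_identical(pf_profile(pf_parse("EMEVEESPEK/2")), "charge")
  expect_identical(pf_profile(pf_parse("PEPTIDE")), character(0L))
  expect_identical(
    pf_profile(pf_parse("EVTSEKC[MOD:00034#XL1]LEMSC[#XL1]EFD")),
    c("cross_link_intra", "cv_accession", "disulfide"))
  expect_identical(
    pf_profile(pf_parse("SEK[XLMOD:02001#XL1]UENCE//EMEVTK[#XL1]SESPEK")),
    c("cross_link_inter", "xlmod_accession"))
  expect_identical(pf_profile(pf_parse("NEEYN[GNO:G59626AS]K")), "gno")
  expect_identical(pf_profile(pf_parse("RTAAX[+367.0537]WT")),
                   c("delta_mass", "gap"))
  expect_identical(pf_profile(pf_parse("(?DQ)NGTWEMESNENFEGYMK")),
                   "sequence_ambiguity")
  expect_identical(
    pf_profile(pf_parse("EMEVT[#g1]S[#g1]ES[Phospho#g1]PEK")),
    c("cv_name", "position_set"))
  expect_identical(
    pf_profile(pf_parse("PROT(ESFRMS)[+19.0523#g1(0.01)]ISK[#g1(0.99)]")),
    c("delta_mass", "range", "range_scores"))
  expect_identical(pf_profile(pf_parse("EMEVEESPEK/2+ELVISLIVER/3")),
                   c("charge", "chimeric"))
})

test_that("exactly five compliance configurations are exposed", {
  lv <- pf_compliance_levels()
  expect_length(lv, 5L)
  expect_identical(names(lv), c("base", "level2", "level2_topdown",
                                "level2_crosslink", "level2_glycan"))
  expect_length(unique(vapply(lv, format, "")), 5L)
  expect_error(pf_level("base", "glycan"), regexp = "imply level 2")
})

test_that("required_level returns the minimal covering configuration", {
  expect_identical(format(pf_required_level(character(0L))), "base")
  expect_identical(format(pf_required_level(c("cv_name", "delta_mass"))),
                   "base")
  p <- pf_profile(pf_parse("SEK[XLMOD:02001#XL1]UENCE//EMEVTK[#XL1]SESPEK"))
  expect_identical(format(pf_required_level(p)), "level2+crosslink")
  p <- pf_profile(pf_parse("NEEYN[GNO:G59626AS]K"))
  expect_identical(format(pf_required_level(p)), "level2+glycan")
  p <- pf_profile(pf_parse("EM[RESID:AA0037]K"))
  expect_identical(format(pf_required_level(p)), "level2+topdown")
  expect_identical(
    format(pf_required_level(c("gno", "cross_link_intra"))),
    "level2+crosslink+glycan")
})

test_that("violations name ungranted features and their minimal level", {
  v <- pf_validate(pf_parse("PEPTIDE"), "base")
  expect_identical(nrow(v), 0L)
  v <- pf_validate(
    pf_parse("SEK[XLMOD:02001#XL1]UENCE//EMEVTK[#XL1]SESPEK"), "base")
  expect_gt(nrow(v), 0L)
  expect_true(any(grepl("crosslink", v$required_level)))
  # the same string is clean once the extension is granted
  v <- pf_validate(
    pf_parse("SEK[XLMOD:02001#XL1]UENCE//EMEVTK[#XL1]SESPEK"),
    "level2_crosslink")
  expect_identical(nrow(v), 0L)
  # ad-hoc extra grants are honored
  v <- pf_validate(pf_parse("NEEYN[GNO:G59626AS]K"), "level2",
                   grants = "gno")
  expect_identical(nrow(v), 0L)
})

test_that("localization-score semantics are enforced at every level", {
  v <- pf_validate(
    pf_parse("EMEVT[#g1(0.01)]S[#g1(0.09)]ES[Phospho#g1(0.90)]PEK"),
    "level2")
  expect_identical(nrow(v), 0L)
  # out-of-range score is an error
  v <- pf_validate(pf_parse("EMS[Phospho#g1(1.5)]K"), "level2")
  expect_true(any(v$severity == "error" &
                    grepl("outside", v$message)))
  # a sum far from 1 is a warning, not an error
  v <- pf_validate(
    pf_parse("EMEVT[#g1(0.10)]S[#g1(0.10)]ES[Phospho#g1(0.10)]PEK"),
    "level2")
  expect_true(any(v$severity == "warning"))
  expect_false(any(v$severity == "error"))
})

test_that("validity is monotone in the level and sound at the required level", {
  full <- pf_level("level2", c("topdown", "crosslink", "glycan"))
  for (s in pf_examples) {
    p <- pf_parse(s)
    req <- pf_required_level(pf_profile(p))
    expect_identical(nrow(pf_validate(p, req)), 0L, info = s)
    expect_identical(nrow(pf_validate(p, full)), 0L, info = s)
  }
})
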