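test_that("verbatim serialization reproduces every input character-for-character", {
  for (s in pf_examples) {
    expect_identical(pf_serialize(pf_parse(s)), s)
  }
  expect_identical(pf_serialize(pf_parse("ELVIS[Phospho|Obs:+79.978]K")),
                   "ELVIS[Phospho|Obs:+79.978]K")
})

test_that("canonical form normalizes case, names and element order", {
  res <- pf_default_resolver()
  expect_identical(pf_serialize(pf_parse("em[oxidation]k"),
                                canonical = TRUE, resolver = res),
                   "EM[Oxidation]K")
  expect_identical(pf_serialize(pf_parse("PEPTIDE"), canonical = TRUE),
                   "PEPTIDE")
  # Obs: after the chemistry element, INFO: last
  expect_identical(
    pf_serialize(pf_parse("ELVIS[INFO:x|Obs:+79.978|Phospho]K"),
                 canonical = TRUE, resolver = res),
    "ELVIS[Phospho|Obs:+79.978|INFO:x]K")
  # group labels lowercase except the reserved BRANCH
  expect_identical(
    pf_serialize(pf_parse("EMEVTK[XLMOD:02001#XL1]SESPEK[#XL1]"),
                 canonical = TRUE, resolver = res),
    "EMEVTK[XLMOD:02001#xl1]SESPEK[#xl1]")
  expect_identical(
    pf_serialize(pf_parse("ETFGD[MOD:00093#branch]//R[#Branch]ATER"),
                 canonical = TRUE, resolver = res),
    "ETFGD[MOD:00093#BRANCH]//R[#BRANCH]ATER")
  # delta-mass lexemes keep their author-written decimal places
  expect_identical(pf_serialize(pf_parse("EM[+15.99490]K"),
                                canonical = TRUE),
                   "EM[+15.99490]K")
})

test_that("canonical serialization is idempotent and round-trips the corpus", {
  res <- pf_default_resolver()
  for (s in pf_examples) {
    p <- pf_parse(s)
    can <- pf_serialize(p, canonical = TRUE, resolver = res)
    p2 <- pf_parse(can)
    expect_true(pf_equivalent(p, p2))
    expect_identical(pf_serialize(p2, canonical = TRUE, resolver = res),
                     can)
  }
})

test_that("serialization from a bare model (no source text) re-parses equivalently", {
  for (s in pf_examples) {
    p <- pf_parse(s)
    p$source_text <- NULL
    out <- pf_serialize(p)
    expect_true(pf_equivalent(pf_parse(out), pf_parse(s)))
  }
})

test_that("JSON rendering is stable and machine-readable", {
  js <- pf_to_json(pf_parse("EMEVEESPEK/2"))
  obj <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_identical(obj$members[[1L]]$charge, 2L)
  expect_identical(obj$members[[1L]]$complex$chains[[1L]]$sequence,
                   "EMEVEESPEK")
  expect_identical(obj$text, "EMEVEESPEK/2")

  js <- pf_to_json(pf_parse("EM[Oxidation]K"))
  obj <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  tag <- obj$members[[1L]]$complex$chains[[1L]]$residues[[2L]]$tags[[1L]]
  expect_identical(tag$elements[[1L]]$name, "Oxidation")
})
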