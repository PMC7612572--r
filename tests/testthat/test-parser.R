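test_that("unmodified and accession-tagged sequences parse to the right structure", {
  p <- pf_parse("PEPTIDE")
  expect_length(p$members, 1L)
  chain <- p$members[[1L]]$complex$chains[[1L]]
  expect_length(chain$residues, 7L)
  expect_identical(pf_sequence(chain), "PEPTIDE")
  expect_true(all(vapply(chain$residues, function(r) length(r$mods), 0L) == 0L))
  expect_identical(p$members[[1L]]$complex$link_mode, "none")
  expect_null(p$members[[1L]]$charge)

  p <- pf_parse("EM[MOD:00719]EVEES[MOD:00046]PEK")
  chain <- p$members[[1L]]$complex$chains[[1L]]
  expect_length(chain$residues, 10L)
  el <- chain$residues[[2L]]$mods[[1L]]$elements[[1L]]
  expect_identical(el[c("kind", "source", "accession")],
                   list(kind = "cv_accession", source = "MOD",
                        accession = "00719"))
  el7 <- chain$residues[[7L]]$mods[[1L]]$elements[[1L]]
  expect_identical(el7$accession, "00046")
})

test_that("cross-links, branches and chain separators are recognized", {
  p <- pf_parse("EMEVTK[XLMOD:02001#XL1]SESPEK[#XL1]")
  cx <- p$members[[1L]]$complex
  expect_identical(cx$link_mode, "cross_link")
  chain <- cx$chains[[1L]]
  def <- chain$residues[[6L]]$mods[[1L]]
  expect_identical(def$elements[[1L]]$source, "XLMOD")
  expect_identical(def$elements[[1L]]$accession, "02001")
  expect_true(def$group$is_defining)
  expect_identical(def$group$label, "XL1")
  ref <- chain$residues[[12L]]$mods[[1L]]
  expect_length(ref$elements, 0L)
  expect_false(ref$group$is_defining)

  p <- pf_parse("SEK[XLMOD:02001#XL1]UENCE//EMEVTK[#XL1]SESPEK")
  expect_length(p$members[[1L]]$complex$chains, 2L)
  expect_identical(p$members[[1L]]$complex$link_mode, "cross_link")

  p <- pf_parse("ETFGD[MOD:00093#BRANCH]//R[#BRANCH]ATER")
  expect_identical(p$members[[1L]]$complex$link_mode, "branch")

  # ambiguity groups are not cross-links
  p <- pf_parse("EMEVT[#g1]S[#g1]ES[Phospho#g1]PEK")
  expect_identical(p$members[[1L]]$complex$link_mode, "none")
})

test_that("terminal, labile and unknown-position context parses", {
  p <- pf_parse("[iTRAQ4plex]-EMEVNESPEK")
  chain <- p$members[[1L]]$complex$chains[[1L]]
  expect_length(chain$residues, 10L)
  expect_length(chain$n_term_mods, 1L)
  expect_identical(chain$n_term_mods[[1L]]$elements[[1L]]$name, "iTRAQ4plex")

  chain <- pf_parse("EMEVNESPEK-[Oxidation]")$members[[1L]]$complex$chains[[1L]]
  expect_length(chain$c_term_mods, 1L)

  chain <- pf_parse("{Glycan:Hex}EMEVNESPEK")$members[[1L]]$complex$chains[[1L]]
  expect_length(chain$labile_mods, 1L)
  comp <- chain$labile_mods[[1L]]$elements[[1L]]$composition
  expect_identical(comp$monosaccharide, "Hex")
  expect_identical(comp$count, 1L)

  chain <- pf_parse("[Phospho]?EMEVTSESPEK")$members[[1L]]$complex$chains[[1L]]
  expect_length(chain$unknown_position_mods, 1L)
  expect_identical(chain$unknown_position_mods[[1L]]$multiplicity, 1L)

  chain <- pf_parse("[Phospho]^2?EMEVTSESPEK")$members[[1L]]$complex$chains[[1L]]
  expect_identical(chain$unknown_position_mods[[1L]]$multiplicity, 2L)
})

test_that("ranges and order-ambiguous segments use half-open 0-based intervals", {
  chain <- pf_parse("PROT(ESFRMS)[+19.0523]ISK")$members[[1L]]$complex$chains[[1L]]
  expect_length(chain$ranges, 1L)
  expect_identical(chain$ranges[[1L]][c("start", "end")],
                   list(start = 4L, end = 10L))
  expect_identical(chain$ranges[[1L]]$tag$elements[[1L]]$value, 19.0523)
  expect_identical(pf_sequence(chain), "PROTESFRMSISK")

  chain <- pf_parse("(?DQ)NGTWEMESNENFEGYMK")$members[[1L]]$complex$chains[[1L]]
  expect_identical(chain$unordered_segments, list(c(0L, 2L)))
  expect_identical(substr(pf_sequence(chain), 1L, 2L), "DQ")
})

test_that("charges and chimeric members parse, including signed charges", {
  p <- pf_parse("EMEVEESPEK/2+ELVISLIVER/3")
  expect_length(p$members, 2L)
  expect_identical(p$members[[1L]]$charge, 2L)
  expect_identical(p$members[[2L]]$charge, 3L)
  expect_identical(pf_parse("PEPTIDE/-2")$members[[1L]]$charge, -2L)
  expect_identical(pf_parse("PEPTIDE/+4")$members[[1L]]$charge, 4L)
})

test_that("global rules parse: isotopes and fixed modifications", {
  chain <- pf_parse("<13C>ATPEILTVNSIGQLK")$members[[1L]]$complex$chains[[1L]]
  expect_identical(chain$isotope_rules[[1L]]$mass_number, 13L)
  expect_identical(chain$isotope_rules[[1L]]$element, "C")

  chain <- pf_parse("<[MOD:01090]@C>ATPEILTCNSIGCLK")$members[[1L]]$complex$chains[[1L]]
  expect_length(chain$fixed_rules, 1L)
  expect_identical(chain$fixed_rules[[1L]]$targets, "C")
  expect_identical(chain$fixed_rules[[1L]]$tag$elements[[1L]]$accession,
                   "01090")

  chain <- pf_parse("<[Carbamidomethyl]@C,M>ATPEILTCNSIGCLK")$members[[1L]]$complex$chains[[1L]]
  expect_identical(chain$fixed_rules[[1L]]$targets, c("C", "M"))
})

test_that("tag payloads split on pipes and classify every element kind", {
  tag <- pf_parse_tag("Phospho|INFO:newly discovered")
  expect_identical(vapply(tag$elements, `[[`, "", "kind"),
                   c("cv_name", "info"))
  expect_identical(tag$elements[[2L]]$text, "newly discovered")

  tag <- pf_parse_tag("Phospho|Obs:+79.978")
  expect_identical(tag$elements[[2L]]$kind, "observed_mass")
  expect_identical(tag$elements[[2L]]$value, 79.978)

  tag <- pf_parse_tag("#g1(0.01)")
  expect_length(tag$elements, 0L)
  expect_identical(tag$group$label, "g1")
  expect_identical(tag$group$score, 0.01)
  expect_false(tag$group$is_defining)

  tag <- pf_parse_tag("GNO:G59626AS")
  expect_identical(tag$elements[[1L]][c("source", "accession")],
                   list(source = "GNO", accession = "G59626AS"))

  tag <- pf_parse_tag("Formula:[13C2]CH6N")
  comp <- tag$elements[[1L]]$composition
  expect_identical(comp$element, c("C", "C", "H", "N"))
  expect_identical(comp$isotope, c(13L, NA, NA, NA))
  expect_identical(comp$count, c(2L, 1L, 6L, 1L))

  tag <- pf_parse_tag("+15.99490")
  expect_identical(tag$elements[[1L]]$value, 15.9949)
  expect_identical(tag$elements[[1L]]$lexeme, "+15.99490")
})

test_that("gap residues are X plus a delta-mass tag", {
  chain <- pf_parse("RTAAX[+367.0537]WT")$members[[1L]]$complex$chains[[1L]]
  expect_identical(chain$residues[[5L]]$letter, "X")
  expect_identical(chain$residues[[5L]]$mods[[1L]]$elements[[1L]]$value,
                   367.0537)
})

test_that("tokenizer reports payload spans, separators and offsets", {
  tk <- pf_tokenize("A[+1.0]")
  expect_identical(tk$type, c("residue", "tag"))
  expect_identical(tk$text, c("A", "+1.0"))
  expect_identical(tk$start, c(1L, 2L))

  tk <- pf_tokenize("SEK[XLMOD:02001#XL1]UENCE//EMEVTK[#XL1]SESPEK")
  expect_identical(sum(tk$type == "dslash"), 1L)

  tk <- pf_tokenize("<13C>ATP")
  expect_identical(tk$type[1L], "global")
  expect_identical(tk$text[1L], "13C")
})

test_that("malformed input is rejected with position-annotated errors", {
  expect_offset <- function(text, offset) {
    err <- tryCatch(pf_parse(text), pf_parse_error = function(e) e)
    expect_s3_class(err, "pf_parse_error")
    expect_identical(err$offset, offset)
  }
  expect_offset("EM[Ox", 3L)       # unbalanced bracket
  expect_offset("]K", 1L)          # stray close
  expect_offset("A/2.5", 4L)       # fractional charge
  expect_offset("(?DQ", 1L)        # unclosed segment
  expect_offset("PEP\nTIDE", 4L)   # line break
  expect_error(pf_parse(""), class = "pf_parse_error")
  expect_error(pf_parse("A[Foo:bar]"), class = "pf_parse_error",
               regexp = "unknown tag prefix")
  expect_error(pf_parse("PEP[#g1]TIDE"), class = "pf_parse_error",
               regexp = "dangling group reference")
  expect_error(pf_parse("PEP TIDE"), class = "pf_parse_error",
               regexp = "unexpected character")
  expect_error(pf_parse("PEPT1DE"), class = "pf_parse_error")
  expect_error(pf_parse("[Phospho]PEP"), class = "pf_parse_error",
               regexp = "followed by '\\?' or '-'")
  expect_error(pf_parse("PROT(ESFRMS)ISK"), class = "pf_parse_error",
               regexp = "range must be followed")
  expect_error(pf_parse("PEPTIDE/0"), class = "pf_parse_error",
               regexp = "nonzero")
  expect_error(pf_parse("A[+1.0|]B"), class = "pf_parse_error",
               regexp = "empty tag element")
  expect_error(pf_parse("<13>PEP"), class = "pf_parse_error")
  expect_error(pf_parse("<[Phospho]>PEP"), class = "pf_parse_error",
               regexp = "@")
})

test_that("the bundled example file matches the in-suite corpus", {
  path <- system.file("extdata", "notation_examples.txt",
                      package = "proforma")
  expect_identical(unname(pf_read_file(path, parse = FALSE)),
                   unname(pf_examples))
  parsed <- pf_read_file(path)
  expect_length(parsed, length(pf_examples))
  expect_true(all(vapply(parsed, inherits, TRUE, "pf_set")))
})
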