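# The canonical one-example-per-feature corpus, used throughout the suite.
# Mirrors inst/extdata/notation_examples.txt (a test asserts they agree).
pf_examples <- c(
  cv_name            = "EM[Oxidation]EVEES[Phospho]PEK",
  cv_accession       = "EM[MOD:00719]EVEES[MOD:00046]PEK",
  crosslink_intra    = "EMEVTK[XLMOD:02001#XL1]SESPEK[#XL1]",
  crosslink_inter    = "SEK[XLMOD:02001#XL1]UENCE//EMEVTK[#XL1]SESPEK",
  disulfide          = "EVTSEKC[MOD:00034#XL1]LEMSC[#XL1]EFD",
  branch             = "ETFGD[MOD:00093#BRANCH]//R[#BRANCH]ATER",
  gno                = "NEEYN[GNO:G59626AS]K",
  delta_mass         = "EM[+15.9949]EVEES[+79.9663]PEK",
  gap                = "RTAAX[+367.0537]WT",
  formula            = "SEQUEN[Formula:C12H20O2]CE",
  glycan_composition = "SEQUEN[Glycan:HexNAc1Hex2]CE",
  terminal_mods      = "[iTRAQ4plex]-EMEVNESPEK",
  labile             = "{Glycan:Hex}EMEVNESPEK",
  unknown_position   = "[Phospho]?EMEVTSESPEK",
  position_set       = "EMEVT[#g1]S[#g1]ES[Phospho#g1]PEK",
  range              = "PROT(ESFRMS)[+19.0523]ISK",
  loc_scores         = "EMEVT[#g1(0.01)]S[#g1(0.09)]ES[Phospho#g1(0.90)]PEK",
  range_scores       = "PROT(ESFRMS)[+19.0523#g1(0.01)]ISK[#g1(0.99)]",
  isotope            = "<13C>ATPEILTVNSIGQLK",
  fixed_mod          = "<[MOD:01090]@C>ATPEILTCNSIGCLK",
  order_ambiguity    = "(?DQ)NGTWEMESNENFEGYMK",
  info_tag           = "ELVIS[Phospho|INFO:newly discovered]K",
  observed_mass      = "ELVIS[Phospho|Obs:+79.978]K",
  charge             = "EMEVEESPEK/2",
  chimeric           = "EMEVEESPEK/2+ELVISLIVER/3"
)

# Independent residue-mass oracle: IUPAC monoisotopic residue masses,
# transcribed (not derived from the package's elemental tables) so that
# backbone sums are cross-checked against a second source.
pf_oracle_residue_mass <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)
pf_oracle_water <- 18.01056

pf_oracle_backbone <- function(seq) {
  aa <- strsplit(seq, "")[[1L]]
  sum(pf_oracle_residue_mass[aa]) + pf_oracle_water
}

# Plain (unmodified) backbone sequence of every chain in a parsed model,
# mass gaps (X) excluded since they carry no residue mass.
pf_plain_backbone <- function(set) {
  out <- character(0L)
  for (m in set$members) {
    for (chain in m$complex$chains) {
      letters <- vapply(chain$residues, `[[`, "", "letter")
      out <- c(out, paste(letters[letters != "X"], collapse = ""))
    }
  }
  out
}

pf_run_cli <- function(args, input = NULL) {
  script <- system.file("cli", "proforma", package = "proforma")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(shQuote(script), vapply(args, shQuote, "")),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
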