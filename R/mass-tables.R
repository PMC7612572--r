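# Monoisotopic mass tables.
#
# Atomic masses are the masses of the most abundant (principal) isotope of
# each element, taken from the NIST Atomic Weights and Isotopic Compositions
# compilation (AME2020-based values, accessed 2021); frozen here so that
# results are reproducible independent of any external library.

.pf_atomic_mass <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  Se = 79.9165213,
  Na = 22.9897692809,
  K  = 38.96370668,
  Ca = 39.96259098,
  Mg = 23.9850417,
  Fe = 55.9349375,
  Zn = 63.9291422,
  Cu = 62.9295975,
  Mn = 54.9380451,
  Ni = 57.9353429,
  Co = 58.9331950,
  F  = 18.99840322,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473,
  Si = 27.9769265325,
  B  = 11.0093054,
  Li = 7.01600455,
  As = 74.9215965,
  Mo = 97.9054082,
  W  = 183.9509312,
  Hg = 201.970643,
  Au = 196.9665687,
  Pt = 194.9647911
)

# Specific isotopes addressable in formulas ([13C2]) and in global isotope
# rules (<13C>), keyed by "<mass number><symbol>".
.pf_isotope_mass <- c(
  `2H`   = 2.01410177785,
  `3H`   = 3.01604927767,
  `13C`  = 13.00335483507,
  `14C`  = 14.0032419884,
  `15N`  = 15.00010889888,
  `17O`  = 16.99913175650,
  `18O`  = 17.99915961286,
  `33S`  = 32.97145876,
  `34S`  = 33.96786690,
  `36S`  = 35.96708071,
  `37Cl` = 36.96590259,
  `81Br` = 80.9162906,
  `76Se` = 75.9192136,
  `77Se` = 76.9199140,
  `78Se` = 77.9173091,
  `82Se` = 81.9166994
)

.pf_proton_mass <- 1.00727646688

# Elemental composition of amino acid residues (the in-chain residue, i.e.
# the amino acid minus water).  B (Asx), Z (Glx) and X have no defined
# composition; J (Leu/Ile) is compositionally unambiguous.
.pf_residue_comp <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1),
  A = c(C = 3,  H = 5,  N = 1, O = 1),
  S = c(C = 3,  H = 5,  N = 1, O = 2),
  P = c(C = 5,  H = 7,  N = 1, O = 1),
  V = c(C = 5,  H = 9,  N = 1, O = 1),
  T = c(C = 4,  H = 7,  N = 1, O = 2),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1),
  I = c(C = 6,  H = 11, N = 1, O = 1),
  J = c(C = 6,  H = 11, N = 1, O = 1),
  N = c(C = 4,  H = 6,  N = 2, O = 2),
  D = c(C = 4,  H = 5,  N = 1, O = 3),
  Q = c(C = 5,  H = 8,  N = 2, O = 2),
  K = c(C = 6,  H = 12, N = 2, O = 1),
  E = c(C = 5,  H = 7,  N = 1, O = 3),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1),
  F = c(C = 9,  H = 9,  N = 1, O = 1),
  R = c(C = 6,  H = 12, N = 4, O = 1),
  Y = c(C = 9,  H = 9,  N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1),
  U = c(C = 3,  H = 5,  N = 1, O = 1, Se = 1),
  O = c(C = 12, H = 19, N = 3, O = 2)
)

.pf_water_comp <- c(H = 2, O = 1)

# Residue letters legal in sequence position.  X carries mass gaps; B, J,
# O, U, Z cover the IUPAC extended alphabet.
.pf_residue_alphabet <- c(names(.pf_residue_comp), "B", "Z", "X")

# Monosaccharide residue (dehydro) compositions for Glycan: composition
# strings.  Masses are derived from these at run time.
.pf_glycan_comp <- list(
  Hex    = c(C = 6,  H = 10, O = 5),
  HexNAc = c(C = 8,  H = 13, N = 1, O = 5),
  dHex   = c(C = 6,  H = 10, O = 4),
  Fuc    = c(C = 6,  H = 10, O = 4),
  NeuAc  = c(C = 11, H = 17, N = 1, O = 8),
  NeuGc  = c(C = 11, H = 17, N = 1, O = 9),
  Neu5Ac = c(C = 11, H = 17, N = 1, O = 8),
  Neu5Gc = c(C = 11, H = 17, N = 1, O = 9),
  Pen    = c(C = 5,  H = 8,  O = 4),
  HexS   = c(C = 6,  H = 10, O = 8, S = 1),
  HexP   = c(C = 6,  H = 11, O = 8, P = 1)
)

# Monoisotopic mass of an elemental composition given as a named count
# vector; `isotopes` optionally maps element symbols to a specific mass
# number (global isotope rules).
.pf_comp_mass <- function(comp, isotopes = NULL) {
  if (length(comp) == 0L) return(0)
  syms <- names(comp)
  m <- .pf_atomic_mass[syms]
  if (!is.null(isotopes) && length(isotopes)) {
    hit <- syms %in% names(isotopes)
    if (any(hit)) {
      key <- paste0(isotopes[syms[hit]], syms[hit])
      im <- .pf_isotope_mass[key]
      if (anyNA(im)) {
        stop("no mass table entry for isotope ", key[is.na(im)][1L],
             call. = FALSE)
      }
      m[hit] <- im
    }
  }
  if (anyNA(m)) {
    stop("unknown element symbol: ", syms[is.na(m)][1L], call. = FALSE)
  }
  sum(m * comp)
}
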