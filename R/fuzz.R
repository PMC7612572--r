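# Deterministic fuzz-corpus generator.
#
# Emits syntactically valid ProForma strings over random sequences of
# length 5-50, drawing every notation feature with a fixed incidence of
# at least 2%, so that a corpus of a few thousand strings exercises the
# whole grammar.  Structurally conflicting features (the interval-based
# ones, and the linkage ones) are drawn from categorical choices so that
# intervals never overlap and group labels never collide.

.pf_fuzz_names <- c("Oxidation", "Phospho", "Acetyl", "Carbamidomethyl",
                    "iTRAQ4plex")
.pf_fuzz_accessions <- c("MOD:00719", "MOD:00046", "UNIMOD:35", "UNIMOD:21",
                         "UNIMOD:1", "RESID:AA0038")

.pf_fuzz_delta <- function() {
  sprintf("%+.4f", stats::runif(1L, 0.5, 400) *
            sample(c(-1, 1), 1L, prob = c(0.2, 0.8)))
}

.pf_fuzz_tag_body <- function() {
  k <- sample.int(6L, 1L,
                  prob = c(0.30, 0.18, 0.28, 0.08, 0.08, 0.08))
  body <- switch(k,
    sample(.pf_fuzz_names, 1L),
    sample(.pf_fuzz_accessions, 1L),
    .pf_fuzz_delta(),
    paste0("Formula:C", sample(1:20, 1L), "H", sample(1:30, 1L),
           if (stats::runif(1L) < 0.3) paste0("O", sample(1:5, 1L)) else "",
           if (stats::runif(1L) < 0.15) "[13C2]" else ""),
    paste0("Glycan:",
           paste0(sample(c("Hex", "HexNAc", "NeuAc", "dHex"),
                         sample(1:2, 1L)),
                  sample(1:3, sample(1:2, 1L)[1L], replace = TRUE),
                  collapse = "")),
    sample(.pf_fuzz_names, 1L))
  if (stats::runif(1L) < 0.08) {
    body <- paste0(body, "|Obs:", .pf_fuzz_delta())
  }
  if (stats::runif(1L) < 0.08) {
    body <- paste0(body, "|INFO:", paste(sample(c(letters, " "), 8L,
                                                replace = TRUE),
                                         collapse = ""))
  }
  body
}

.pf_fuzz_member <- function() {
  len <- sample(5:50, 1L)
  aa <- sample(names(.pf_residue_comp)[1:20], len, replace = TRUE)
  mods <- character(len)

  # residue-level tags
  for (i in seq_len(len)) {
    if (stats::runif(1L) < 0.06) {
      mods[i] <- paste0("[", .pf_fuzz_tag_body(), "]")
    }
  }
  if (stats::runif(1L) < 0.03) {  # mass gap
    i <- sample.int(len, 1L)
    aa[i] <- "X"
    mods[i] <- paste0("[", .pf_fuzz_delta(), "]")
  }
  if (stats::runif(1L) < 0.04) {  # GNO glycan site
    i <- sample.int(len, 1L)
    mods[i] <- "[GNO:G59626AS]"
  }

  # one interval / ambiguity construct per member, on the residue midriff
  prefix <- character(0L)
  iv <- sample.int(6L, 1L, prob = c(0.06, 0.03, 0.05, 0.06, 0.05, 0.75))
  lo <- max(2L, len %/% 3L); hi <- min(len - 1L, lo + 4L)
  seg <- function(open) {
    mods[lo:hi] <<- ""
    c(paste0(aa[seq_len(lo - 1L)], mods[seq_len(lo - 1L)]),
      open,
      aa[lo:hi],
      ")",
      if (hi < len) paste0(aa[(hi + 1L):len], mods[(hi + 1L):len]))
  }
  body <- NULL
  if (iv == 1L) {          # range
    body <- c(seg("("), NULL)
    body <- append(body, paste0("[", .pf_fuzz_delta(), "]"),
                   after = which(body == ")")[1L])
  } else if (iv == 2L) {   # scored range + scored reference
    body <- seg("(")
    at <- which(body == ")")[1L]
    body <- append(body, "[+19.0523#r1(0.01)]", after = at)
    body[length(body)] <- paste0(body[length(body)], "[#r1(0.99)]")
  } else if (iv == 3L) {   # order-ambiguous segment
    body <- seg("(?")
  } else if (iv == 4L) {   # localization scores summing to 1
    pos <- sort(sample.int(len, 3L))
    s <- c(0.05, 0.15, 0.80)
    mods[pos[1L]] <- sprintf("[#s1(%.2f)]", s[1L])
    mods[pos[2L]] <- sprintf("[#s1(%.2f)]", s[2L])
    mods[pos[3L]] <- sprintf("[Phospho#s1(%.2f)]", s[3L])
    body <- paste0(aa, mods)
  } else if (iv == 5L) {   # unscored position set
    pos <- sort(sample.int(len, 2L))
    mods[pos[1L]] <- "[#a1]"
    mods[pos[2L]] <- "[Phospho#a1]"
    body <- paste0(aa, mods)
  } else {
    body <- paste0(aa, mods)
  }
  seq_text <- paste(body, collapse = "")

  # linkage: at most one construct, so labels never collide
  link <- sample.int(5L, 1L, prob = c(0.05, 0.035, 0.025, 0.025, 0.865))
  if (link == 1L) {        # intra-chain cross-link
    p <- sort(sample.int(len, 2L))
    mods2 <- character(len)
    mods2[p[1L]] <- "[XLMOD:02001#XL9]"
    mods2[p[2L]] <- "[#XL9]"
    seq_text <- paste0(paste0(aa, mods2), collapse = "")
  } else if (link == 2L) { # inter-chain cross-link
    len2 <- sample(5:15, 1L)
    aa2 <- sample(names(.pf_residue_comp)[1:20], len2, replace = TRUE)
    seq_text <- paste0(
      paste0(aa[1L:min(10L, len)], collapse = ""),
      "K[XLMOD:02001#XL9]//",
      paste0(aa2, collapse = ""), "K[#XL9]")
  } else if (link == 3L) { # disulfide
    p <- sort(sample.int(len, 2L))
    aa[p] <- "C"
    mods2 <- character(len)
    mods2[p[1L]] <- "[MOD:00034#XL9]"
    mods2[p[2L]] <- "[#XL9]"
    seq_text <- paste0(paste0(aa, mods2), collapse = "")
  } else if (link == 4L) { # branched peptide
    len2 <- sample(3:8, 1L)
    aa2 <- sample(names(.pf_residue_comp)[1:20], len2, replace = TRUE)
    seq_text <- paste0(
      paste0(aa[1L:min(8L, len)], collapse = ""),
      "[MOD:00093#BRANCH]//",
      paste0(aa2, collapse = ""), "[#BRANCH]")
  }

  # prefixes: global rules, labile, unknown position, N-terminal
  if (stats::runif(1L) < 0.03) {
    prefix <- c(prefix, sample(c("<13C>", "<15N>", "<2H>"), 1L))
  }
  if (stats::runif(1L) < 0.03) {
    prefix <- c(prefix, "<[Carbamidomethyl]@C,M>")
  }
  if (stats::runif(1L) < 0.04) {
    prefix <- c(prefix, sample(c("{Glycan:Hex}", "{Glycan:HexNAc1Hex2}"),
                               1L))
  }
  if (stats::runif(1L) < 0.05) {
    mult <- sample(c("", "^2"), 1L, prob = c(0.7, 0.3))
    prefix <- c(prefix, paste0("[", sample(.pf_fuzz_names, 1L), "]",
                               mult, "?"))
  }
  if (stats::runif(1L) < 0.08) {
    prefix <- c(prefix, paste0("[", sample(c("iTRAQ4plex", "Acetyl"), 1L),
                               "]-"))
  }
  suffix <- if (stats::runif(1L) < 0.05) {
    paste0("-[", sample(.pf_fuzz_names, 1L), "]")
  } else ""
  charge <- if (stats::runif(1L) < 0.15) {
    z <- sample(1:5, 1L)
    if (stats::runif(1L) < 0.15) z <- -z
    paste0("/", z)
  } else ""
  paste0(paste(prefix, collapse = ""), seq_text, suffix, charge)
}

#' Generate a deterministic fuzz corpus of valid ProForma strings
#'
#' Every emitted string is syntactically valid and parses with
#' [pf_parse()]; the generator exercises all notation features (each with
#' at least 2% incidence) over random sequences of 5-50 residues.  The
#' corpus is reproducible for a fixed seed and leaves the caller's random
#' number generator state untouched.
#'
#' @param n number of strings (>= 1).
#' @param seed integer RNG seed.
#' @return a character vector of length `n`.
#' @examples
#' pf_fuzz(3, seed = 1)
#' @export
pf_fuzz <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  out <- character(n)
  for (i in seq_len(n)) {
    member <- .pf_fuzz_member()
    if (stats::runif(1L) < 0.05 && !grepl("/", member, fixed = TRUE)) {
      # chimeric: both members need a charge for the '+' to be unambiguous
      member <- paste0(member, "/2+", .pf_fuzz_simple(), "/3")
    }
    out[i] <- member
  }
  out
}

.pf_fuzz_simple <- function() {
  len <- sample(5:15, 1L)
  paste0(sample(names(.pf_residue_comp)[1:20], len, replace = TRUE),
         collapse = "")
}
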