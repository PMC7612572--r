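# Recursive-descent parser: token stream -> object model.
#
# Top level:   set     := member ('+' member)*
#              member  := complex ('/' charge)?
#              complex := chain ('//' chain)*
# Chain level: global rules '<...>', labile '{...}', unknown-position
#              '[tag](^n)?...?' and N-terminal '[tag]...-' prefixes, then
#              residues with attached tags, ranges '(SEQ)[tag]', order-
#              ambiguous segments '(?SEQ)', and a C-terminal '-[tag]' suffix.

.pf_cv_sources <- c("UNIMOD", "MOD", "RESID", "XLMOD", "GNO")

# ---- tag payload ------------------------------------------------------------

# Split a payload on '|' outside any nested () or [].
.pf_pipe_split <- function(payload) {
  chars <- strsplit(payload, "", fixed = TRUE)[[1L]]
  depth <- 0L
  cuts <- integer(0L)
  for (j in seq_along(chars)) {
    cj <- chars[j]
    if (cj == "[" || cj == "(") depth <- depth + 1L
    else if (cj == "]" || cj == ")") depth <- depth - 1L
    else if (cj == "|" && depth == 0L) cuts <- c(cuts, j)
  }
  if (length(cuts) == 0L) return(list(text = payload, at = 0L))
  lo <- c(1L, cuts + 1L)
  hi <- c(cuts - 1L, length(chars))
  list(text = substring(payload, lo, hi), at = lo - 1L)
}

.pf_parse_group_spec <- function(spec, offset, text) {
  # spec is the text after '#': "label" or "label(score)"
  op <- regexpr("(", spec, fixed = TRUE)
  if (op == -1L) {
    if (!nzchar(spec)) pf_parse_error("empty group label", offset, text)
    return(list(label = spec, score = NULL, score_lexeme = NULL))
  }
  label <- substr(spec, 1L, op - 1L)
  if (!nzchar(label)) pf_parse_error("empty group label", offset, text)
  rest <- substr(spec, op, nchar(spec))
  m <- regmatches(rest, regexec("^\\(([0-9]*\\.?[0-9]+)\\)$", rest))[[1L]]
  if (length(m) == 0L) {
    pf_parse_error("malformed localization score", offset + op, text)
  }
  list(label = label, score = as.numeric(m[2L]), score_lexeme = m[2L])
}

# Element symbols are normalized to standard capitalization so that the
# format's case-insensitivity holds for formulas: the character after a
# letter joins the symbol only when it is written in lowercase and the
# resulting two-letter symbol is a known element ("co2" is cobalt, "CO2"
# is carbon plus two oxygens).
.pf_formula_symbol <- function(t, i, nt) {
  c1 <- substr(t, i, i)
  if (!c1 %in% c(LETTERS, letters)) return(NULL)
  c2 <- if (i < nt) substr(t, i + 1L, i + 1L) else ""
  if (c2 %in% letters) {
    two <- paste0(toupper(c1), c2)
    if (two %in% names(.pf_atomic_mass)) {
      return(list(symbol = two, width = 2L))
    }
  }
  list(symbol = toupper(c1), width = 1L)
}

.pf_parse_formula <- function(s, offset, text) {
  t <- gsub(" ", "", s, fixed = TRUE)
  element <- character(0L); isotope <- integer(0L); count <- integer(0L)
  i <- 1L; nt <- nchar(t)
  digits <- as.character(0:9)
  while (i <= nt) {
    ch <- substr(t, i, i)
    iso <- NA_integer_
    if (ch == "[") {
      j <- regexpr("]", substr(t, i, nt), fixed = TRUE)
      if (j == -1L) pf_parse_error("unbalanced '[' in formula", offset, text)
      inner <- substr(t, i + 1L, i + j - 2L)
      m <- regmatches(inner, regexec("^([0-9]+)", inner))[[1L]]
      sym <- if (length(m)) {
        .pf_formula_symbol(inner, nchar(m[2L]) + 1L, nchar(inner))
      } else NULL
      bad <- is.null(sym)
      if (!bad) {
        iso <- as.integer(m[2L])
        cnt_text <- substr(inner, nchar(m[2L]) + sym$width + 1L,
                           nchar(inner))
        cnt <- if (nzchar(cnt_text)) suppressWarnings(as.integer(cnt_text))
               else 1L
        bad <- is.na(cnt) ||
          !grepl("^(-?[0-9]+)?$", cnt_text)
      }
      if (bad) {
        pf_parse_error(paste0("malformed isotope group [", inner,
                              "] in formula"), offset, text)
      }
      i <- i + j
    } else {
      sym <- .pf_formula_symbol(t, i, nt)
      if (is.null(sym)) {
        pf_parse_error(paste0("malformed formula near '",
                              substr(t, i, i + 4L), "'"), offset, text)
      }
      i <- i + sym$width
      j <- i
      if (j <= nt && substr(t, j, j) == "-") j <- j + 1L
      while (j <= nt && substr(t, j, j) %in% digits) j <- j + 1L
      cnt_text <- substr(t, i, j - 1L)
      cnt <- if (cnt_text %in% c("", "-")) {
        if (cnt_text == "-") {
          pf_parse_error("malformed formula count", offset, text)
        }
        1L
      } else as.integer(cnt_text)
      i <- j
    }
    if (cnt == 0L) {
      pf_parse_error("formula atom count must be nonzero", offset, text)
    }
    element <- c(element, sym$symbol)
    isotope <- c(isotope, iso)
    count <- c(count, cnt)
  }
  data.frame(element = element, isotope = isotope, count = count,
             stringsAsFactors = FALSE)
}

.pf_glycan_names <- local({
  nm <- names(.pf_glycan_comp)
  nm[order(-nchar(nm))]
})

.pf_parse_glycan <- function(s, offset, text) {
  t <- gsub(" ", "", s, fixed = TRUE)
  mono <- character(0L); count <- integer(0L)
  i <- 1L; nt <- nchar(t)
  while (i <= nt) {
    hit <- NULL
    for (nm in .pf_glycan_names) {
      if (toupper(substr(t, i, i + nchar(nm) - 1L)) == toupper(nm)) {
        hit <- nm
        break
      }
    }
    if (is.null(hit)) {
      pf_parse_error(paste0("unknown monosaccharide near '",
                            substr(t, i, i + 5L), "'"), offset, text)
    }
    i <- i + nchar(hit)
    j <- i
    while (j <= nt && substr(t, j, j) %in% as.character(0:9)) {
      j <- j + 1L
    }
    cnt <- if (j > i) as.integer(substr(t, i, j - 1L)) else 1L
    if (cnt < 1L) {
      pf_parse_error("monosaccharide count must be >= 1", offset, text)
    }
    mono <- c(mono, hit)
    count <- c(count, cnt)
    i <- j
  }
  data.frame(monosaccharide = mono, count = count, stringsAsFactors = FALSE)
}

.pf_num_re <- "^[+-]?[0-9]+(\\.[0-9]+)?$"

#' Parse the payload of one bracketed modification tag
#'
#' Splits the text between one matched bracket pair on `|` and classifies
#' each element: CV accessions (`MOD:`, `UNIMOD:`, `RESID:`, `XLMOD:`,
#' `GNO:`), chemical formulas (`Formula:`), glycan compositions
#' (`Glycan:`), observed masses (`Obs:`), free-text information (`INFO:`),
#' delta masses (leading sign and digits), ambiguity-group references
#' (`#label` with optional `(score)`), and otherwise CV names.  All
#' prefixes are recognized case-insensitively.
#'
#' @param payload text between one `[` `]` pair.
#' @param offset 1-based offset of the payload within the full string
#'   (used in error messages).
#' @param text the full string being parsed (error context only).
#' @return a `pf_tag`.
#' @examples
#' pf_parse_tag("Phospho|Obs:+79.978")
#' @export
pf_parse_tag <- function(payload, offset = 1L, text = payload) {
  parts <- .pf_pipe_split(payload)
  elements <- list()
  group <- NULL
  for (pi in seq_along(parts$text)) {
    el_text <- parts$text[pi]
    el_off <- offset + parts$at[pi]
    if (!nzchar(el_text)) {
      pf_parse_error("empty tag element", el_off, text)
    }
    pm <- regmatches(el_text, regexec("^([A-Za-z]+):", el_text))[[1L]]
    prefix <- if (length(pm)) toupper(pm[2L]) else ""
    if (prefix == "INFO") {
      elements <- c(elements,
                    list(pf_el_info(substr(el_text, 6L, nchar(el_text)))))
      next
    }
    # detach a '#label(score)' group suffix (outside parentheses)
    chem <- el_text
    gspec <- NULL
    chars <- strsplit(el_text, "", fixed = TRUE)[[1L]]
    depth <- 0L
    for (j in seq_along(chars)) {
      cj <- chars[j]
      if (cj == "(" || cj == "[") depth <- depth + 1L
      else if (cj == ")" || cj == "]") depth <- depth - 1L
      else if (cj == "#" && depth == 0L) {
        chem <- substr(el_text, 1L, j - 1L)
        gspec <- substr(el_text, j + 1L, nchar(el_text))
        break
      }
    }
    if (!is.null(gspec)) {
      if (!is.null(group)) {
        pf_parse_error("more than one group reference in a tag",
                       el_off, text)
      }
      g <- .pf_parse_group_spec(gspec, el_off, text)
      group <- new_pf_group(g$label, g$score)
      group$score_lexeme <- g$score_lexeme
    }
    if (!nzchar(chem)) next  # pure group-reference element
    pm <- regmatches(chem, regexec("^([A-Za-z]+):", chem))[[1L]]
    prefix <- if (length(pm)) toupper(pm[2L]) else ""
    body <- if (length(pm)) {
      substr(chem, nchar(pm[2L]) + 2L, nchar(chem))
    } else chem
    el <- if (prefix %in% .pf_cv_sources) {
      if (!nzchar(body)) {
        pf_parse_error("empty CV accession", el_off, text)
      }
      pf_el_cv_accession(prefix, body)
    } else if (prefix == "FORMULA") {
      pf_el_formula(.pf_parse_formula(body, el_off, text), body)
    } else if (prefix == "GLYCAN") {
      pf_el_glycan(.pf_parse_glycan(body, el_off, text), body)
    } else if (prefix == "OBS") {
      if (!grepl(.pf_num_re, body)) {
        pf_parse_error(paste0("malformed observed mass '", body, "'"),
                       el_off, text)
      }
      pf_el_observed_mass(as.numeric(body), body)
    } else if (nzchar(prefix)) {
      pf_parse_error(paste0("unknown tag prefix '", pm[2L], ":'"),
                     el_off, text)
    } else if (grepl("^[+-][0-9]", chem)) {
      if (!grepl(.pf_num_re, chem)) {
        pf_parse_error(paste0("malformed delta mass '", chem, "'"),
                       el_off, text)
      }
      pf_el_delta_mass(as.numeric(chem), chem)
    } else {
      pf_el_cv_name(chem)
    }
    elements <- c(elements, list(el))
  }
  if (length(elements) == 0L && is.null(group)) {
    pf_parse_error("empty modification tag", offset, text)
  }
  if (!is.null(group)) group$is_defining <- length(elements) > 0L
  new_pf_tag(elements, group)
}

# ---- global rules -----------------------------------------------------------

.pf_parse_global <- function(payload, offset, text) {
  m <- regmatches(payload,
                  regexec("^([0-9]+)([A-Za-z][A-Za-z]?)$", payload))[[1L]]
  if (length(m)) {
    num <- as.integer(m[2L])
    if (num <= 1L) {
      pf_parse_error("isotope mass number must be > 1", offset, text)
    }
    sym <- paste0(toupper(substr(m[3L], 1L, 1L)),
                  tolower(substr(m[3L], 2L, 2L)))
    if (!sym %in% names(.pf_atomic_mass)) {
      pf_parse_error(paste0("unknown element '", m[3L],
                            "' in isotope rule"), offset, text)
    }
    return(list(kind = "isotope", rule = new_pf_isotope_rule(num, sym)))
  }
  if (substr(payload, 1L, 1L) == "[") {
    chars <- strsplit(payload, "", fixed = TRUE)[[1L]]
    depth <- 0L
    close <- 0L
    for (j in seq_along(chars)) {
      if (chars[j] == "[") depth <- depth + 1L
      else if (chars[j] == "]") {
        depth <- depth - 1L
        if (depth == 0L) { close <- j; break }
      }
    }
    if (close == 0L) {
      pf_parse_error("unbalanced '[' in fixed-modification rule",
                     offset, text)
    }
    tag <- pf_parse_tag(substr(payload, 2L, close - 1L), offset + 1L, text)
    rest <- substr(payload, close + 1L, nchar(payload))
    if (substr(rest, 1L, 1L) != "@" || nchar(rest) < 2L) {
      pf_parse_error("fixed-modification rule needs '@' target residues",
                     offset + close, text)
    }
    targets <- toupper(strsplit(substr(rest, 2L, nchar(rest)), ",",
                                fixed = TRUE)[[1L]])
    bad <- targets[!targets %in% .pf_residue_alphabet | nchar(targets) != 1L]
    if (length(targets) == 0L || length(bad)) {
      pf_parse_error("invalid fixed-modification target residue",
                     offset + close + 1L, text)
    }
    return(list(kind = "fixed", rule = new_pf_fixed_rule(tag, targets)))
  }
  pf_parse_error(paste0("malformed global rule '<", payload, ">'"),
                 offset, text)
}

# ---- chain ------------------------------------------------------------------

.pf_parse_chain <- function(type, tex, start, lo, hi, text) {
  n_term <- list(); c_term <- list(); labile <- list()
  unknown <- list(); fixed <- list(); isotopes <- list()
  ranges <- list(); segments <- list()
  residues <- vector("list", hi - lo + 1L)
  nres <- 0L
  i <- lo

  # prefix: global rules, labile tags, unknown-position and N-terminal tags
  in_prefix <- TRUE
  while (in_prefix && i <= hi) {
    t <- type[i]
    if (t == "global") {
      g <- .pf_parse_global(tex[i], start[i] + 1L, text)
      if (g$kind == "isotope") isotopes <- c(isotopes, list(g$rule))
      else fixed <- c(fixed, list(g$rule))
      i <- i + 1L
    } else if (t == "labile") {
      labile <- c(labile, list(pf_parse_tag(tex[i], start[i] + 1L, text)))
      i <- i + 1L
    } else if (t == "tag") {
      tags <- list(); mults <- integer(0L)
      j <- i
      while (j <= hi && type[j] == "tag") {
        tags <- c(tags, list(pf_parse_tag(tex[j], start[j] + 1L, text)))
        j <- j + 1L
        if (j <= hi && type[j] == "mult") {
          mults <- c(mults, as.integer(tex[j]))
          j <- j + 1L
        } else mults <- c(mults, 1L)
      }
      if (j <= hi && type[j] == "qmark") {
        for (k in seq_along(tags)) {
          unknown <- c(unknown, list(list(tag = tags[[k]],
                                          multiplicity = mults[k])))
        }
        i <- j + 1L
      } else if (j <= hi && type[j] == "dash") {
        if (any(mults != 1L)) {
          pf_parse_error("'^' multiplicity is only valid before '?'",
                         start[j - 1L], text)
        }
        n_term <- c(n_term, tags)
        i <- j + 1L
        in_prefix <- FALSE
      } else {
        pf_parse_error(
          "leading modification tag must be followed by '?' or '-'",
          if (j <= hi) start[j] else nchar(text) + 1L, text)
      }
    } else in_prefix <- FALSE
  }

  # sequence with attached tags, ranges and unordered segments
  open_range <- NULL  # c(start0, open_offset)
  open_seg <- NULL
  while (i <= hi) {
    t <- type[i]
    if (t == "residue") {
      letter <- tex[i]
      if (!letter %in% .pf_residue_alphabet) {
        pf_parse_error(paste0("'", letter,
                              "' is not a valid residue letter"),
                       start[i], text)
      }
      mods <- list()
      pos <- start[i]
      i <- i + 1L
      while (i <= hi && type[i] == "tag") {
        mods <- c(mods, list(pf_parse_tag(tex[i], start[i] + 1L, text)))
        i <- i + 1L
        if (i <= hi && type[i] == "mult") {
          pf_parse_error("'^' multiplicity is only valid before '?'",
                         start[i], text)
        }
      }
      nres <- nres + 1L
      residues[[nres]] <- new_pf_residue(letter, mods)
      if (!is.null(open_seg) && length(mods)) {
        pf_parse_error("residues inside '(?...)' cannot carry tags", pos,
                       text)
      }
    } else if (t == "lparen") {
      if (!is.null(open_range) || !is.null(open_seg)) {
        pf_parse_error("nested parentheses are not supported",
                       start[i], text)
      }
      if (i < hi && type[i + 1L] == "qmark") {
        open_seg <- c(nres, start[i])
        i <- i + 2L
      } else {
        open_range <- c(nres, start[i])
        i <- i + 1L
      }
    } else if (t == "rparen") {
      if (!is.null(open_seg)) {
        if (nres == open_seg[1L]) {
          pf_parse_error("empty '(?...)' segment", open_seg[2L], text)
        }
        segments <- c(segments, list(c(open_seg[1L], nres)))
        open_seg <- NULL
        i <- i + 1L
      } else if (!is.null(open_range)) {
        if (nres == open_range[1L]) {
          pf_parse_error("empty '(...)' range", open_range[2L], text)
        }
        i <- i + 1L
        if (i > hi || type[i] != "tag") {
          pf_parse_error("a range must be followed by a modification tag",
                         if (i <= hi) start[i] else nchar(text) + 1L, text)
        }
        while (i <= hi && type[i] == "tag") {
          ranges <- c(ranges,
                      list(new_pf_range(open_range[1L], nres,
                                        pf_parse_tag(tex[i],
                                                     start[i] + 1L, text))))
          i <- i + 1L
        }
        open_range <- NULL
      } else {
        pf_parse_error("unmatched ')'", start[i], text)
      }
    } else if (t == "dash") {
      if (nres == 0L) {
        pf_parse_error("'-' before any residue", start[i], text)
      }
      i <- i + 1L
      if (i > hi || type[i] != "tag") {
        pf_parse_error("'-' must be followed by a C-terminal tag",
                       if (i <= hi) start[i] else nchar(text) + 1L, text)
      }
      while (i <= hi && type[i] == "tag") {
        c_term <- c(c_term, list(pf_parse_tag(tex[i], start[i] + 1L, text)))
        i <- i + 1L
      }
      if (i <= hi) {
        pf_parse_error("unexpected input after C-terminal modification",
                       start[i], text)
      }
    } else if (t == "tag") {
      pf_parse_error("a modification tag must follow a residue, range ')'",
                     start[i], text)
    } else if (t == "global" || t == "labile") {
      pf_parse_error("global and labile tags must precede the sequence",
                     start[i], text)
    } else {
      pf_parse_error(paste0("unexpected '", tex[i], "'"), start[i], text)
    }
  }
  if (!is.null(open_range)) {
    pf_parse_error("unclosed '('", open_range[2L], text)
  }
  if (!is.null(open_seg)) {
    pf_parse_error("unclosed '(?'", open_seg[2L], text)
  }
  if (nres == 0L) {
    pf_parse_error("empty peptide sequence",
                   if (lo <= hi) start[lo] else 1L, text)
  }
  new_pf_peptidoform(residues[seq_len(nres)],
                     n_term_mods = n_term, c_term_mods = c_term,
                     labile_mods = labile,
                     unknown_position_mods = unknown,
                     fixed_rules = fixed, isotope_rules = isotopes,
                     ranges = ranges, unordered_segments = segments)
}

# ---- complex / member / set -------------------------------------------------

# A group is a cross-link group when its label starts with "XL", or its
# defining tag carries XLMOD chemistry, or the known disulfide cross-link
# accession MOD:00034.  Other group labels are localization-ambiguity
# groups.  The reserved label BRANCH marks branched peptides.
.pf_is_crosslink_tag <- function(tag) {
  if (is.null(tag$group)) return(FALSE)
  lab <- tolower(tag$group$label)
  if (lab == "branch") return(FALSE)
  if (startsWith(lab, "xl")) return(TRUE)
  for (el in tag$elements) {
    if (el$kind == "cv_accession" &&
        (el$source == "XLMOD" ||
         (el$source == "MOD" && el$accession == "00034"))) {
      return(TRUE)
    }
  }
  FALSE
}

.pf_parse_member <- function(type, tex, start, lo, hi, text) {
  charge <- NULL
  si <- which(type[lo:hi] == "slash")
  if (length(si) > 1L) {
    pf_parse_error("more than one charge separator", start[lo + si[2L] - 1L],
                   text)
  }
  if (length(si) == 1L) {
    si <- lo + si - 1L
    if (si != hi - 1L || type[hi] != "charge") {
      pf_parse_error("charge must terminate the ion", start[si], text)
    }
    charge <- as.integer(tex[hi])
    if (charge == 0L) {
      pf_parse_error("charge must be nonzero", start[hi], text)
    }
    hi <- si - 1L
  }
  if (hi < lo) pf_parse_error("empty ion", start[min(lo, length(start))],
                              text)
  cuts <- lo - 1L + which(type[lo:hi] == "dslash")
  clo <- c(lo, cuts + 1L)
  chi <- c(cuts - 1L, hi)
  chains <- vector("list", length(clo))
  for (ci in seq_along(clo)) {
    if (chi[ci] < clo[ci]) {
      pf_parse_error("empty chain",
                     start[min(max(clo[ci], 1L), length(start))], text)
    }
    chains[[ci]] <- .pf_parse_chain(type, tex, start, clo[ci], chi[ci], text)
  }

  # group bookkeeping across the whole complex
  defining <- character(0L); referenced <- character(0L)
  has_xl <- FALSE; has_branch <- FALSE
  for (chain in chains) {
    for (tag in pf_chain_tags(chain)) {
      g <- tag$group
      if (is.null(g)) next
      lab <- tolower(g$label)
      if (lab == "branch") has_branch <- TRUE
      if (.pf_is_crosslink_tag(tag)) has_xl <- TRUE
      if (g$is_defining) defining <- c(defining, lab)
      else referenced <- c(referenced, lab)
    }
  }
  dangling <- setdiff(referenced, defining)
  if (length(dangling)) {
    pf_parse_error(paste0("dangling group reference '#", dangling[1L], "'"),
                   start[lo], text)
  }
  dup <- unique(defining[duplicated(defining)])
  if (length(dup)) {
    pf_parse_error(paste0("group '#", dup[1L],
                          "' is defined more than once"),
                   start[lo], text)
  }
  link_mode <- if (has_branch) "branch"
  else if (length(chains) > 1L || has_xl) "cross_link"
  else "none"
  new_pf_ion(new_pf_complex(chains, link_mode), charge)
}

#' Parse a ProForma 2.0 string
#'
#' Parses a single-line ProForma 2.0 string into its full object model
#' (see [proforma-model]).  Parsing is case-insensitive; the original
#' string is retained on the result so that verbatim serialization can
#' reproduce the input exactly.  Malformed input raises a condition of
#' class `pf_parse_error` carrying the character `offset` and the
#' offending `fragment`.
#'
#' @param text a single ProForma string (UTF-8, no line breaks).
#' @return a `pf_set`.
#' @examples
#' pf_parse("EM[Oxidation]EVEES[Phospho]PEK")
#' pf_parse("EMEVEESPEK/2+ELVISLIVER/3")    # chimeric spectrum
#' pf_parse("<13C>ATPEILTVNSIGQLK")         # global isotope rule
#' @export
pf_parse <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(text)) pf_parse_error("empty input", 1L, text)
  tk <- .pf_tokens(text)
  type <- tk$type; tex <- tk$tex; start <- tk$start
  nt <- length(type)
  cuts <- which(type == "plus")
  mlo <- c(1L, cuts + 1L)
  mhi <- c(cuts - 1L, nt)
  members <- vector("list", length(mlo))
  for (mi in seq_along(mlo)) {
    if (mhi[mi] < mlo[mi]) {
      pf_parse_error("empty chimeric member",
                     if (length(cuts)) start[cuts[min(mi, length(cuts))]]
                     else 1L, text)
    }
    members[[mi]] <- .pf_parse_member(type, tex, start, mlo[mi], mhi[mi],
                                      text)
  }
  new_pf_set(members, source_text = text)
}
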