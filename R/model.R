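#' @title Object model for ProForma 2.0
#' @description
#' The parsed representation is a small hierarchy of plain R lists with S3
#' classes, mirroring the structure of the notation itself:
#'
#' * `pf_set` — top-level parse result; one or more ion assignments
#'   (more than one when a chimeric spectrum is encoded with `+`).
#' * `pf_ion` — one ion assignment: a proteoform complex plus an optional
#'   integer charge (`/2`).
#' * `pf_complex` — one or more peptide chains (`//`-separated) with a
#'   `link_mode` of `"none"`, `"cross_link"` or `"branch"`.
#' * `pf_peptidoform` — a single chain: residues, terminal / labile /
#'   unknown-position modifications, fixed-modification and isotope rules,
#'   ranges, and order-ambiguous segments.
#' * `pf_tag` — one bracketed modification tag: a list of pipe-separated
#'   elements plus an optional ambiguity-group reference.
#'
#' All residue intervals (ranges, unordered segments) are stored 0-based,
#' half-open; printed output uses 1-based residue numbers.
#' @name proforma-model
NULL

new_pf_set <- function(members, source_text = NULL) {
  stopifnot(length(members) >= 1L)
  structure(list(members = members, source_text = source_text),
            class = "pf_set")
}

new_pf_ion <- function(complex, charge = NULL) {
  if (!is.null(charge)) {
    stopifnot(charge == as.integer(charge), charge != 0L)
    charge <- as.integer(charge)
  }
  structure(list(complex = complex, charge = charge), class = "pf_ion")
}

new_pf_complex <- function(chains, link_mode = "none") {
  stopifnot(length(chains) >= 1L,
            link_mode %in% c("none", "cross_link", "branch"))
  if (link_mode == "none" && length(chains) != 1L) {
    stop("link_mode 'none' requires exactly one chain", call. = FALSE)
  }
  structure(list(chains = chains, link_mode = link_mode),
            class = "pf_complex")
}

new_pf_peptidoform <- function(residues,
                               n_term_mods = list(),
                               c_term_mods = list(),
                               labile_mods = list(),
                               unknown_position_mods = list(),
                               fixed_rules = list(),
                               isotope_rules = list(),
                               ranges = list(),
                               unordered_segments = list()) {
  stopifnot(length(residues) >= 1L)
  structure(list(residues = residues,
                 n_term_mods = n_term_mods,
                 c_term_mods = c_term_mods,
                 labile_mods = labile_mods,
                 unknown_position_mods = unknown_position_mods,
                 fixed_rules = fixed_rules,
                 isotope_rules = isotope_rules,
                 ranges = ranges,
                 unordered_segments = unordered_segments),
            class = "pf_peptidoform")
}

new_pf_residue <- function(letter, mods = list()) {
  list(letter = letter, mods = mods)
}

new_pf_tag <- function(elements = list(), group = NULL) {
  if (length(elements) == 0L && is.null(group)) {
    stop("a modification tag needs at least one element or a group reference",
         call. = FALSE)
  }
  structure(list(elements = elements, group = group), class = "pf_tag")
}

new_pf_group <- function(label, score = NULL, is_defining = FALSE) {
  list(label = label, score = score, is_defining = is_defining)
}

# Tag elements are tagged lists; `kind` selects the variant.
pf_el_cv_name       <- function(name) list(kind = "cv_name", name = name)
pf_el_cv_accession  <- function(source, accession)
  list(kind = "cv_accession", source = source, accession = accession)
pf_el_delta_mass    <- function(value, lexeme)
  list(kind = "delta_mass", value = value, lexeme = lexeme)
pf_el_formula       <- function(composition, lexeme)
  list(kind = "formula", composition = composition, lexeme = lexeme)
pf_el_glycan        <- function(composition, lexeme)
  list(kind = "glycan_composition", composition = composition,
       lexeme = lexeme)
pf_el_observed_mass <- function(value, lexeme)
  list(kind = "observed_mass", value = value, lexeme = lexeme)
pf_el_info          <- function(text) list(kind = "info", text = text)

new_pf_fixed_rule <- function(tag, targets) {
  stopifnot(length(targets) >= 1L)
  list(tag = tag, targets = targets)
}

new_pf_isotope_rule <- function(mass_number, element) {
  stopifnot(mass_number > 1L)
  list(mass_number = as.integer(mass_number), element = element)
}

new_pf_range <- function(start, end, tag) {
  stopifnot(start >= 0L, end > start)
  list(start = as.integer(start), end = as.integer(end), tag = tag)
}

# ---- traversal helpers ------------------------------------------------------

# Apply FUN to every pf_tag in a peptidoform (residue, terminal, labile,
# unknown-position, fixed-rule and range tags); returns a flat list.
pf_chain_tags <- function(chain) {
  out <- list()
  for (r in chain$residues) out <- c(out, r$mods)
  out <- c(out, chain$n_term_mods, chain$c_term_mods, chain$labile_mods)
  for (u in chain$unknown_position_mods) out <- c(out, list(u$tag))
  for (f in chain$fixed_rules) out <- c(out, list(f$tag))
  for (rg in chain$ranges) out <- c(out, list(rg$tag))
  out
}

pf_set_tags <- function(set) {
  out <- list()
  for (m in set$members) {
    for (chain in m$complex$chains) out <- c(out, pf_chain_tags(chain))
  }
  out
}

pf_sequence <- function(chain) {
  paste(vapply(chain$residues, `[[`, "", "letter"), collapse = "")
}

# ---- invariant checks -------------------------------------------------------

# Group-reference bookkeeping: every label used must have exactly one
# defining occurrence (a tag that carries chemistry alongside the label);
# enforced per proteoform complex.
pf_check_groups <- function(complex) {
  defining <- character()
  referenced <- character()
  for (chain in complex$chains) {
    for (tag in pf_chain_tags(chain)) {
      g <- tag$group
      if (is.null(g)) next
      lab <- tolower(g$label)
      if (g$is_defining) defining <- c(defining, lab)
      else referenced <- c(referenced, lab)
    }
  }
  dup <- unique(defining[duplicated(defining)])
  dangling <- setdiff(referenced, defining)
  list(duplicate_definitions = dup, dangling_references = dangling)
}

#' Check model invariants
#'
#' Verifies the structural invariants of a parsed model: non-empty members
#' and residues, well-formed intervals, nonzero integral charges, and group
#' labels with exactly one defining occurrence per complex.
#'
#' @param set a `pf_set`.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
pf_check <- function(set) {
  stopifnot(inherits(set, "pf_set"), length(set$members) >= 1L)
  for (m in set$members) {
    if (!is.null(m$charge) &&
        (m$charge != as.integer(m$charge) || m$charge == 0L)) {
      stop("charge must be a nonzero integer", call. = FALSE)
    }
    gr <- pf_check_groups(m$complex)
    if (length(gr$dangling_references)) {
      stop("dangling group reference: #", gr$dangling_references[1L],
           call. = FALSE)
    }
    if (length(gr$duplicate_definitions)) {
      stop("group label defined more than once: #",
           gr$duplicate_definitions[1L], call. = FALSE)
    }
    for (chain in m$complex$chains) {
      n <- length(chain$residues)
      if (n < 1L) stop("empty peptidoform", call. = FALSE)
      letters <- vapply(chain$residues, `[[`, "", "letter")
      bad <- setdiff(letters, .pf_residue_alphabet)
      if (length(bad)) {
        stop("illegal residue letter: ", bad[1L], call. = FALSE)
      }
      iv <- c(chain$ranges, lapply(chain$unordered_segments, function(s) {
        list(start = s[1L], end = s[2L])
      }))
      for (r in iv) {
        if (r$start < 0L || r$end > n || r$start >= r$end) {
          stop("interval [", r$start, ", ", r$end,
               ") out of bounds for ", n, " residues", call. = FALSE)
        }
      }
    }
  }
  invisible(TRUE)
}

# ---- semantic equivalence ---------------------------------------------------

.pf_num_key <- function(x) sprintf("%.10g", x)

.pf_el_key <- function(el) {
  switch(el$kind,
    cv_name = paste0("n:", tolower(el$name)),
    cv_accession = paste0("a:", toupper(el$source), ":",
                          toupper(el$accession)),
    delta_mass = paste0("d:", .pf_num_key(el$value)),
    formula = {
      comp <- el$composition
      parts <- sort(paste0(ifelse(is.na(comp$isotope), "",
                                  comp$isotope),
                           comp$element, ":", comp$count))
      paste0("f:", paste(parts, collapse = ","))
    },
    glycan_composition = {
      comp <- el$composition
      parts <- sort(paste0(tolower(comp$monosaccharide), ":", comp$count))
      paste0("g:", paste(parts, collapse = ","))
    },
    observed_mass = paste0("o:", .pf_num_key(el$value)),
    info = paste0("i:", el$text),
    stop("unknown element kind ", el$kind)
  )
}

.pf_tag_key <- function(tag) {
  els <- sort(vapply(tag$elements, .pf_el_key, ""))
  g <- ""
  if (!is.null(tag$group)) {
    g <- paste0("#", tolower(tag$group$label),
                if (!is.null(tag$group$score))
                  paste0("(", .pf_num_key(tag$group$score), ")") else "",
                if (tag$group$is_defining) "!" else "")
  }
  paste0("[", paste(els, collapse = "|"), g, "]")
}

.pf_tags_key <- function(tags) {
  paste(sort(vapply(tags, .pf_tag_key, "")), collapse = "")
}

.pf_chain_key <- function(chain) {
  res <- vapply(chain$residues, function(r) {
    paste0(toupper(r$letter), .pf_tags_key(r$mods))
  }, "")
  unk <- sort(vapply(chain$unknown_position_mods, function(u) {
    paste0(.pf_tag_key(u$tag), "^", u$multiplicity)
  }, character(1L)))
  fx <- sort(vapply(chain$fixed_rules, function(f) {
    paste0(.pf_tag_key(f$tag), "@",
           paste(sort(toupper(f$targets)), collapse = ","))
  }, character(1L)))
  iso <- sort(vapply(chain$isotope_rules, function(i) {
    paste0(i$mass_number, toupper(i$element))
  }, character(1L)))
  rng <- sort(vapply(chain$ranges, function(r) {
    paste0(r$start, "-", r$end, .pf_tag_key(r$tag))
  }, character(1L)))
  seg <- sort(vapply(chain$unordered_segments, function(s) {
    paste0(s[1L], "-", s[2L])
  }, character(1L)))
  paste0("N{", .pf_tags_key(chain$n_term_mods), "}",
         "C{", .pf_tags_key(chain$c_term_mods), "}",
         "L{", .pf_tags_key(chain$labile_mods), "}",
         "U{", paste(unk, collapse = ";"), "}",
         "F{", paste(fx, collapse = ";"), "}",
         "I{", paste(iso, collapse = ";"), "}",
         "R{", paste(rng, collapse = ";"), "}",
         "S{", paste(seg, collapse = ";"), "}",
         paste(res, collapse = ""))
}

.pf_member_key <- function(m) {
  ch <- vapply(m$complex$chains, .pf_chain_key, "")
  paste0("z=", if (is.null(m$charge)) "." else m$charge,
         ";", m$complex$link_mode, ";",
         paste(ch, collapse = "//"))
}

#' Semantic equivalence of two parsed models
#'
#' Two models are equivalent when they denote the same proteoform set,
#' ignoring the case of names and group labels, the textual formatting of
#' numbers (parsed decimal values are compared), the order of pipe-separated
#' elements inside one tag, and the order of chimeric members.
#'
#' @param a,b `pf_set` objects.
#' @return logical scalar.
#' @examples
#' pf_equivalent(pf_parse("EM[Oxidation]K"), pf_parse("em[oxidation]k"))
#' @export
pf_equivalent <- function(a, b) {
  stopifnot(inherits(a, "pf_set"), inherits(b, "pf_set"))
  ka <- sort(vapply(a$members, .pf_member_key, ""))
  kb <- sort(vapply(b$members, .pf_member_key, ""))
  identical(ka, kb)
}

#' @export
print.pf_set <- function(x, ...) {
  n <- length(x$members)
  cat("<ProForma set: ", n, if (n > 1L) " ion assignments (chimeric)>"
      else " ion assignment>", "\n", sep = "")
  for (i in seq_len(n)) {
    m <- x$members[[i]]
    seqs <- vapply(m$complex$chains, pf_sequence, "")
    cat("  [", i, "] ", paste(seqs, collapse = " // "),
        if (!is.null(m$charge)) paste0("  charge ", m$charge) else "",
        if (m$complex$link_mode != "none")
          paste0("  (", m$complex$link_mode, ")") else "",
        "\n", sep = "")
  }
  cat("  text: ", pf_serialize(x), "\n", sep = "")
  invisible(x)
}
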