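# Theoretical neutral monoisotopic masses.
#
# The mass of a peptidoform is the sum of its residue masses (computed
# from elemental compositions), one water for the termini, and one delta
# per modification tag.  A tag's delta is taken from the first of its
# pipe-separated elements that yields a number: an explicit delta mass, a
# chemical formula, a glycan composition, or a CV term with a known
# monoisotopic mass.  Observed-mass and INFO elements never contribute;
# bare group references carry no chemistry (the defining tag of a
# cross-link counts exactly once per complex).  Global isotope rules
# (<13C>) substitute the specified isotope's mass for every atom of that
# element in the residue/water accounting.  Tags that cannot be resolved
# to a number are reported in `unresolved` — never silently zero.

#' Monoisotopic mass of an elemental formula
#'
#' @param f a `Formula:` composition as parsed by [pf_parse_tag()] (a data
#'   frame with columns `element`, `isotope`, `count`), or a formula
#'   string such as `"C12H20O2"` or `"[13C2]C-2H2N"`.
#' @return the monoisotopic mass in daltons; isotope-annotated atoms use
#'   that isotope's mass, negative counts subtract.
#' @examples
#' pf_formula_mass("C12H20O2")
#' pf_formula_mass("H2O") - pf_formula_mass("H2O")
#' @export
pf_formula_mass <- function(f) {
  if (is.character(f)) {
    f <- .pf_parse_formula(f, 1L, f)
  }
  if (nrow(f) == 0L) return(0)
  m <- numeric(nrow(f))
  for (i in seq_len(nrow(f))) {
    if (is.na(f$isotope[i])) {
      am <- .pf_atomic_mass[f$element[i]]
      if (is.na(am)) {
        stop("unknown element symbol '", f$element[i], "'", call. = FALSE)
      }
    } else {
      key <- paste0(f$isotope[i], f$element[i])
      am <- .pf_isotope_mass[key]
      if (is.na(am)) {
        stop("no mass table entry for isotope ", key, call. = FALSE)
      }
    }
    m[i] <- am * f$count[i]
  }
  sum(m)
}

#' Monoisotopic mass of a glycan composition
#'
#' Sums count times the residue (dehydro) monosaccharide mass; masses are
#' derived from the bundled monosaccharide elemental compositions.
#'
#' @param g a `Glycan:` composition as parsed by [pf_parse_tag()] (a data
#'   frame with columns `monosaccharide`, `count`), or a composition
#'   string such as `"HexNAc1Hex2"`.
#' @return the monoisotopic mass in daltons.
#' @examples
#' pf_glycan_mass("HexNAc1Hex2")
#' @export
pf_glycan_mass <- function(g) {
  if (is.character(g)) {
    g <- .pf_parse_glycan(g, 1L, g)
  }
  if (nrow(g) == 0L) return(0)
  m <- vapply(seq_len(nrow(g)), function(i) {
    comp <- .pf_glycan_comp[[g$monosaccharide[i]]]
    if (is.null(comp)) {
      stop("unknown monosaccharide '", g$monosaccharide[i], "'",
           call. = FALSE)
    }
    .pf_comp_mass(comp) * g$count[i]
  }, 0)
  sum(m)
}

# Delta contributed by one tag: list(delta=, label=, unresolved=lgl).
# The first resolvable chemistry element wins; a tag with chemistry that
# cannot be resolved is unresolved; a tag with no chemistry (bare group
# reference, info only) contributes zero.
.pf_tag_delta <- function(tag, resolver) {
  label <- .pf_render_tag(tag, canonical = FALSE, resolver = NULL)
  chem <- FALSE
  for (el in tag$elements) {
    d <- switch(el$kind,
      delta_mass = el$value,
      formula = pf_formula_mass(el$composition),
      glycan_composition = pf_glycan_mass(el$composition),
      cv_name = ,
      cv_accession = {
        rec <- pf_resolve_element(resolver, el)
        if (is.null(rec)) NULL else rec$delta_monoisotopic_da
      },
      NULL)
    if (el$kind %in% c("delta_mass", "formula", "glycan_composition",
                       "cv_name", "cv_accession")) {
      chem <- TRUE
    }
    if (!is.null(d)) {
      return(list(delta = d, label = label, unresolved = FALSE))
    }
  }
  if (chem) {
    list(delta = NA_real_, label = label, unresolved = TRUE)
  } else {
    list(delta = 0, label = label, unresolved = FALSE)
  }
}

.pf_chain_mass <- function(chain, resolver, include_labile) {
  isotopes <- NULL
  if (length(chain$isotope_rules)) {
    isotopes <- vapply(chain$isotope_rules, `[[`, 0L, "mass_number")
    names(isotopes) <- vapply(chain$isotope_rules, `[[`, "", "element")
  }
  unresolved <- character(0L)
  letters <- vapply(chain$residues, `[[`, "", "letter")
  residue_sum <- 0
  for (le in letters) {
    comp <- .pf_residue_comp[[le]]
    if (is.null(comp)) {
      if (le != "X") {  # X is a mass gap: its tag carries the mass
        unresolved <- c(unresolved,
                        paste0("residue '", le,
                               "' has no defined monoisotopic mass"))
      }
    } else {
      residue_sum <- residue_sum + .pf_comp_mass(comp, isotopes)
    }
  }
  water <- .pf_comp_mass(.pf_water_comp, isotopes)

  deltas <- numeric(0L)
  add_tag <- function(tag, times = 1L, where = "") {
    td <- .pf_tag_delta(tag, resolver)
    if (td$unresolved) {
      unresolved <<- c(unresolved,
                       paste0(td$label,
                              if (nzchar(where)) paste0(" ", where) else ""))
    } else if (td$delta != 0) {
      d <- td$delta * times
      names(d) <- td$label
      deltas <<- c(deltas, d)
    }
  }
  for (r in chain$residues) for (tag in r$mods) add_tag(tag)
  for (tag in chain$n_term_mods) add_tag(tag, where = "(N-term)")
  for (tag in chain$c_term_mods) add_tag(tag, where = "(C-term)")
  if (include_labile) {
    for (tag in chain$labile_mods) add_tag(tag, where = "(labile)")
  }
  for (u in chain$unknown_position_mods) {
    add_tag(u$tag, times = u$multiplicity, where = "(unlocalized)")
  }
  for (rg in chain$ranges) add_tag(rg$tag, where = "(range)")
  for (fx in chain$fixed_rules) {
    nmatch <- sum(letters %in% fx$targets)
    if (nmatch > 0L) add_tag(fx$tag, times = nmatch, where = "(fixed)")
  }
  list(residue_sum = residue_sum, water = water, deltas = deltas,
       unresolved = unresolved)
}

#' Theoretical neutral monoisotopic mass
#'
#' Computes the neutral monoisotopic mass of a peptidoform, a proteoform
#' complex (sum over its cross-linked or branched chains, with the linker
#' chemistry counted once at its defining tag), or a single-member parse
#' result.  Modifications that cannot be resolved to a numeric mass are
#' reported in `unresolved`; the total mass is only reported when that
#' list is empty.
#'
#' @param x a ProForma string, or a `pf_set` with one ion assignment, a
#'   `pf_ion`, `pf_complex` or `pf_peptidoform`.  For a chimeric set,
#'   compute each member separately (`pf_mass(set$members[[i]])`).
#' @param resolver a `pf_resolver` for CV name/accession lookup;
#'   `NULL` leaves every CV tag unresolved.
#' @param include_labile logical; include labile modifications (lost on
#'   fragmentation but part of the intact molecule) in the neutral mass.
#' @return a `pf_mass_result`: `mass` (Da, `NA` when anything is
#'   unresolved), `unresolved` (character), and `breakdown` with
#'   `residue_sum`, `water` and named per-tag `deltas`.
#' @examples
#' pf_mass("EM[+15.9949]EVEES[+79.9663]PEK")
#' pf_mass("PEPTIDE")$mass
#' @export
pf_mass <- function(x, resolver = pf_default_resolver(),
                    include_labile = TRUE) {
  if (is.character(x)) x <- pf_parse(x)
  if (inherits(x, "pf_set")) {
    if (length(x$members) > 1L) {
      stop("chimeric set: compute each member separately, e.g. ",
           "pf_mass(set$members[[1]])", call. = FALSE)
    }
    x <- x$members[[1L]]
  }
  if (inherits(x, "pf_ion")) x <- x$complex
  chains <- if (inherits(x, "pf_complex")) x$chains else list(x)
  stopifnot(all(vapply(chains, inherits, TRUE, "pf_peptidoform")))
  residue_sum <- 0; water <- 0
  deltas <- numeric(0L); unresolved <- character(0L)
  for (chain in chains) {
    cm <- .pf_chain_mass(chain, resolver, include_labile)
    residue_sum <- residue_sum + cm$residue_sum
    water <- water + cm$water
    deltas <- c(deltas, cm$deltas)
    unresolved <- c(unresolved, cm$unresolved)
  }
  mass <- if (length(unresolved)) NA_real_
          else residue_sum + water + sum(deltas)
  structure(list(mass = mass, unresolved = unresolved,
                 breakdown = list(residue_sum = residue_sum,
                                  water = water, deltas = deltas)),
            class = "pf_mass_result")
}

#' Mass-to-charge ratio of an ion assignment
#'
#' Convenience around [pf_mass()]: adds (or, for negative charges,
#' removes) `charge` protons and divides by the absolute charge.
#'
#' @param x a ProForma string or `pf_ion`/single-member `pf_set` carrying
#'   a charge, or a `pf_mass_result`.
#' @param charge the ion charge; taken from the model when omitted.
#' @param ... passed to [pf_mass()].
#' @return m/z in thomson, or `NA` if the mass is unresolved.
#' @examples
#' pf_mz("EMEVEESPEK/2")
#' @export
pf_mz <- function(x, charge = NULL, ...) {
  if (is.character(x)) x <- pf_parse(x)
  if (inherits(x, "pf_set") && length(x$members) == 1L) {
    x <- x$members[[1L]]
  }
  if (is.null(charge) && inherits(x, "pf_ion")) charge <- x$charge
  if (is.null(charge)) {
    stop("no charge on the model and none supplied", call. = FALSE)
  }
  m <- if (inherits(x, "pf_mass_result")) x else pf_mass(x, ...)
  (m$mass + charge * .pf_proton_mass) / abs(charge)
}

#' @export
print.pf_mass_result <- function(x, ...) {
  if (is.na(x$mass)) {
    cat("<mass: unresolved>\n")
  } else {
    cat(sprintf("<neutral monoisotopic mass: %.6f Da>\n", x$mass))
  }
  b <- x$breakdown
  cat(sprintf("  residues %.6f + water %.6f\n", b$residue_sum, b$water))
  if (length(b$deltas)) {
    for (i in seq_along(b$deltas)) {
      cat(sprintf("  %+12.6f  %s\n", b$deltas[i], names(b$deltas)[i]))
    }
  }
  for (u in x$unresolved) cat("  unresolved: ", u, "\n", sep = "")
  invisible(x)
}
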