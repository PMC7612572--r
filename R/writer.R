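# Serialization back to ProForma text.
#
# Two modes: verbatim (default) reproduces the original input exactly when
# the model came from pf_parse(); canonical normalizes case and layout:
# uppercase residues, resolver-preferred capitalization for CV names,
# lowercase group labels (except the reserved BRANCH), and a fixed element
# order inside each tag (chemistry first, then Obs:, then INFO:, group
# reference appended to the first chemistry element).  Numeric lexemes are
# reproduced as written: the number of decimal places an author chose is
# treated as intent, never re-rounded.

.pf_render_element <- function(el, canonical, resolver) {
  switch(el$kind,
    cv_name = {
      name <- el$name
      if (canonical && !is.null(resolver)) {
        rec <- pf_resolve(resolver, name = name)
        if (!is.null(rec)) name <- rec$name
      }
      name
    },
    cv_accession = paste0(el$source, ":", el$accession),
    delta_mass = el$lexeme,
    formula = paste0("Formula:", el$lexeme),
    glycan_composition = paste0("Glycan:", el$lexeme),
    observed_mass = paste0("Obs:", el$lexeme),
    info = paste0("INFO:", el$text),
    stop("unknown element kind ", el$kind)
  )
}

.pf_render_group <- function(group, canonical) {
  label <- group$label
  if (canonical) {
    label <- if (toupper(label) == "BRANCH") "BRANCH" else tolower(label)
  }
  score <- ""
  if (!is.null(group$score)) {
    lex <- group$score_lexeme
    if (is.null(lex)) lex <- sprintf("%.10g", group$score)
    score <- paste0("(", lex, ")")
  }
  paste0("#", label, score)
}

.pf_render_tag <- function(tag, canonical, resolver) {
  els <- tag$elements
  if (canonical && length(els) > 1L) {
    rank <- vapply(els, function(el) {
      switch(el$kind, observed_mass = 2L, info = 3L, 1L)
    }, 0L)
    els <- els[order(rank)]
  }
  out <- vapply(els, .pf_render_element, "", canonical = canonical,
                resolver = resolver)
  g <- if (is.null(tag$group)) NULL else .pf_render_group(tag$group,
                                                          canonical)
  if (!is.null(g)) {
    if (length(out) == 0L) out <- g
    else out[1L] <- paste0(out[1L], g)
  }
  paste0("[", paste(out, collapse = "|"), "]")
}

.pf_render_tags <- function(tags, canonical, resolver) {
  paste(vapply(tags, .pf_render_tag, "", canonical = canonical,
               resolver = resolver), collapse = "")
}

.pf_render_chain <- function(chain, canonical, resolver) {
  parts <- character(0L)
  for (iso in chain$isotope_rules) {
    parts <- c(parts, paste0("<", iso$mass_number, iso$element, ">"))
  }
  for (fx in chain$fixed_rules) {
    parts <- c(parts, paste0("<",
                             .pf_render_tag(fx$tag, canonical, resolver),
                             "@", paste(fx$targets, collapse = ","), ">"))
  }
  for (lb in chain$labile_mods) {
    tag <- .pf_render_tag(lb, canonical, resolver)
    parts <- c(parts, paste0("{", substr(tag, 2L, nchar(tag) - 1L), "}"))
  }
  for (u in chain$unknown_position_mods) {
    parts <- c(parts, paste0(.pf_render_tag(u$tag, canonical, resolver),
                             if (u$multiplicity > 1L)
                               paste0("^", u$multiplicity) else "",
                             "?"))
  }
  if (length(chain$n_term_mods)) {
    parts <- c(parts, paste0(.pf_render_tags(chain$n_term_mods, canonical,
                                             resolver), "-"))
  }
  n <- length(chain$residues)
  range_start <- integer(0L); range_end <- integer(0L)
  if (length(chain$ranges)) {
    range_start <- vapply(chain$ranges, `[[`, 0L, "start")
    range_end <- vapply(chain$ranges, `[[`, 0L, "end")
  }
  seg_start <- vapply(chain$unordered_segments, `[`, 0L, 1L)
  seg_end <- vapply(chain$unordered_segments, `[`, 0L, 2L)
  body <- character(0L)
  for (i0 in seq_len(n) - 1L) {
    if (i0 %in% seg_start) body <- c(body, "(?")
    if (i0 %in% range_start) body <- c(body, "(")
    r <- chain$residues[[i0 + 1L]]
    body <- c(body, toupper(r$letter),
              .pf_render_tags(r$mods, canonical, resolver))
    if ((i0 + 1L) %in% seg_end) body <- c(body, ")")
    if ((i0 + 1L) %in% range_end) {
      body <- c(body, ")")
      for (ri in which(range_end == i0 + 1L)) {
        body <- c(body, .pf_render_tag(chain$ranges[[ri]]$tag, canonical,
                                       resolver))
      }
    }
  }
  parts <- c(parts, body)
  if (length(chain$c_term_mods)) {
    parts <- c(parts, "-", .pf_render_tags(chain$c_term_mods, canonical,
                                           resolver))
  }
  paste(parts, collapse = "")
}

#' Serialize a model back to ProForma text
#'
#' @param set a `pf_set` (or a `pf_ion`, `pf_complex` or `pf_peptidoform`).
#' @param canonical logical; if `FALSE` (default) and the model was
#'   produced by [pf_parse()], the original input string is returned
#'   character-for-character.  If `TRUE`, a normalized rendering is
#'   produced (see Details in the package vignette); re-serializing a
#'   canonical form is idempotent.
#' @param resolver optional `pf_resolver` used in canonical mode to render
#'   CV names with their CV-preferred capitalization.
#' @return a single character string that re-parses to an equivalent model.
#' @examples
#' pf_serialize(pf_parse("em[oxidation]k"), canonical = TRUE,
#'              resolver = pf_default_resolver())
#' @export
pf_serialize <- function(set, canonical = FALSE, resolver = NULL) {
  if (inherits(set, "pf_peptidoform")) {
    return(.pf_render_chain(set, canonical, resolver))
  }
  if (inherits(set, "pf_complex")) {
    return(paste(vapply(set$chains, .pf_render_chain, "",
                        canonical = canonical, resolver = resolver),
                 collapse = "//"))
  }
  if (inherits(set, "pf_ion")) {
    set <- new_pf_set(list(set))
  }
  stopifnot(inherits(set, "pf_set"))
  if (!canonical && !is.null(set$source_text)) {
    return(set$source_text)
  }
  out <- vapply(set$members, function(m) {
    s <- paste(vapply(m$complex$chains, .pf_render_chain, "",
                      canonical = canonical, resolver = resolver),
               collapse = "//")
    if (!is.null(m$charge)) s <- paste0(s, "/", m$charge)
    s
  }, "")
  paste(out, collapse = "+")
}

# ---- JSON rendering ---------------------------------------------------------

.pf_model_list <- function(x) {
  if (inherits(x, "pf_set")) {
    list(members = lapply(x$members, .pf_model_list))
  } else if (inherits(x, "pf_ion")) {
    list(charge = x$charge, complex = .pf_model_list(x$complex))
  } else if (inherits(x, "pf_complex")) {
    list(link_mode = x$link_mode,
         chains = lapply(x$chains, .pf_model_list))
  } else if (inherits(x, "pf_peptidoform")) {
    list(sequence = pf_sequence(x),
         residues = lapply(seq_along(x$residues), function(i) {
           r <- x$residues[[i]]
           if (length(r$mods) == 0L) return(NULL)
           list(position = i, letter = r$letter,
                tags = lapply(r$mods, .pf_model_list))
         }),
         n_term_mods = lapply(x$n_term_mods, .pf_model_list),
         c_term_mods = lapply(x$c_term_mods, .pf_model_list),
         labile_mods = lapply(x$labile_mods, .pf_model_list),
         unknown_position_mods = lapply(x$unknown_position_mods,
           function(u) list(multiplicity = u$multiplicity,
                            tag = .pf_model_list(u$tag))),
         fixed_rules = lapply(x$fixed_rules,
           function(f) list(targets = as.list(f$targets),
                            tag = .pf_model_list(f$tag))),
         isotope_rules = lapply(x$isotope_rules,
           function(i) list(mass_number = i$mass_number,
                            element = i$element)),
         ranges = lapply(x$ranges,
           function(r) list(start = r$start, end = r$end,
                            tag = .pf_model_list(r$tag))),
         unordered_segments = lapply(x$unordered_segments,
           function(s) list(start = s[1L], end = s[2L])))
  } else if (inherits(x, "pf_tag")) {
    out <- list(elements = lapply(x$elements, function(el) {
      el2 <- el
      if (!is.null(el2$composition)) {
        el2$composition <- as.list(el2$composition)
      }
      el2
    }))
    if (!is.null(x$group)) {
      out$group <- list(label = x$group$label, score = x$group$score,
                        is_defining = x$group$is_defining)
    }
    out
  } else x
}

#' Render a parsed model as JSON
#'
#' Produces a stable JSON rendering of the full object model, suitable for
#' downstream tools; field names match the model documented in
#' [proforma-model].
#'
#' @param set a `pf_set`.
#' @param pretty logical; pretty-print the JSON.
#' @return a JSON string (class `json`).
#' @export
pf_to_json <- function(set, pretty = FALSE) {
  stopifnot(inherits(set, "pf_set"))
  lst <- .pf_model_list(set)
  lst$text <- pf_serialize(set)
  jsonlite::toJSON(lst, auto_unbox = TRUE, null = "null", digits = NA,
                   pretty = pretty)
}
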