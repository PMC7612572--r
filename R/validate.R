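# Feature detection and compliance-level validation.
#
# Every notation feature a string can use maps to one flag; the five
# published compliance configurations each grant a set of flags.  The
# grant mapping below is this package's declared reading of the base /
# level-2 split (the level names and count are fixed; which feature sits
# at which level is configurable via the `grants` argument of
# pf_validate()).

.pf_feature_flags <- c(
  "cv_name", "cv_accession", "resid_accession", "xlmod_accession",
  "cross_link_intra", "cross_link_inter", "disulfide", "branch", "gno",
  "delta_mass", "gap", "formula", "glycan_composition", "terminal_mods",
  "labile", "unknown_position", "position_set", "range",
  "localization_scores", "range_scores", "isotope", "fixed_mod",
  "sequence_ambiguity", "info_tag", "observed_mass", "charge", "chimeric"
)

.pf_base_grants <- c("cv_name", "cv_accession", "delta_mass",
                     "terminal_mods", "info_tag")
.pf_level2_grants <- c(.pf_base_grants, "formula", "glycan_composition",
                       "gap", "labile", "unknown_position", "position_set",
                       "range", "localization_scores", "range_scores",
                       "isotope", "fixed_mod", "sequence_ambiguity",
                       "observed_mass", "charge", "chimeric")
.pf_ext_grants <- list(
  topdown = "resid_accession",
  crosslink = c("xlmod_accession", "cross_link_intra", "cross_link_inter",
                "disulfide", "branch"),
  glycan = "gno"
)

#' The five ProForma 2.0 compliance configurations
#'
#' Returns the five published compliance configurations: base, level 2,
#' and level 2 combined with each of the top-down, cross-linking and
#' glycan extensions.  Extensions are combinable: build ad-hoc
#' configurations with `pf_level("level2", c("crosslink", "glycan"))`.
#'
#' @return a named list of five `pf_level` objects.
#' @export
pf_compliance_levels <- function() {
  list(base = pf_level("base"),
       level2 = pf_level("level2"),
       level2_topdown = pf_level("level2", "topdown"),
       level2_crosslink = pf_level("level2", "crosslink"),
       level2_glycan = pf_level("level2", "glycan"))
}

#' Construct a compliance level
#'
#' @param base `"base"` or `"level2"`; extensions require `"level2"`.
#' @param extensions any of `"topdown"`, `"crosslink"`, `"glycan"`.
#' @return a `pf_level`.
#' @export
pf_level <- function(base = c("base", "level2"), extensions = character()) {
  base <- match.arg(base)
  extensions <- unique(extensions)
  stopifnot(all(extensions %in% names(.pf_ext_grants)))
  if (base == "base" && length(extensions)) {
    stop("extensions imply level 2 compliance", call. = FALSE)
  }
  structure(list(base = base, extensions = extensions), class = "pf_level")
}

.pf_as_level <- function(level) {
  if (inherits(level, "pf_level")) return(level)
  stopifnot(is.character(level), length(level) == 1L)
  cfg <- pf_compliance_levels()[[level]]
  if (is.null(cfg)) {
    stop("unknown compliance level '", level, "'; one of: ",
         paste(names(pf_compliance_levels()), collapse = ", "),
         call. = FALSE)
  }
  cfg
}

.pf_level_grants <- function(level, grants = NULL) {
  g <- if (level$base == "base") .pf_base_grants else .pf_level2_grants
  for (e in level$extensions) g <- c(g, .pf_ext_grants[[e]])
  unique(c(g, grants))
}

#' @export
format.pf_level <- function(x, ...) {
  if (length(x$extensions) == 0L) x$base
  else paste0(x$base, "+", paste(x$extensions, collapse = "+"))
}

#' @export
print.pf_level <- function(x, ...) {
  cat("<compliance level: ", format(x), ">\n", sep = "")
  invisible(x)
}

# ---- feature profile --------------------------------------------------------

#' Detect which notation features a parsed model uses
#'
#' @param set a `pf_set`.
#' @return a character vector of feature flags (a subset of the flags
#'   listed in `proforma:::.pf_feature_flags`), empty for a plain
#'   unmodified sequence.
#' @examples
#' pf_profile(pf_parse("EMEVEESPEK/2"))
#' pf_profile(pf_parse("PEPTIDE"))
#' @export
pf_profile <- function(set) {
  stopifnot(inherits(set, "pf_set"))
  flags <- character(0L)
  add <- function(f) flags <<- c(flags, f)
  if (length(set$members) > 1L) add("chimeric")
  for (m in set$members) {
    if (!is.null(m$charge)) add("charge")
    cx <- m$complex
    if (cx$link_mode == "branch") add("branch")
    if (cx$link_mode == "cross_link") {
      add(if (length(cx$chains) > 1L) "cross_link_inter"
          else "cross_link_intra")
    }
    for (chain in cx$chains) {
      if (length(chain$n_term_mods) || length(chain$c_term_mods)) {
        add("terminal_mods")
      }
      if (length(chain$labile_mods)) add("labile")
      if (length(chain$unknown_position_mods)) add("unknown_position")
      if (length(chain$isotope_rules)) add("isotope")
      if (length(chain$fixed_rules)) add("fixed_mod")
      if (length(chain$ranges)) add("range")
      if (length(chain$unordered_segments)) add("sequence_ambiguity")

      range_groups <- character(0L)
      for (rg in chain$ranges) {
        if (!is.null(rg$tag$group)) {
          range_groups <- c(range_groups, tolower(rg$tag$group$label))
        }
      }
      for (r in chain$residues) {
        if (r$letter != "X") next
        for (tag in r$mods) {
          numeric_tag <- any(vapply(tag$elements, function(el) {
            el$kind %in% c("delta_mass", "formula")
          }, TRUE))
          if (numeric_tag) add("gap")
        }
      }
      gr_scored <- FALSE; gr_bare_plain <- FALSE
      for (tag in pf_chain_tags(chain)) {
        for (el in tag$elements) {
          switch(el$kind,
            cv_name = add("cv_name"),
            cv_accession = {
              if (el$source %in% c("MOD", "UNIMOD")) add("cv_accession")
              if (el$source == "RESID") add("resid_accession")
              if (el$source == "XLMOD") add("xlmod_accession")
              if (el$source == "GNO") add("gno")
              if (el$source == "MOD" && el$accession == "00034") {
                add("disulfide")
              }
            },
            delta_mass = add("delta_mass"),
            formula = add("formula"),
            glycan_composition = add("glycan_composition"),
            info = add("info_tag"),
            observed_mass = add("observed_mass"),
            NULL)
        }
        g <- tag$group
        if (!is.null(g) && !.pf_is_crosslink_tag(tag) &&
            tolower(g$label) != "branch") {
          lab <- tolower(g$label)
          if (!is.null(g$score)) {
            add(if (lab %in% range_groups) "range_scores"
                else "localization_scores")
          } else if (!g$is_defining) {
            gr_bare_plain <- TRUE
          }
        }
      }
      if (gr_bare_plain) add("position_set")
    }
  }
  sort(unique(flags))
}

#' Minimal compliance level covering a feature profile
#'
#' @param profile a feature-flag vector from [pf_profile()].
#' @return a `pf_level`: `base` when the profile fits the base grants,
#'   otherwise level 2 plus whichever extensions the profile requires.
#' @examples
#' pf_required_level(pf_profile(pf_parse("PEPTIDE")))
#' @export
pf_required_level <- function(profile) {
  if (all(profile %in% .pf_base_grants)) return(pf_level("base"))
  ext <- names(.pf_ext_grants)[vapply(.pf_ext_grants, function(g) {
    any(profile %in% g)
  }, TRUE)]
  pf_level("level2", ext)
}

# ---- validation -------------------------------------------------------------

.pf_violation <- function(feature, message, span = NA_character_,
                          required = NA_character_, severity = "error") {
  data.frame(feature = feature, message = message, span = span,
             required_level = required, severity = severity,
             stringsAsFactors = FALSE)
}

#' Validate a model against a compliance level
#'
#' Checks that every notation feature the model uses is granted by the
#' compliance level, and enforces the level-independent semantic rules:
#' group references must resolve to exactly one defining tag, localization
#' scores must lie in [0, 1], the scores of one ambiguity group should sum
#' to 1 (a deviation beyond 0.01 is reported as a warning), and charges
#' must be nonzero integers.
#'
#' @param set a `pf_set`.
#' @param level a `pf_level`, or the name of one of the five published
#'   configurations (see [pf_compliance_levels()]).
#' @param grants optional extra feature flags to grant on top of the
#'   level's own (the feature-to-level mapping is a package decision and
#'   deliberately overridable).
#' @return a `pf_violations` data frame with columns `feature`,
#'   `message`, `span`, `required_level` and `severity`; zero rows when
#'   the model is fully valid at the level.
#' @examples
#' pf_validate(pf_parse("PEPTIDE"), "base")
#' pf_validate(pf_parse("SEK[XLMOD:02001#XL1]UENCE//EMEVTK[#XL1]SESPEK"),
#'             "base")
#' @export
pf_validate <- function(set, level = "level2", grants = NULL) {
  stopifnot(inherits(set, "pf_set"))
  level <- .pf_as_level(level)
  granted <- .pf_level_grants(level, grants)
  out <- list()
  used <- pf_profile(set)
  for (f in setdiff(used, granted)) {
    req <- pf_required_level(f)
    out <- c(out, list(.pf_violation(
      f,
      paste0("feature '", f, "' is not granted at level ", format(level),
             "; requires ", format(req)),
      required = format(req))))
  }
  # semantic rules, independent of level
  for (m in set$members) {
    gr <- pf_check_groups(m$complex)
    for (lab in gr$dangling_references) {
      out <- c(out, list(.pf_violation(
        "group_reference",
        paste0("group '#", lab, "' is referenced but never defined"),
        span = paste0("#", lab))))
    }
    for (lab in gr$duplicate_definitions) {
      out <- c(out, list(.pf_violation(
        "group_reference",
        paste0("group '#", lab, "' is defined more than once"),
        span = paste0("#", lab))))
    }
    score_sum <- list()
    for (chain in m$complex$chains) {
      for (tag in pf_chain_tags(chain)) {
        g <- tag$group
        if (is.null(g)) next
        if (!is.null(g$score)) {
          if (g$score < 0 || g$score > 1) {
            out <- c(out, list(.pf_violation(
              "localization_scores",
              paste0("score ", g$score, " outside [0, 1]"),
              span = .pf_render_tag(tag, FALSE, NULL))))
          }
          lab <- tolower(g$label)
          score_sum[[lab]] <- (score_sum[[lab]] %||% 0) + g$score
        }
      }
    }
    for (lab in names(score_sum)) {
      if (abs(score_sum[[lab]] - 1) > 0.01) {
        out <- c(out, list(.pf_violation(
          "localization_scores",
          sprintf("scores of group '#%s' sum to %.4g, expected 1",
                  lab, score_sum[[lab]]),
          span = paste0("#", lab), severity = "warning")))
      }
    }
  }
  v <- if (length(out)) do.call(rbind, out)
       else .pf_violation(character(0L), character(0L), character(0L),
                          character(0L), character(0L))
  class(v) <- c("pf_violations", "data.frame")
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pf_violations <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("No violations.\n")
  } else {
    for (i in seq_len(nrow(x))) {
      cat(toupper(x$severity[i]), ": ", x$message[i],
          if (!is.na(x$span[i])) paste0(" [", x$span[i], "]") else "",
          "\n", sep = "")
    }
  }
  invisible(x)
}
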