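# Offline controlled-vocabulary resolver.
#
# ProForma tags name modifications either by CV name ("Phospho") or by
# accession ("MOD:00046").  The resolver maps both to a CvRecord carrying
# the term's preferred name and monoisotopic delta mass.  Everything is
# offline: the bundled table covers the terms used in the package examples
# and tests; users point pf_resolver() at richer tables (same TSV layout)
# to widen coverage.  Bare names are searched across CVs in a fixed
# precedence order: Unimod, PSI-MOD, RESID, XL-MOD, GNO — so an
# unqualified "Phospho" resolves to the Unimod term.

.pf_name_precedence <- c("UNIMOD", "MOD", "RESID", "XLMOD", "GNO")

#' Load a controlled-vocabulary table
#'
#' Reads a tab-separated table with columns `source`, `accession`, `name`
#' and `delta_monoisotopic_da` (empty when the term has no single
#' monoisotopic mass, e.g. some glycan ontology entries) into a resolver
#' object.  Lines starting with `#` are comments.
#'
#' @param path path to the TSV file.
#' @return a `pf_resolver`.
#' @export
pf_resolver <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "character", "character"))
  need <- c("source", "accession", "name", "delta_monoisotopic_da")
  if (!identical(names(df), need)) {
    stop("CV table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$source <- toupper(df$source)
  bad <- !df$source %in% .pf_name_precedence
  if (any(bad)) {
    stop("unknown CV source '", df$source[bad][1L], "' in ", path,
         call. = FALSE)
  }
  df$delta <- suppressWarnings(as.numeric(df$delta_monoisotopic_da))
  malformed <- nzchar(df$delta_monoisotopic_da) & is.na(df$delta)
  if (any(malformed)) {
    stop("malformed delta mass '",
         df$delta_monoisotopic_da[malformed][1L], "' in ", path,
         call. = FALSE)
  }
  key <- paste0(df$source, ":", toupper(df$accession))
  if (anyDuplicated(key)) {
    stop("duplicate CV record ", key[duplicated(key)][1L], " in ", path,
         call. = FALSE)
  }
  structure(list(table = df, by_accession = key,
                 by_name = tolower(df$name)),
            class = "pf_resolver")
}

.pf_record <- function(df, i) {
  list(source = df$source[i], accession = df$accession[i],
       name = df$name[i],
       delta_monoisotopic_da = if (is.na(df$delta[i])) NULL
                               else df$delta[i])
}

#' Resolve a CV name or accession
#'
#' Name lookup is case-insensitive and searches the CVs in the fixed
#' precedence order Unimod, PSI-MOD, RESID, XL-MOD, GNO; accession lookup
#' is exact within its source.  Absence is a value, not an error.
#'
#' @param resolver a `pf_resolver`.
#' @param name a CV term name (e.g. `"Phospho"`); or
#' @param source,accession a CV accession pair (e.g. `"MOD"`, `"00046"`).
#' @return a CvRecord list (`source`, `accession`, `name`,
#'   `delta_monoisotopic_da` which is `NULL` when the term has no mass),
#'   or `NULL` when the term is unknown.
#' @examples
#' r <- pf_default_resolver()
#' pf_resolve(r, name = "phospho")$delta_monoisotopic_da
#' pf_resolve(r, source = "MOD", accession = "00046")$name
#' @export
pf_resolve <- function(resolver, name = NULL, source = NULL,
                       accession = NULL) {
  stopifnot(inherits(resolver, "pf_resolver"))
  df <- resolver$table
  if (!is.null(name)) {
    hits <- which(resolver$by_name == tolower(name))
    if (length(hits) == 0L) return(NULL)
    if (length(hits) > 1L) {
      ord <- match(df$source[hits], .pf_name_precedence)
      hits <- hits[order(ord)]
    }
    return(.pf_record(df, hits[1L]))
  }
  stopifnot(!is.null(source), !is.null(accession))
  key <- paste0(toupper(source), ":", toupper(accession))
  i <- match(key, resolver$by_accession)
  if (is.na(i)) return(NULL)
  .pf_record(df, i)
}

# Resolve a cv_name / cv_accession tag element.
pf_resolve_element <- function(resolver, el) {
  if (is.null(resolver)) return(NULL)
  switch(el$kind,
         cv_name = pf_resolve(resolver, name = el$name),
         cv_accession = pf_resolve(resolver, source = el$source,
                                   accession = el$accession),
         NULL)
}

.pf_resolver_cache <- new.env(parent = emptyenv())

#' The bundled controlled-vocabulary table
#'
#' Returns a resolver backed by the CV table shipped with the package,
#' covering the Unimod, PSI-MOD, XL-MOD and GNO terms used in the
#' package's examples and tests (loaded once per session and cached).
#'
#' @return a `pf_resolver`.
#' @export
pf_default_resolver <- function() {
  if (is.null(.pf_resolver_cache$default)) {
    .pf_resolver_cache$default <- pf_resolver(
      system.file("extdata", "cv_terms.tsv", package = "proforma",
                  mustWork = TRUE))
  }
  .pf_resolver_cache$default
}

#' @export
print.pf_resolver <- function(x, ...) {
  tab <- table(x$table$source)
  cat("<CV resolver: ", nrow(x$table), " records (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")>\n",
      sep = "")
  invisible(x)
}
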