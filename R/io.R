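#' Read a file of ProForma strings
#'
#' Reads a plain-text file with one ProForma string per line; empty lines
#' and lines starting with `#` are skipped.
#'
#' @param path path to the text file.
#' @param parse logical; parse each line (default) or return the raw
#'   strings.
#' @return a list of `pf_set` (named by line number), or a character
#'   vector when `parse = FALSE`.
#' @examples
#' path <- system.file("extdata", "table_examples.txt",
#'                     package = "proforma")
#' length(pf_read_file(path))
#' @export
pf_read_file <- function(path, parse = TRUE) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  strings <- trimws(lines[keep])
  if (!parse) return(strings)
  out <- lapply(seq_along(strings), function(i) {
    tryCatch(pf_parse(strings[i]), pf_parse_error = function(e) {
      stop("line ", which(keep)[i], ": ", conditionMessage(e),
           call. = FALSE)
    })
  })
  names(out) <- as.character(which(keep))
  out
}
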