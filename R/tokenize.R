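# Tokenizer: one left-to-right pass producing a flat token stream.
# Bracketed payloads ([..], {..}, <..>) are captured as atomic spans, so the
# structural characters '+', '/', '//', '(' etc. are only ever recognized at
# the top nesting level; payloads may contain arbitrary text (INFO tags,
# delta masses with '+', nested brackets in isotope formulas).

pf_parse_error <- function(message, offset, text) {
  frag <- substr(text, max(1L, offset - 8L),
                 min(nchar(text), offset + 8L))
  cond <- structure(
    class = c("pf_parse_error", "error", "condition"),
    list(message = sprintf("%s (at position %d, near \"%s\")",
                           message, offset, frag),
         call = NULL, offset = offset, fragment = frag))
  stop(cond)
}

# Internal tokenizer returning parallel vectors (fast path for the parser).
# Token types: residue, tag, labile, global, lparen, rparen, qmark, dash,
# slash, dslash, plus, mult, charge.
.pf_tokens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  type <- character(n)
  tex <- character(n)
  start <- integer(n)
  k <- 0L
  push <- function(t, x, s) {
    k <<- k + 1L
    type[k] <<- t; tex[k] <<- x; start[k] <<- s
  }
  digits <- as.character(0:9)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% LETTERS) {
      push("residue", ch, i); i <- i + 1L
    } else if (ch %in% letters) {
      push("residue", toupper(ch), i); i <- i + 1L
    } else if (ch == "[") {
      depth <- 1L; j <- i + 1L
      while (j <= n) {
        cj <- chars[j]
        if (cj == "[") depth <- depth + 1L
        else if (cj == "]") {
          depth <- depth - 1L
          if (depth == 0L) break
        }
        j <- j + 1L
      }
      if (depth != 0L) pf_parse_error("unbalanced '['", i, text)
      push("tag", substr(text, i + 1L, j - 1L), i)
      i <- j + 1L
      if (i <= n && chars[i] == "^") {
        j <- i + 1L
        while (j <= n && chars[j] %in% digits) j <- j + 1L
        if (j == i + 1L) {
          pf_parse_error("'^' must be followed by a positive integer",
                         i, text)
        }
        push("mult", substr(text, i + 1L, j - 1L), i)
        i <- j
      }
    } else if (ch == "{") {
      depth <- 1L; j <- i + 1L
      while (j <= n) {
        cj <- chars[j]
        if (cj == "{") depth <- depth + 1L
        else if (cj == "}") {
          depth <- depth - 1L
          if (depth == 0L) break
        }
        j <- j + 1L
      }
      if (depth != 0L) pf_parse_error("unbalanced '{'", i, text)
      push("labile", substr(text, i + 1L, j - 1L), i)
      i <- j + 1L
    } else if (ch == "<") {
      j <- i + 1L
      while (j <= n && chars[j] != ">") j <- j + 1L
      if (j > n) pf_parse_error("unbalanced '<'", i, text)
      push("global", substr(text, i + 1L, j - 1L), i)
      i <- j + 1L
    } else if (ch == "(") {
      push("lparen", "(", i); i <- i + 1L
    } else if (ch == ")") {
      push("rparen", ")", i); i <- i + 1L
    } else if (ch == "?") {
      push("qmark", "?", i); i <- i + 1L
    } else if (ch == "-") {
      push("dash", "-", i); i <- i + 1L
    } else if (ch == "/") {
      if (i < n && chars[i + 1L] == "/") {
        push("dslash", "//", i); i <- i + 2L
      } else {
        push("slash", "/", i)
        j <- i + 1L
        sgn <- ""
        if (j <= n && (chars[j] == "+" || chars[j] == "-")) {
          sgn <- chars[j]; j <- j + 1L
        }
        d0 <- j
        while (j <= n && chars[j] %in% digits) j <- j + 1L
        if (j == d0) {
          pf_parse_error("charge must be an integer", i + 1L, text)
        }
        push("charge", paste0(sgn, substr(text, d0, j - 1L)), i + 1L)
        i <- j
      }
    } else if (ch == "+") {
      push("plus", "+", i); i <- i + 1L
    } else if (ch == "]" || ch == "}" || ch == ">") {
      pf_parse_error(paste0("unmatched '", ch, "'"), i, text)
    } else if (ch == "\n" || ch == "\r") {
      pf_parse_error("line breaks are not allowed", i, text)
    } else {
      pf_parse_error(paste0("unexpected character '", ch, "'"), i, text)
    }
  }
  list(type = type[seq_len(k)], tex = tex[seq_len(k)],
       start = start[seq_len(k)])
}

#' Tokenize a ProForma 2.0 string
#'
#' Splits a string into its lexical tokens: residue letters, bracketed
#' payload spans (`[...]`, `{...}`, `<...>` captured atomically), the
#' structural characters `( ) ? -`, the chain separator `//`, the chimeric
#' separator `+`, the charge separator `/` with its integer, and
#' unknown-position multiplicities `^n`.  Character offsets (1-based) are
#' preserved for error reporting.
#'
#' @param text a single ProForma string.
#' @return a data frame with columns `type`, `text` and `start`.
#' @examples
#' pf_tokenize("A[+1.0]")
#' @export
pf_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  tk <- .pf_tokens(text)
  data.frame(type = tk$type, text = tk$tex, start = tk$start,
             stringsAsFactors = FALSE)
}
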