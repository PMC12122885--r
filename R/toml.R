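#' Minimal TOML configuration reader
#'
#' Parses the subset of TOML used by the pipeline configuration files:
#' `[table]` headers, `key = value` pairs with string, number, boolean and
#' flat-array values, and `#` comments. Nested tables (`[a.b]`) become
#' nested lists. (No TOML parser is available among the supported
#' dependencies; this reader intentionally covers only the configuration
#' subset.)
#'
#' @param path file path.
#' @return a named nested list.
#' @export
read_config_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- character(0)
  parse_scalar <- function(tok) {
    tok <- trimws(tok)
    if (tok %in% c("true", "false")) return(tok == "true")
    if (grepl('^".*"$', tok)) return(gsub('^"|"$', "", tok))
    if (grepl("^'.*'$", tok)) return(gsub("^'|'$", "", tok))
    num <- suppressWarnings(as.numeric(tok))
    if (!is.na(num)) return(num)
    tok
  }
  parse_value <- function(tok) {
    tok <- trimws(tok)
    if (grepl("^\\[.*\\]$", tok)) {
      inner <- substr(tok, 2, nchar(tok) - 1)
      if (trimws(inner) == "") return(list())
      parts <- strsplit(inner, ",")[[1]]
      vals <- lapply(parts, parse_scalar)
      return(unlist(vals))
    }
    parse_scalar(tok)
  }
  set_nested <- function(lst, keys, value) {
    if (length(keys) == 1) { lst[[keys]] <- value; return(lst) }
    if (is.null(lst[[keys[1]]])) lst[[keys[1]]] <- list()
    lst[[keys[1]]] <- set_nested(lst[[keys[1]]], keys[-1], value)
    lst
  }
  for (raw in lines) {
    line <- sub("#.*$", "", raw)
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[.*\\]$", line)) {
      section <- strsplit(gsub("^\\[|\\]$", "", line), ".", fixed = TRUE)[[1]]
      next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0) stop(sprintf("malformed TOML line: %s", raw))
    key <- trimws(substr(line, 1, eq - 1))
    val <- parse_value(substr(line, eq + 1, nchar(line)))
    out <- set_nested(out, c(section, key), val)
  }
  out
}
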