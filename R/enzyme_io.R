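#' Parse a restriction-enzyme list
#'
#' One enzyme per non-empty line: the enzyme name followed by its
#' recognition sequence, tab or space delimited.  IUPAC ambiguity codes are
#' allowed in the recognition sequence.  Blank lines and `#`-prefixed
#' comment lines are skipped.  Duplicate names: the last entry wins, with a
#' warning.
#'
#' @param text either a character vector of lines, a single string with
#'   embedded newlines, or a path to a file.
#' @return an `enzyme_catalog`: a data frame with columns `name`,
#'   `recognition`, `site_length`, and a `selection` attribute (enabled
#'   enzyme names; defaults to all).
#' @export
parse_enzyme_list <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  if (!length(idx)) stop("enzyme list contains no entries", call. = FALSE)
  name <- character(0); recog <- character(0)
  for (i in idx) {
    fields <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(fields) != 2L)
      stop(sprintf("enzyme list parse error at line %d: expected 'NAME SITE', got %d field(s)",
                   i, length(fields)), call. = FALSE)
    pat <- toupper(fields[[2]])
    bad <- setdiff(unique(strsplit(pat, "")[[1]]), IUPAC_SYMBOLS)
    if (length(bad))
      stop(sprintf("enzyme list parse error at line %d: invalid recognition pattern '%s'",
                   i, fields[[2]]), call. = FALSE)
    name <- c(name, fields[[1]]); recog <- c(recog, pat)
  }
  if (anyDuplicated(name)) {
    dup <- unique(name[duplicated(name)])
    warning("duplicate enzyme name(s), keeping the last definition: ",
            paste(dup, collapse = ", "), call. = FALSE)
    keep_last <- !duplicated(name, fromLast = TRUE)
    name <- name[keep_last]; recog <- recog[keep_last]
  }
  new_catalog(name, recog)
}

new_catalog <- function(name, recognition, selection = name) {
  rc <- vapply(recognition, revcomp, "", USE.NAMES = FALSE)
  cat <- data.frame(name = name, recognition = recognition,
                    site_length = nchar(recognition),
                    rc = rc, palindromic = recognition == rc,
                    stringsAsFactors = FALSE)
  structure(cat, class = c("enzyme_catalog", "data.frame"),
            selection = selection)
}

#' Built-in restriction-enzyme catalog
#'
#' A packaged catalog of common commercially available Type II enzymes
#' (REBASE-derived recognition sequences, 4-8 nt, palindromic and
#' degenerate sites included).  The user-supplied list from
#' [parse_enzyme_list()] is the authoritative override.
#'
#' @return an `enzyme_catalog`.
#' @export
default_catalog <- function() {
  path <- system.file("extdata", "enzymes_default.txt", package = "sdmprimer",
                      mustWork = TRUE)
  parse_enzyme_list(path)
}

#' Enable a subset of enzymes in a catalog
#'
#' @param catalog an `enzyme_catalog`.
#' @param names enzyme names to enable; must all exist in the catalog.
#' @return the catalog with its `selection` attribute replaced.
#' @export
select_enzymes <- function(catalog, names) {
  stopifnot(inherits(catalog, "enzyme_catalog"))
  missing <- setdiff(names, catalog$name)
  if (length(missing))
    stop("enzyme(s) not in catalog: ", paste(missing, collapse = ", "),
         call. = FALSE)
  attr(catalog, "selection") <- names
  catalog
}

#' Enabled subset of a catalog
#' @param catalog an `enzyme_catalog`.
#' @return data frame of the enabled enzymes, in catalog order.
#' @export
enabled_enzymes <- function(catalog) {
  stopifnot(inherits(catalog, "enzyme_catalog"))
  sel <- attr(catalog, "selection")
  catalog[catalog$name %in% sel, , drop = FALSE]
}

#' Serialize a catalog back to the `NAME<tab>SITE` line format
#' @param catalog an `enzyme_catalog`.
#' @return character vector of lines; `parse_enzyme_list()` of the result
#'   reproduces the catalog.
#' @export
serialize_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "enzyme_catalog"))
  paste(catalog$name, catalog$recognition, sep = "\t")
}

#' @export
print.enzyme_catalog <- function(x, ...) {
  cat(sprintf("<enzyme catalog: %d enzymes, %d enabled>\n",
              nrow(x), length(attr(x, "selection"))))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
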