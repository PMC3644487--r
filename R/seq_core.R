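#' sdmprimer: SDM primers with silent restriction-site identifiers
#'
#' Design and score site-directed mutagenesis (SDM) primer pairs that carry a
#' silent restriction-site identifier, so mutant clones can be screened by a
#' diagnostic digest.  The workflow is: validate an in-frame coding sequence
#' ([as_cds()]), enumerate all codon realizations of the requested amino-acid
#' substitutions ([enumerate_candidates()]), search/remove/insert restriction
#' sites silently ([find_sites()], [remove_sites_silently()],
#' [insert_sites_silently()]), rank the candidate windows ([preselect()]),
#' design partially overlapping primer pairs ([design_primer_pairs()]) and
#' score them ([score_primer()]).  [run_pipeline()] chains all steps.
#'
#' @importFrom methods is
#' @importFrom stats setNames
#' @importFrom utils write.table head
#' @keywords internal
"_PACKAGE"

IUPAC_SYMBOLS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' Normalize raw DNA text
#'
#' Uppercases the input and strips whitespace, digits and ruler artifacts
#' (anything that is not a letter).  Any remaining character outside
#' `A/C/G/T` is an error -- ambiguous bases are not guessed at.
#'
#' @param x a single character string of DNA.
#' @return an uppercase string over `ACGT`.
#' @export
normalize_dna <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("DNA input must be a single character string", call. = FALSE)
  s <- toupper(gsub("[^A-Za-z]", "", x))
  bad <- unique(strsplit(gsub("[ACGT]", "", s), "")[[1]])
  if (length(bad))
    stop("non-ACGT character(s) in sequence after normalization: ",
         paste(bad, collapse = ", "), call. = FALSE)
  s
}

#' Validated in-frame coding sequence
#'
#' Constructs a coding-sequence object from raw text.  The sequence is
#' assumed to begin in frame at base 1; a trailing partial codon (1-2 nt) is
#' tolerated and ignored by all codon-level operations.
#'
#' @param x raw DNA text (whitespace, digits and case are tolerated).
#' @return a character scalar of class `sdm_cds`.
#' @export
as_cds <- function(x) {
  if (inherits(x, "sdm_cds")) return(x)
  s <- normalize_dna(x)
  if (nchar(s) < 3L)
    stop("coding sequence must contain at least one complete codon", call. = FALSE)
  structure(s, class = "sdm_cds")
}

#' @export
print.sdm_cds <- function(x, ...) {
  n <- nchar(x)
  cat(sprintf("<coding sequence: %d nt, %d codons>\n", n, n %/% 3L))
  cat(if (n > 60) paste0(substr(x, 1, 60), "...") else unclass(x), "\n")
  invisible(x)
}

#' Read a coding sequence from a plain-text or FASTA file
#'
#' Single-record FASTA (first non-blank line starts with `>`) or plain text.
#' Multi-record FASTA is rejected.
#'
#' @param path file path.
#' @return an `sdm_cds` object.
#' @export
read_cds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty sequence file: ", path, call. = FALSE)
  if (startsWith(trimws(lines[[1]]), ">")) {
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) != 1L)
      stop("expected a single FASTA record, found ", length(set), call. = FALSE)
    as_cds(as.character(set[[1]]))
  } else {
    as_cds(paste(lines, collapse = ""))
  }
}

#' Split a sequence into complete codons
#'
#' @param s DNA string; a trailing partial codon is dropped.
#' @return character vector of 3-nt codons.
#' @export
codons_of <- function(s) {
  s <- as.character(s)
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0))
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a coding sequence
#'
#' Standard genetic code (translation table 1); stops are reported as `*`.
#' A trailing partial codon is ignored, so the protein length is
#' `floor(nchar(cds) / 3)`.
#'
#' @param cds an `sdm_cds` object or DNA string over `ACGT`.
#' @return single-letter amino-acid string (may contain `*`).
#' @export
translate_cds <- function(cds) {
  s <- if (inherits(cds, "sdm_cds")) unclass(cds) else normalize_dna(cds)
  if (nchar(s) < 3L)
    stop("nothing to translate: fewer than 3 nt", call. = FALSE)
  aa <- Biostrings::GENETIC_CODE[codons_of(s)]
  if (anyNA(aa)) stop("untranslatable codon encountered", call. = FALSE)
  paste(aa, collapse = "")
}

# codon sets by residue, built once per session from the standard code
.syn_cache <- new.env(parent = emptyenv())
syn_table <- function() {
  if (is.null(.syn_cache$tab)) {
    gc <- Biostrings::GENETIC_CODE
    .syn_cache$tab <- lapply(split(names(gc), unname(gc)), sort)
  }
  .syn_cache$tab
}

#' Synonymous codons of a residue
#'
#' @param aa one-letter amino-acid code (or `*` for stop).
#' @return sorted character vector of codons encoding `aa` in the standard
#'   code (1-6 codons; 3 for `*`).
#' @export
synonymous_codons <- function(aa) {
  if (!is.character(aa) || length(aa) != 1L || nchar(aa) != 1L)
    stop("expected a single one-letter residue code", call. = FALSE)
  hits <- syn_table()[[aa]]
  if (is.null(hits)) stop("unknown residue: ", aa, call. = FALSE)
  hits
}

#' Expand an IUPAC pattern to concrete sequences
#'
#' @param p string over the 15 IUPAC nucleotide codes.
#' @return sorted character vector; length equals the product of the
#'   per-symbol degeneracies.
#' @export
expand_iupac <- function(p) {
  p <- toupper(as.character(p))
  if (length(p) != 1L || !nchar(p))
    stop("expected a single non-empty pattern", call. = FALSE)
  sym <- strsplit(p, "")[[1]]
  bad <- setdiff(unique(sym), IUPAC_SYMBOLS)
  if (length(bad))
    stop("illegal IUPAC symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  sets <- lapply(sym, function(s) {
    sort(strsplit(Biostrings::IUPAC_CODE_MAP[[s]], "")[[1]])
  })
  out <- ""
  for (set in sets) out <- as.vector(t(outer(out, set, paste0)))
  sort(out)
}

#' Per-pattern degeneracy
#' @param p IUPAC pattern.
#' @return integer product of per-symbol degeneracies.
#' @export
iupac_cardinality <- function(p) {
  sym <- strsplit(toupper(p), "")[[1]]
  bad <- setdiff(unique(sym), IUPAC_SYMBOLS)
  if (length(bad))
    stop("illegal IUPAC symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  prod(vapply(sym, function(s) nchar(Biostrings::IUPAC_CODE_MAP[[s]]), 1))
}

#' Reverse complement
#'
#' IUPAC ambiguity codes are complemented correctly (so recognition patterns
#' can be strand-flipped).  Applying the function twice is the identity.
#'
#' @param s DNA string (IUPAC codes allowed).
#' @return reverse complement, 5' to 3'.
#' @export
revcomp <- function(s) {
  s <- toupper(as.character(s))
  if (length(s) != 1L) stop("expected a single string", call. = FALSE)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), IUPAC_SYMBOLS)
  if (length(bad))
    stop("non-nucleotide character(s): ", paste(bad, collapse = ", "), call. = FALSE)
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s),
                     "")[[1]]), collapse = "")
}

#' Is a recognition pattern palindromic?
#'
#' A pattern is palindromic when it equals its own IUPAC-aware reverse
#' complement (e.g. `CATATG`, `GTYRAC`).
#'
#' @param p IUPAC pattern.
#' @return logical.
#' @export
is_palindromic <- function(p) {
  identical(toupper(as.character(p)), revcomp(p))
}
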