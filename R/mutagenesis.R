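#' Amino-acid substitution request
#'
#' @param aa_position 1-based codon index in the coding sequence.
#' @param wt_residue expected wild-type residue at that position (checked
#'   against the translation when a window is built).
#' @param target_residue residue to mutate to.
#' @param forced_codon optional codon to force for the target residue
#'   (must translate to `target_residue`).
#' @return a `mutation_spec` list.
#' @export
mutation_spec <- function(aa_position, wt_residue, target_residue,
                          forced_codon = NULL) {
  aa_position <- as.integer(aa_position)
  if (is.na(aa_position) || aa_position < 1L)
    stop("aa_position must be a positive integer", call. = FALSE)
  for (r in c(wt_residue, target_residue))
    if (!r %in% c(Biostrings::AA_STANDARD, "*"))
      stop("unknown residue code: ", r, call. = FALSE)
  if (!is.null(forced_codon)) {
    forced_codon <- toupper(forced_codon)
    if (!forced_codon %in% synonymous_codons(target_residue))
      stop(sprintf("forced codon %s does not encode %s",
                   forced_codon, target_residue), call. = FALSE)
  }
  structure(list(aa_position = aa_position, wt_residue = wt_residue,
                 target_residue = target_residue, forced_codon = forced_codon),
            class = "mutation_spec")
}

#' Parse mutation strings like `"G255A"` or `"G255A=GCA"`
#'
#' @param x character vector of substitution requests: wild-type residue,
#'   1-based position, target residue, optionally `=CODON` to force a codon.
#' @return list of `mutation_spec`.
#' @export
parse_mutations <- function(x) {
  out <- lapply(x, function(m) {
    mt <- regmatches(m, regexec("^([A-Z*])([0-9]+)([A-Z*])(=([ACGTacgt]{3}))?$", m))[[1]]
    if (!length(mt))
      stop("cannot parse mutation '", m,
           "' (expected e.g. G255A or G255A=GCA)", call. = FALSE)
    mutation_spec(as.integer(mt[[3]]), mt[[2]], mt[[4]],
                  forced_codon = if (nzchar(mt[[6]])) mt[[6]] else NULL)
  })
  out
}

#' Extract the mutation window around the requested substitutions
#'
#' The window spans all mutated codons plus `flank_codons` codons on each
#' side (clipped at the sequence ends).  With the default flank of 3 codons,
#' two mutations two codons apart give a 9-residue window.
#'
#' @param cds an `sdm_cds` (or coercible DNA string).
#' @param specs list of `mutation_spec` (or character vector accepted by
#'   [parse_mutations()]).
#' @param flank_codons codons of wild-type context each side (default 3).
#' @return a `mutation_window` list: `first_codon`, `last_codon` (1-based in
#'   the CDS), `wt_bases`, `wt_residues`, `specs`, `cds`.
#' @export
build_window <- function(cds, specs, flank_codons = 3L) {
  cds <- as_cds(cds)
  if (is.character(specs)) specs <- parse_mutations(specs)
  if (inherits(specs, "mutation_spec")) specs <- list(specs)
  if (!length(specs)) stop("no mutations requested", call. = FALSE)
  n_codons <- nchar(cds) %/% 3L
  protein <- translate_cds(cds)
  for (sp in specs) {
    if (sp$aa_position > n_codons)
      stop(sprintf("mutation position %d beyond the last complete codon (%d)",
                   sp$aa_position, n_codons), call. = FALSE)
    found <- substr(protein, sp$aa_position, sp$aa_position)
    if (found != sp$wt_residue)
      stop(sprintf(
        "wild-type residue mismatch at codon %d: expected %s, translation shows %s",
        sp$aa_position, sp$wt_residue, found), call. = FALSE)
  }
  pos <- vapply(specs, `[[`, 1L, "aa_position")
  if (anyDuplicated(pos))
    stop("multiple mutations at the same codon", call. = FALSE)
  first <- max(1L, min(pos) - as.integer(flank_codons))
  last <- min(n_codons, max(pos) + as.integer(flank_codons))
  wt_bases <- substr(cds, 3L * first - 2L, 3L * last)
  structure(list(first_codon = first, last_codon = last,
                 wt_bases = wt_bases,
                 wt_residues = translate_cds(wt_bases),
                 specs = specs, cds = cds),
            class = "mutation_window")
}

#' @export
print.mutation_window <- function(x, ...) {
  cat(sprintf("<mutation window: codons %d-%d (%d residues)>\n %s\n %s\n",
              x$first_codon, x$last_codon, x$last_codon - x$first_codon + 1L,
              x$wt_bases, x$wt_residues))
  invisible(x)
}

# Per-window-codon codon sets after applying the specs: mutated codons get
# the target residue's synonymous set (or the forced codon); all other
# codons are pinned to their wild-type codon.
window_codon_sets <- function(window, free_flanks = FALSE) {
  wt_codons <- codons_of(window$wt_bases)
  sets <- as.list(wt_codons)
  for (sp in window$specs) {
    k <- sp$aa_position - window$first_codon + 1L
    sets[[k]] <- if (is.null(sp$forced_codon))
      synonymous_codons(sp$target_residue) else sp$forced_codon
  }
  if (free_flanks) {
    mut_idx <- vapply(window$specs, `[[`, 1L, "aa_position") -
      window$first_codon + 1L
    for (k in setdiff(seq_along(sets), mut_idx))
      sets[[k]] <- synonymous_codons(Biostrings::GENETIC_CODE[[wt_codons[[k]]]])
  }
  sets
}

# The residue string the window must translate to after mutation.
target_residues <- function(window) {
  res <- strsplit(window$wt_residues, "")[[1]]
  for (sp in window$specs)
    res[sp$aa_position - window$first_codon + 1L] <- sp$target_residue
  paste(res, collapse = "")
}

new_candidate <- function(window, bases, origin = "substitution") {
  wt <- strsplit(window$wt_bases, "")[[1]]
  mu <- strsplit(bases, "")[[1]]
  changed <- which(wt != mu)
  structure(list(bases = bases,
                 changed_positions = changed,
                 n_changes = length(changed),
                 residues = translate_cds(bases),
                 gc = gc_percent(bases),
                 origin = origin,
                 sites_gained = NULL, sites_lost = NULL),
            class = "sdm_candidate")
}

#' Enumerate all codon realizations of the requested substitutions
#'
#' Every combination of synonymous codons for the target residues (or the
#' forced codon, where given); unmutated codons keep their wild-type bases.
#' Ordering is deterministic: codon sets are iterated lexicographically,
#' with the last mutated codon varying fastest.
#'
#' @param window a `mutation_window`.
#' @param cap maximum number of candidates (default 10000); exceeding it is
#'   an error suggesting forced codons.
#' @return list of `sdm_candidate` objects.
#' @export
enumerate_candidates <- function(window, cap = 10000L) {
  stopifnot(inherits(window, "mutation_window"))
  sets <- window_codon_sets(window)
  n <- prod(vapply(sets, length, 1L))
  if (n > cap)
    stop(sprintf(
      "%d candidate sequences exceed the cap of %d; force codons (e.g. G255A=GCA) to narrow the search",
      n, cap), call. = FALSE)
  grid <- expand.grid(rev(sets), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)[, rev(seq_along(sets)), drop = FALSE]
  bases <- apply(grid, 1L, paste, collapse = "")
  lapply(bases, function(b) new_candidate(window, b))
}

#' @export
print.sdm_candidate <- function(x, ...) {
  cat(sprintf("<candidate (%s): %s | %d change(s) at %s | GC %.1f%%>\n",
              x$origin, x$bases, x$n_changes,
              paste(x$changed_positions, collapse = ","), x$gc))
  invisible(x)
}
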