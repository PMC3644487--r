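stage <- function(label, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", label, conditionMessage(e)), call. = FALSE))
}

#' Run the full SDM primer-design pipeline
#'
#' Chains window extraction, candidate enumeration, silent site
#' removal/insertion, candidate ranking, primer-pair design, metric
#' computation and scoring, and returns the pre-evaluation table together
#' with the primer report.
#'
#' @param seq coding sequence: an `sdm_cds`, a DNA string, or a path to a
#'   plain-text/FASTA file.
#' @param mutations character vector like `c("G255A", "G257A")` (optionally
#'   `"G255A=GCA"` to force a codon) or a list of [mutation_spec()].
#' @param catalog an `enzyme_catalog` (default [default_catalog()]).
#' @param select optional character vector of enzyme names to enable.
#' @param candidate `"auto"` (default: first ranked candidate that gains or
#'   loses a site, falling back to the first row) or a row number of the
#'   pre-evaluation table.
#' @param flank_codons wild-type codons flanking the mutations in the
#'   window (default 3).
#' @param params a [design_params()].
#' @param config a [scoring_config()].
#' @param cap candidate cap for [enumerate_candidates()].
#' @param ... forwarded to [melting_temperature()].
#' @return an `sdm_run` list: `window`, `preselect` (ranked candidate
#'   table), `selected` (chosen row), `report` (primer table), `catalog`.
#' @export
run_pipeline <- function(seq, mutations, catalog = default_catalog(),
                         select = NULL, candidate = "auto",
                         flank_codons = 3L, params = design_params(),
                         config = scoring_config(), cap = 10000L, ...) {
  cds <- stage("input", {
    if (is.character(seq) && length(seq) == 1L && file.exists(seq))
      read_cds(seq) else as_cds(seq)
  })
  if (!is.null(select))
    catalog <- stage("enzymes", select_enzymes(catalog, select))
  if (!nrow(enabled_enzymes(catalog)))
    warning("no restriction enzymes enabled: primers will carry no ",
            "silent-site identifier", call. = FALSE)
  window <- stage("window", build_window(cds, mutations, flank_codons))
  pool <- stage("site engineering",
                survey_candidates(window, catalog, cap = cap))
  ranked <- stage("preselect", preselect(pool))
  sel_row <- stage("selection", {
    if (identical(candidate, "auto")) {
      with_id <- which(nzchar(ranked$sites_gained) | nzchar(ranked$sites_lost))
      if (length(with_id)) with_id[[1]]
      else {
        if (nrow(enabled_enzymes(catalog)))
          warning("no candidate gains or loses a restriction site; ",
                  "selecting the top-ranked candidate without an identifier",
                  call. = FALSE)
        1L
      }
    } else {
      k <- as.integer(candidate)
      if (is.na(k) || k < 1L || k > nrow(ranked))
        stop("candidate index out of range 1-", nrow(ranked))
      k
    }
  })
  selected <- ranked[sel_row, , drop = FALSE]
  report <- stage("primer design",
                  design_primer_pairs(cds, selected$bases, window,
                                      params = params, catalog = catalog,
                                      config = config, ...))
  structure(list(window = window, preselect = ranked, selected = selected,
                 report = report, catalog = catalog),
            class = "sdm_run")
}

#' @export
print.sdm_run <- function(x, ...) {
  print(x$window)
  cat(sprintf("%d candidate window(s); selected #%d: %s (%d changes%s)\n",
              nrow(x$preselect), x$selected$candidate, x$selected$bases,
              x$selected$n_changes,
              if (nzchar(x$selected$sites_gained))
                paste0(", gains ", x$selected$sites_gained)
              else if (nzchar(x$selected$sites_lost))
                paste0(", loses ", x$selected$sites_lost) else ""))
  cat(sprintf("%d primer(s) designed:\n", nrow(x$report)))
  print(format_report(x$report), row.names = FALSE, right = FALSE)
  invisible(x)
}

REPORT_HEADER <- c("No.", "Orientation", "Primer (5'-3')", "Score [%]",
                   "nt changes", "Tm [C]", "nt", "GC%", "3'dG", "5'dG",
                   "Runs", "Rep.", "RE sites", "3'GC%", "Comments")

format_report <- function(report) {
  stopifnot(is.data.frame(report))
  out <- data.frame(
    report$no, report$orientation, report$primer,
    as.integer(report$score_pct), report$nt_changes,
    sprintf("%.2f", report$tm_c), report$nt,
    sprintf("%.2f", report$gc_pct),
    sprintf("%.2f", report$dg3), sprintf("%.2f", report$dg5),
    report$runs, report$repeats, report$re_sites,
    as.integer(round(report$gc3_pct)), report$comments,
    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- REPORT_HEADER
  out
}

#' Write the primer report as a tab-separated file
#'
#' Fifteen columns (primer number, orientation, sequence, score, mismatch
#' count, Tm, length, GC%, 3'/5' delta-G, runs, repeats, restriction-site
#' count, 3'-GC% and comments), UTF-8, header row; scores and 3'-GC% as
#' integers, Tm/GC/delta-G with two decimals, ASCII minus signs.  Output is
#' byte-identical across runs for identical inputs.
#'
#' @param report a `primer_report` (or the `report` element of an
#'   `sdm_run`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "sdm_run")) report <- report$report
  if (!nrow(report)) stop("empty report", call. = FALSE)
  out <- format_report(report)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(out), collapse = "\t"),
               do.call(paste, c(unname(out), sep = "\t"))),
             con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Seeded random test fixture
#'
#' Reproducible in-frame coding sequence (uniform draw over the 61 sense
#' codons, so there is no internal stop) plus random substitution requests
#' whose wild-type residues match the translation.  Mutated positions keep
#' at least 3 codons of flank inside the sequence.
#'
#' @param seed integer seed.
#' @param n_codons number of codons (must be at least `n_mutations + 8`).
#' @param n_mutations number of substitution requests.
#' @return list with `cds` (an `sdm_cds`) and `specs` (list of
#'   [mutation_spec()]).
#' @export
generate_fixture <- function(seed, n_codons, n_mutations = 1L) {
  n_codons <- as.integer(n_codons); n_mutations <- as.integer(n_mutations)
  if (n_codons < n_mutations + 8L)
    stop("need n_codons >= n_mutations + 8", call. = FALSE)
  set.seed(as.integer(seed))
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  codons <- sample(sense, n_codons, replace = TRUE)
  cds <- as_cds(paste(codons, collapse = ""))
  protein <- strsplit(translate_cds(cds), "")[[1]]
  pos <- sort(sample(seq(4L, n_codons - 3L), n_mutations))
  specs <- lapply(pos, function(p) {
    wt <- protein[[p]]
    target <- sample(setdiff(Biostrings::AA_STANDARD, wt), 1L)
    mutation_spec(p, wt, target)
  })
  list(cds = cds, specs = specs)
}
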