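#' Primer-pair geometry parameters
#'
#' Partially overlapping SDM primer pairs: each primer keeps a fixed
#' wild-type-identical 5' anchor upstream of the first changed base and
#' enumerates 3' ends extending `three_min` to `three_max` nt past the last
#' changed base; forward and reverse primers overlap over the mutated core
#' only.  The defaults (anchor 10 nt, 3' extension 12-16 nt, length bounds
#' 25-45 nt) give a five-primer series of 29-33 nt per orientation for a
#' 7-nt mutated core.
#'
#' @param min_len,max_len primer length bounds in nt.
#' @param five_anchor nt of wild-type-identical sequence 5' of the first
#'   changed base.
#' @param three_min,three_max nt of wild-type-identical 3' extension past
#'   the last changed base.
#' @return a `design_params` list.
#' @export
design_params <- function(min_len = 25L, max_len = 45L, five_anchor = 10L,
                          three_min = 12L, three_max = 16L) {
  p <- lapply(list(min_len = min_len, max_len = max_len,
                   five_anchor = five_anchor, three_min = three_min,
                   three_max = three_max), as.integer)
  stopifnot(p$min_len <= p$max_len, p$three_min <= p$three_max,
            p$five_anchor >= 0L, p$three_min >= 0L)
  structure(p, class = "design_params")
}

#' Mismatches between a primer and its template
#'
#' Hamming distance between the primer and the strand-appropriate template
#' substring.  `template_start` is the 1-based position of the primer's 5'
#' base on its own strand's coordinates (for reverse primers, on the
#' antisense strand, whose base 1 pairs with the last sense base).
#'
#' @param primer primer sequence, 5' to 3'.
#' @param template the wild-type coding sequence (`sdm_cds` or string).
#' @param template_start 1-based 5' position on the primer's strand.
#' @param orientation `"forward"` or `"reverse"`.
#' @return integer mismatch count.
#' @export
count_nt_changes <- function(primer, template, template_start,
                             orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  primer <- normalize_dna(as.character(primer))
  template <- as.character(as_cds(template))
  if (orientation == "reverse") template <- revcomp(template)
  stop_at <- template_start + nchar(primer) - 1L
  if (template_start < 1L || stop_at > nchar(template))
    stop("primer overhangs the template (positions ", template_start, "-",
         stop_at, " on a ", nchar(template), " nt strand)", call. = FALSE)
  ref <- substr(template, template_start, stop_at)
  sum(strsplit(primer, "")[[1]] != strsplit(ref, "")[[1]])
}

#' Design partially overlapping SDM primer pairs
#'
#' Builds the mutant template (wild type with the selected candidate window
#' substituted), then enumerates forward primers with a fixed 5' start
#' `five_anchor` nt upstream of the first changed base and 3' ends
#' `three_min..three_max` nt past the last changed base; reverse primers
#' are built symmetrically on the antisense strand.  Every primer covers
#' all changed bases and carries its metric panel, weighted score and
#' re-verified restriction sites (positions 1-based within the primer's own
#' 5'->3' sequence).
#'
#' @param template wild-type coding sequence (`sdm_cds` or string).
#' @param selected the chosen `sdm_candidate` (or its window base string).
#' @param window the `mutation_window` the candidate was built on.
#' @param params a [design_params()].
#' @param catalog an `enzyme_catalog` used to annotate sites in the primers.
#' @param config a [scoring_config()].
#' @param ... forwarded to [melting_temperature()].
#' @return a `primer_report` data frame, one row per primer: `no`,
#'   `orientation`, `primer`, `score_pct`, `nt_changes`, `tm_c`, `nt`,
#'   `gc_pct`, `dg3`, `dg5`, `runs`, `repeats`, `re_sites`, `gc3_pct`,
#'   `comments`, `template_start`.
#' @export
design_primer_pairs <- function(template, selected, window,
                                params = design_params(),
                                catalog = default_catalog(),
                                config = scoring_config(), ...) {
  stopifnot(inherits(window, "mutation_window"), inherits(params, "design_params"))
  template <- as_cds(template)
  bases <- if (inherits(selected, "sdm_candidate")) selected$bases
           else as.character(selected)
  if (nchar(bases) != nchar(window$wt_bases))
    stop("selected candidate length does not match the window", call. = FALSE)
  offset <- 3L * (window$first_codon - 1L)
  wt_chars <- strsplit(window$wt_bases, "")[[1]]
  changed_local <- which(strsplit(bases, "")[[1]] != wt_chars)
  if (!length(changed_local))
    stop("selected candidate is identical to the wild type; no primer to design",
         call. = FALSE)
  n <- nchar(template)
  mutant <- paste0(substr(template, 1L, offset), bases,
                   substr(template, offset + nchar(bases) + 1L, n))
  d1 <- offset + min(changed_local)
  d2 <- offset + max(changed_local)

  fstart <- d1 - params$five_anchor
  fends <- d2 + params$three_min:params$three_max
  rstart <- d2 + params$five_anchor          # sense coord of reverse 5' base
  rends <- d1 - params$three_min:params$three_max
  if (fstart < 1L)
    stop("mutation too close to the 5' end: forward anchor needs ",
         1L - fstart, " nt more upstream", call. = FALSE)
  if (max(fends) > n)
    stop("mutation too close to the 3' end: forward extension needs ",
         max(fends) - n, " nt more downstream", call. = FALSE)
  if (rstart > n)
    stop("mutation too close to the 3' end: reverse anchor needs ",
         rstart - n, " nt more downstream", call. = FALSE)
  if (min(rends) < 1L)
    stop("mutation too close to the 5' end: reverse extension needs ",
         1L - min(rends), " nt more upstream", call. = FALSE)

  build <- function(seq5to3, orientation, template_start) {
    nc <- count_nt_changes(seq5to3, template, template_start, orientation)
    met <- primer_metrics(seq5to3, nc, ...)
    sc <- score_primer(met, config)
    sites <- find_sites(seq5to3, catalog)
    data.frame(orientation = orientation, primer = seq5to3,
               score_pct = sc$percent, nt_changes = nc, tm_c = met$tm_c,
               nt = met$length_nt, gc_pct = met$gc_pct,
               dg3 = met$dg3_kcal, dg5 = met$dg5_kcal,
               runs = met$runs, repeats = met$repeats,
               re_sites = nrow(sites), gc3_pct = met$gc3_pct,
               comments = if (nrow(sites))
                 paste0("RE sites: ", fmt_sites(sites)) else "",
               template_start = template_start, stringsAsFactors = FALSE)
  }

  rows <- list()
  for (e in fends) {
    len <- e - fstart + 1L
    if (len < params$min_len || len > params$max_len) next
    rows[[length(rows) + 1L]] <-
      build(substr(mutant, fstart, e), "forward", fstart)
  }
  for (e in rends) {
    len <- rstart - e + 1L
    if (len < params$min_len || len > params$max_len) next
    rows[[length(rows) + 1L]] <-
      build(revcomp(substr(mutant, e, rstart)), "reverse", n - rstart + 1L)
  }
  if (!length(rows))
    stop("no primer satisfies the length bounds ", params$min_len, "-",
         params$max_len, " nt", call. = FALSE)
  report <- do.call(rbind, rows)
  report <- cbind(no = seq_len(nrow(report)), report)
  rownames(report) <- NULL
  class(report) <- c("primer_report", "data.frame")
  report
}
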