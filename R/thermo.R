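# Nearest-neighbor parameter tables, keyed by the 5'->3' dinucleotide of
# the top strand (the complementary stack shares the same parameters).
# dh: kcal/mol, ds: cal/(mol K).
NN_TABLES <- list(
  # Breslauer, Frank, Bloecker & Marky 1986, PNAS 83:3746 (classic primer
  # design set; duplex initiation entropy -16.8 with at least one G:C pair,
  # -20.1 for all-A:T duplexes)
  breslauer1986 = list(
    dh = c(AA = -9.1, AT = -8.6, TA = -6.0, CA = -5.8, GT = -6.5,
           CT = -7.8, GA = -5.6, CG = -11.9, GC = -11.1, GG = -11.0),
    ds = c(AA = -24.0, AT = -23.9, TA = -16.9, CA = -12.9, GT = -17.3,
           CT = -20.8, GA = -13.5, CG = -27.8, GC = -26.7, GG = -26.6),
    init = function(seq) {
      anyGC <- grepl("[GC]", seq)
      list(dh = 0, ds = if (anyGC) -16.8 else -20.1)
    }),
  # Allawi & SantaLucia 1997 / SantaLucia 1998 unified set, with terminal
  # A:T / G:C initiation penalties
  santalucia1998 = list(
    dh = c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0),
    ds = c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9),
    init = function(seq) {
      ends <- c(substr(seq, 1, 1), substr(seq, nchar(seq), nchar(seq)))
      nAT <- sum(ends %in% c("A", "T")); nGC <- 2L - nAT
      list(dh = 2.3 * nAT + 0.1 * nGC, ds = 4.1 * nAT - 2.8 * nGC)
    })
)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# dinucleotide stacks of a sequence, folded onto the 10 canonical keys
nn_stacks <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  di <- paste0(ch[-length(ch)], ch[-1])
  folded <- ifelse(di %in% names(NN_TABLES$breslauer1986$dh), di,
                   paste0(COMPLEMENT[substring(di, 2, 2)],
                          COMPLEMENT[substring(di, 1, 1)]))
  folded
}

#' GC content of a sequence
#' @param seq non-empty DNA string over `ACGT`.
#' @return percent G+C, `100 * (#G + #C) / length`.
#' @export
gc_percent <- function(seq) {
  seq <- normalize_dna(as.character(seq))
  if (!nchar(seq)) stop("empty sequence", call. = FALSE)
  100 * nchar(gsub("[AT]", "", seq)) / nchar(seq)
}

#' 3'-terminal GC content
#'
#' GC percentage of the `window` 3'-terminal bases (default 4, so the value
#' is one of 0/25/50/75/100).
#'
#' @param seq DNA string, at least `window` nt long.
#' @param window terminal window width in nt (default 4).
#' @return percent G+C over the terminal window.
#' @export
gc3_percent <- function(seq, window = 4L) {
  seq <- normalize_dna(as.character(seq))
  if (nchar(seq) < window)
    stop("sequence shorter than the 3' window of ", window, " nt", call. = FALSE)
  gc_percent(substr(seq, nchar(seq) - window + 1L, nchar(seq)))
}

#' Nearest-neighbor melting temperature
#'
#' Two-state nearest-neighbor model: `Tm = 1000 dH / (dS + R ln CT) -
#' 273.15`, with the stack sum over the chosen parameter table, duplex
#' initiation terms, and the entropic salt correction `dS + 0.368 (N - 1)
#' ln[Na+]`.  The primer is assumed in excess over template, so `CT` is the
#' primer concentration.  Default parameter table is `breslauer1986`, which
#' together with 250 nM primer and 50 mM monovalent salt tracks the
#' temperature optima used by the primer score; `santalucia1998` (unified)
#' is available as an alternative.
#'
#' @param seq DNA string over `ACGT`, at least 8 nt.
#' @param conc_nM primer concentration in nM (default 250).
#' @param na_mM monovalent cation concentration in mM (default 50).
#' @param table `"breslauer1986"` or `"santalucia1998"`.
#' @return melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(seq, conc_nM = 250, na_mM = 50,
                                table = c("breslauer1986", "santalucia1998")) {
  table <- match.arg(table)
  seq <- normalize_dna(as.character(seq))
  if (nchar(seq) < 8L)
    stop("sequence too short for a meaningful Tm (need >= 8 nt)", call. = FALSE)
  par <- NN_TABLES[[table]]
  st <- nn_stacks(seq)
  init <- par$init(seq)
  dh <- sum(par$dh[st]) + init$dh
  ds <- sum(par$ds[st]) + init$ds
  ds <- ds + 0.368 * (nchar(seq) - 1L) * log(na_mM / 1000)
  R <- 1.987
  1000 * dh / (ds + R * log(conc_nM * 1e-9)) - 273.15
}

#' Terminal duplex stability (5' and 3' pentamer delta-G)
#'
#' Free energy of duplex formation of the `window` (default 5) terminal
#' bases at each end: the sum of the nearest-neighbor stack free energies
#' `dG = dH - T dS` at `temperature_c` (default 25), Breslauer 1986
#' parameters, no initiation term.  Values are negative
#' (duplex formation favorable); a less negative 3' value means a less
#' stable, less misprime-prone 3' end.
#'
#' @param seq DNA string, at least `window` nt.
#' @param window terminal window in nt (default 5).
#' @param temperature_c evaluation temperature in Celsius (default 25).
#' @return named numeric vector `c(dg5 = ..., dg3 = ...)` in kcal/mol.
#' @export
end_stability <- function(seq, window = 5L, temperature_c = 25) {
  seq <- normalize_dna(as.character(seq))
  if (nchar(seq) < window)
    stop("sequence shorter than the terminal window of ", window, " nt",
         call. = FALSE)
  par <- NN_TABLES$breslauer1986
  tk <- temperature_c + 273.15
  dg <- function(s) {
    st <- nn_stacks(s)
    sum(par$dh[st]) - tk * sum(par$ds[st]) / 1000
  }
  c(dg5 = dg(substr(seq, 1L, window)),
    dg3 = dg(substr(seq, nchar(seq) - window + 1L, nchar(seq))))
}

#' Count mononucleotide runs
#'
#' Number of maximal single-base runs of length at least `min_len`
#' (default 4).
#'
#' @param seq non-empty DNA string.
#' @param min_len run-length threshold (default 4).
#' @return integer count.
#' @export
count_runs <- function(seq, min_len = 4L) {
  seq <- normalize_dna(as.character(seq))
  if (!nchar(seq)) stop("empty sequence", call. = FALSE)
  r <- rle(strsplit(seq, "")[[1]])
  sum(r$lengths >= min_len)
}

#' Count tandem dinucleotide repeats
#'
#' Number of maximal tandem dinucleotide repeats with at least `min_units`
#' units (default 4, i.e. `ATATATAT` counts, `ATATAT` does not).
#'
#' @param seq non-empty DNA string.
#' @param min_units repeat-unit threshold (default 4).
#' @return integer count.
#' @export
count_repeats <- function(seq, min_units = 4L) {
  seq <- normalize_dna(as.character(seq))
  if (!nchar(seq)) stop("empty sequence", call. = FALSE)
  pat <- sprintf("([ACGT]{2})\\1{%d,}", min_units - 1L)
  length(regmatches(seq, gregexpr(pat, seq, perl = TRUE))[[1]])
}

#' Full metric panel of a primer
#'
#' @param primer primer sequence, 5' to 3'.
#' @param n_changes number of mismatches versus the template.
#' @param ... forwarded to [melting_temperature()].
#' @return list with `length_nt`, `gc_pct`, `gc3_pct`, `tm_c`, `dg5_kcal`,
#'   `dg3_kcal`, `runs`, `repeats`, `n_changes`.
#' @export
primer_metrics <- function(primer, n_changes, ...) {
  primer <- normalize_dna(as.character(primer))
  dg <- end_stability(primer)
  list(length_nt = nchar(primer),
       gc_pct = gc_percent(primer),
       gc3_pct = gc3_percent(primer),
       tm_c = melting_temperature(primer, ...),
       dg5_kcal = unname(dg[["dg5"]]),
       dg3_kcal = unname(dg[["dg3"]]),
       runs = count_runs(primer),
       repeats = count_repeats(primer),
       n_changes = as.integer(n_changes))
}
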