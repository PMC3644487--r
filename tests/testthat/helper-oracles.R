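# Independent brute-force oracles.  These deliberately re-derive every
# quantity through a different route than the package (explicit 16-entry
# dinucleotide tables, position-by-position substring scans, exhaustive
# enumeration over the genetic code) so that agreement is informative.

ORACLE_DH <- c(AA = -9.1, AC = -6.5, AG = -7.8, AT = -8.6,
               CA = -5.8, CC = -11.0, CG = -11.9, CT = -7.8,
               GA = -5.6, GC = -11.1, GG = -11.0, GT = -6.5,
               TA = -6.0, TC = -5.6, TG = -5.8, TT = -9.1)
ORACLE_DS <- c(AA = -24.0, AC = -17.3, AG = -20.8, AT = -23.9,
               CA = -12.9, CC = -26.6, CG = -27.8, CT = -20.8,
               GA = -13.5, GC = -26.7, GG = -26.6, GT = -17.3,
               TA = -16.9, TC = -13.5, TG = -12.9, TT = -24.0)

oracle_tm <- function(seq, conc_nM = 250, na_mM = 50) {
  dh <- 0; ds <- 0
  for (i in seq_len(nchar(seq) - 1L)) {
    di <- substr(seq, i, i + 1L)
    dh <- dh + ORACLE_DH[[di]]
    ds <- ds + ORACLE_DS[[di]]
  }
  ds <- ds + if (grepl("G|C", seq)) -16.8 else -20.1
  ds <- ds + 0.368 * (nchar(seq) - 1L) * log(na_mM / 1000)
  1000 * dh / (ds + 1.987 * log(conc_nM * 1e-9)) - 273.15
}

oracle_dg <- function(pentamer, temperature_c = 25) {
  dh <- 0; ds <- 0
  for (i in seq_len(nchar(pentamer) - 1L)) {
    di <- substr(pentamer, i, i + 1L)
    dh <- dh + ORACLE_DH[[di]]
    ds <- ds + ORACLE_DS[[di]]
  }
  dh - (temperature_c + 273.15) * ds / 1000
}

# IUPAC expansion by per-symbol cartesian growth over Biostrings' code map
oracle_expand <- function(pattern) {
  sets <- lapply(strsplit(pattern, "")[[1]],
                 function(s) strsplit(Biostrings::IUPAC_CODE_MAP[[s]], "")[[1]])
  Reduce(function(acc, s) as.vector(outer(acc, s, paste0)), sets, "")
}

oracle_revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# all concrete strings (site realizations) that count as a hit for the
# enzyme, per strand
oracle_realsets <- function(pattern) {
  fwd <- oracle_expand(pattern)
  rc_pat <- oracle_revcomp(pattern)
  list(`+` = fwd,
       `-` = if (identical(sort(fwd), sort(oracle_expand(rc_pat))))
         character(0) else oracle_expand(rc_pat))
}

# every synonymous re-assignment of all complete codons of `bases`
# (character vector of full-length strings, wild type included)
oracle_assignments <- function(bases) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  sets <- lapply(codons_of(bases), function(cd) sort(by_aa[[gc[[cd]]]]))
  grid <- expand.grid(sets, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  do.call(paste0, grid)
}

# logical vector: does each string contain a site of `pattern` on either
# strand?  position-by-position substring membership scan
oracle_has_site <- function(strings, pattern) {
  L <- nchar(pattern)
  rs <- oracle_realsets(pattern)
  realset <- c(rs$`+`, rs$`-`)
  hit <- rep(FALSE, length(strings))
  n <- nchar(strings[[1]])
  for (p in seq_len(n - L + 1L))
    hit <- hit | substr(strings, p, p + L - 1L) %in% realset
  hit
}

oracle_hamming <- function(strings, ref) {
  refc <- strsplit(ref, "")[[1]]
  vapply(strsplit(strings, ""), function(ch) sum(ch != refc), 1L)
}

# minimum Hamming distance over all synonymous assignments that leave no
# site of `pattern` anywhere; Inf when impossible
oracle_removal_min <- function(bases, pattern) {
  strings <- oracle_assignments(bases)
  valid <- !oracle_has_site(strings, pattern)
  if (!any(valid)) return(Inf)
  min(oracle_hamming(strings[valid], bases))
}

# all (start, strand) at which some synonymous assignment realizes a site
oracle_insertion_sites <- function(bases, pattern) {
  strings <- oracle_assignments(bases)
  L <- nchar(pattern)
  rs <- oracle_realsets(pattern)
  out <- character(0)
  for (p in seq_len(nchar(bases) - L + 1L)) {
    sub <- substr(strings, p, p + L - 1L)
    if (any(sub %in% rs$`+`)) out <- c(out, paste(p, "+"))
    if (length(rs$`-`) && any(sub %in% rs$`-`)) out <- c(out, paste(p, "-"))
  }
  sort(out)
}
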