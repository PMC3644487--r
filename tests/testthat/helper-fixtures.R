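# Synthetic potassium-channel pore-region fixture, reconstructed in code
# from the published mutagenic primer sequences (the wild type is the
# primer region with the three mutant bases reverted).  The reconstruction
# covers only the primer-spanned region, which places an in-frame TAA one
# codon upstream of the 9-residue window; it lies outside every window
# used here.  Residues 3-11 are T T V G Y G D L H (the TTVGYGD pore
# signature); the double Gly->Ala mutation sits at window codons 4 and 6.
akt1_region <- function() {
  list(
    cds = as_cds("CTCTAAACCACTGTTGGATACGGTGATCTGCATCCTGTG"),
    mutations = c("G6A", "G8A")
  )
}

# The published primer table: sequences plus the printed, recomputable
# columns (GC%, 3'GC%, length, NdeI position, Tm, terminal delta-G).
table1_primers <- function() {
  data.frame(
    no = c(1:5, 22:26),
    orientation = rep(c("forward", "reverse"), each = 5),
    primer = c(
      "ACCACTGTTGCATATGCTGATCTGCATCC",
      "ACCACTGTTGCATATGCTGATCTGCATCCT",
      "ACCACTGTTGCATATGCTGATCTGCATCCTG",
      "ACCACTGTTGCATATGCTGATCTGCATCCTGT",
      "ACCACTGTTGCATATGCTGATCTGCATCCTGTG",
      "GCAGATCAGCATATGCAACAGTGGTTAGAGTAG",
      "TGCAGATCAGCATATGCAACAGTGGTTAGAGTAG",
      "ATGCAGATCAGCATATGCAACAGTGGTTAGAGTAG",
      "GCAGATCAGCATATGCAACAGTGGTTAGAGTA",
      "TGCAGATCAGCATATGCAACAGTGGTTAGAGTA"),
    nt = c(29, 30, 31, 32, 33, 33, 34, 35, 32, 33),
    gc = c(48.28, 46.67, 48.39, 46.88, 48.48, 45.45, 44.12, 42.86, 43.75, 42.42),
    gc3 = c(50, 50, 75, 50, 50, 50, 50, 50, 25, 25),
    tm = c(72.16, 72.75, 74.64, 75.06, 76.82, 70.80, 72.58, 72.64, 70.20, 72.04),
    dg3 = c(-8.07, -7.72, -8.20, -7.96, -6.85, -5.50, -5.50, -5.50, -5.48, -5.48),
    dg5 = c(-7.71, -7.71, -7.71, -7.71, -7.71, -8.27, -8.65, -8.52, -8.27, -8.65),
    ndei_at = c(11, 11, 11, 11, 11, 10, 11, 12, 10, 11),
    stringsAsFactors = FALSE)
}

ndei_catalog <- function() parse_enzyme_list("NdeI CATATG")

# window whose codons may all be re-assigned synonymously: a single
# same-residue "mutation" at codon 1 makes build_window applicable without
# changing the target translation
identity_window <- function(bases) {
  res1 <- substr(translate_cds(bases), 1, 1)
  build_window(bases, list(mutation_spec(1, res1, res1)),
               flank_codons = nchar(bases) %/% 3L)
}

wt_candidate <- function(window) {
  cands <- enumerate_candidates(window)
  cands[[which(vapply(cands, `[[`, "", "bases") == window$wt_bases)]]
}
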