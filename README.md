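# sdmprimer

Site-directed mutagenesis (SDM) primers with **silent restriction-site
identifiers**.

After a QuikChange-style SDM reaction, DpnI digestion of the template is
incomplete and a fair share of recovered clones are un-mutated wild type —
distinguishable only by sequencing.  `sdmprimer` designs the mutagenic
primer pair so that it additionally introduces (or removes) a restriction
site through *silent* mutations: mutant clones then reveal themselves in a
plain diagnostic digest.  It is aimed at molecular biologists doing
structure–function work who would otherwise hand-craft these primers.

## What it computes

For an in-frame CDS and substitutions like `G255A`:

1. enumerates every codon realization of the requested substitutions
   (∏ᵢ |synonymous codons of target residue i| candidates);
2. searches each candidate window for restriction sites
   (IUPAC-degenerate patterns, both strands, overlaps included), silently
   **removes** sites with the minimum number of nucleotide changes (ties →
   GC closest to 50%), and silently **inserts** new sites by sliding every
   concrete realization of each recognition pattern over the window and
   completing partially covered codons so the translation is unchanged;
3. ranks candidates by (nucleotide changes, |GC − 50|) and designs
   partially overlapping primer pairs around the chosen one (fixed 10-nt
   wild-type 5′ anchor, 3′ ends 12–16 nt past the last change);
4. scores every primer on seven weighted parameters
   (weights 2× GC, 3× mismatches, 1× Tm, 3′-GC, 3′ ΔG, 5′ ΔG,
   runs/repeats; 100 points each at optimum):

   *score* = Σᵢ wᵢ·rawᵢ ≤ 1000 points ≡ 100 %,

   with optima Tm 66–74 °C, GC 40–60 %, 3′-GC(4 nt) = 50 %,
   3′ ΔG −5.62…−4.74 kcal/mol, 5′ ΔG −13.50…−12.62 kcal/mol, no
   runs/repeats, and a free mismatch budget of 1–2 changes (3–4: −50,
   5–6: −80, ≥7: 0 raw points).  Tm is nearest-neighbor
   (Breslauer 1986 stacks by default, SantaLucia 1998 unified optional;
   250 nM primer, 50 mM Na⁺); terminal ΔG is the Breslauer stack sum of
   each terminal pentamer at 25 °C.  See the vignette
   (`vignettes/silent-site-primer-design.Rmd`) for why the score and the
   parameter table must share the Breslauer convention.

## Worked example

The potassium-channel pore-region fixture (TTVGYGD signature) with the
double Gly→Ala mutation, restricted to NdeI:

```r
library(sdmprimer)
cds <- as_cds("CTCTAAACCACTGTTGGATACGGTGATCTGCATCCTGTG")
run <- run_pipeline(cds, c("G6A", "G8A"), select = "NdeI")
run
```

The silent-insertion step finds that choosing `GCA` for the first alanine
and recoding the flanking tyrosine `TAC→TAT` realizes `CATATG` (NdeI)
across the mutated codons — three nucleotide changes in total, two of
which are the mutation itself.  The selected window is
`ACCACTGTTGCATATGCTGATCTGCAT` (`TTVAYADLH`) and the forward primer series
begins:

```
No. Orientation Primer (5'-3')                    Score [%] nt changes Tm [C] nt GC%   3'dG  5'dG  Runs Rep. RE sites 3'GC% Comments
1   forward     ACCACTGTTGCATATGCTGATCTGCATCC     66        3          75.06  29 48.28 -8.07 -7.71 0    0    1        50    RE sites: NdeI @11
2   forward     ACCACTGTTGCATATGCTGATCTGCATCCT    66        3          75.33  30 46.67 -7.72 -7.71 0    0    1        50    RE sites: NdeI @11
3   forward     ACCACTGTTGCATATGCTGATCTGCATCCTG   58        3          76.77  31 48.39 -8.20 -7.71 0    0    1        75    RE sites: NdeI @11
```

Read: primer 1 is a 29-mer with 3 template mismatches, 48.28 % GC, a
suitably unstable 3′ pentamer (−8.07 kcal/mol), no runs or repeats, and
an NdeI site starting at primer base 11 — cutting only mutant plasmids.
`write_report(run, "primers.tsv")` emits the 15-column tab-separated
table.  A thin command-line front end lives at `inst/cli/sdm_design.R`:

```sh
Rscript inst/cli/sdm_design.R --seq gene.fa --mut G255A,G257A --select NdeI -o primers.tsv
```

Custom enzyme lists are plain text, one `NAME SITE` pair per line (tab or
space delimited, IUPAC codes allowed), via `--enzymes` or
`parse_enzyme_list()`.

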