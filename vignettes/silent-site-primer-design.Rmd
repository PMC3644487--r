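---
title: "Designing SDM primers with silent restriction-site identifiers"
author: "sdmprimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing SDM primers with silent restriction-site identifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmprimer)
```

## The problem

QuikChange-style site-directed mutagenesis (SDM) amplifies a whole plasmid
with a pair of mutagenic primers and then digests the methylated template
with DpnI.  The digestion is unreliable: a substantial fraction of
recovered clones are un-mutated wild type, and the only way to tell them
apart is sequencing.  A long-standing trick is to let the mutagenic primer
carry *additional silent* substitutions that create (or destroy) a
restriction-endonuclease recognition site, so that a plain diagnostic
digest separates mutant from wild-type clones before anything is sent for
sequencing.  Designing such primers by hand means juggling codon
degeneracy, recognition-site degeneracy, reading frame and primer
thermodynamics at the same time; `sdmprimer` automates the whole search
and ranks every resulting oligonucleotide.

## The procedure

Given an in-frame coding sequence and one or more amino-acid substitution
requests (`G255A` style, optionally with a forced codon), the pipeline
runs five stages.

1. **Window extraction.** All mutated codons plus a symmetric flank
   (default 3 codons per side, `flank_codons`) are excised as the
   *mutation window*.  Two substitutions two codons apart give the
   canonical 9-residue window.  The flank default balances two pressures:
   enough context for a recognition site to straddle the mutated codons,
   against a combinatorial search space that grows with every extra
   codon.
2. **Candidate enumeration.** Every codon-level realization of the
   requested substitutions is generated — the Cartesian product of the
   synonymous-codon sets of the target residues (two serine substitutions
   give 6 × 6 = 36 candidates).  Unmutated codons keep their wild-type
   bases.  A cap (default 10,000) guards against pathological multi-site
   requests; forcing codons collapses factors of the product.
3. **Silent site engineering.**  For each candidate the enabled
   recognition patterns (IUPAC-degenerate, searched on both strands, with
   overlaps) are located.
   * *Removal*: the codons spanned by a site are re-assigned
     synonymously so that no site of that enzyme remains; the edit with
     the minimum Hamming distance wins, ties broken by GC content closest
     to 50%, then lexicographically.  Overlapping sites are eliminated
     jointly.  If no synonymous re-assignment destroys the site (e.g. a
     site forced by Met/Trp codons) the result is an explicit
     "unremovable" status.
   * *Insertion*: every concrete realization of a recognition pattern is
     slid over every window offset; codons partially covered by the site
     are completed with every base combination consistent with the
     (mutated) residue string.  A 6-nt site entering mid-codon splits as
     `NN/NNN/N`, giving 64 codon-aligned realizations to scan
     (`site_frame_realizations()`).  Every emitted variant preserves the
     translation exactly.  Edits that would spawn a second new site of
     any enabled enzyme are discarded by default (`unique_only`), because
     the identifier is only useful if it is unique.
4. **Pre-evaluation.**  The pooled candidates (plain substitutions,
   removal variants, insertion variants) are de-duplicated, annotated
   with sites gained/lost relative to the wild-type window, and sorted by
   (number of changes, |GC − 50|, base string).  The automatic selection
   takes the *first row that carries an identifier* — a plain "fewest
   changes" rule would always pick the raw substitution, which by
   construction has minimal Hamming distance and no identifier.  Any row
   can be chosen explicitly instead.
5. **Primer design and scoring.**  Partially overlapping primer pairs are
   enumerated around the selected window: a fixed wild-type 5' anchor
   (default 10 nt) upstream of the first changed base, 3' ends extending
   12–16 nt past the last change, length bounds 25–45 nt.  The partial
   overlap favors primer–template annealing over primer–primer annealing.
   Each primer is scored as below.

## The score

Seven parameters, each worth 100 raw points at its optimum, weighted
2× (GC), 3× (mismatches) and 1× (the rest) for a maximum of
`10 × 100 = 1000` points ≡ 100%:

| parameter  | optimum              | schedule outside the optimum      |
|------------|----------------------|-----------------------------------|
| Tm         | 66–74 °C             | −10 points per started °C         |
| GC         | 40–60 %              | −5 points per started % point     |
| 3'-GC (4 nt) | 50 %               | −50 points per 25-point step      |
| 3' ΔG (pentamer) | −5.62…−4.74 kcal/mol | −15 points per started 0.5 kcal/mol |
| 5' ΔG (pentamer) | −13.50…−12.62 kcal/mol | −15 points per started 0.5 kcal/mol |
| runs + repeats | 0                | −50 points each                   |
| mismatches | 1–2                  | 3–4: −50; 5–6: −80; ≥7: 0 points  |

The optimal bands encode SDM-specific craft: an *unstable* 3' terminus
discourages mispriming, a *stable* 5' terminus anchors the primer, and a
mismatch budget of one or two silent changes on top of the mutation is
free because SDM primers must mismatch by design.  The mismatch tier
boundaries leave exactly seven changes ambiguous between the "−80" and
"zero" tiers; seven is scored 0 here, reading the terminal tier as
"seven or more", and the alternative (20 points) is one configuration
entry away.  Zero mismatches score 100 with a logged note, since an SDM
primer over its own mutation window cannot have zero changes.  The
deduction schedules for the continuous parameters are stepwise and
deliberately explicit in `scoring_config()`; they are a design choice of
this package, user-recalibratable, and the published percentage column of
the reference design cannot be inverted uniquely to recover the original
schedule — so no claim of bit-identical scores is made.

## Thermodynamic model

Melting temperature uses the two-state nearest-neighbor model

\[ T_m = \frac{1000\,\Delta H}{\Delta S + 0.368\,(N-1)\ln[\mathrm{Na^+}] + R \ln C_T} - 273.15 \]

with the primer assumed in excess over template
(\(C_T\) = primer concentration, default 250 nM; monovalent salt default
50 mM; no self-complementarity correction).  The default stack parameter
table is **Breslauer et al. (1986, PNAS 83:3746)**; the unified set of
**Allawi & SantaLucia (1997) / SantaLucia (1998)** ships as a selectable
alternative (`table = "santalucia1998"`).  Breslauer is the default
because the score's own terminal-stability optima identify it: terminal
ΔG is computed as the stack sum ΔH − (298.15 K)·ΔS over the four stacks
of each terminal pentamer, and on that convention the stated optimal
bands (−4.74…−5.62 and −13.50…−12.62 kcal/mol) are exactly
Breslauer-scale pentamer values — the unified table tops out near
−9 kcal/mol and could never reach the 5' band.  The score and the model
therefore have to share the parameter set to be meaningful.  Runs
(mononucleotide, ≥ 4 nt) and tandem dinucleotide repeats (≥ 4 units)
stand in for secondary-structure liability; no hairpin/dimer dynamic
programming is attempted.

## Coordinates and conventions

* Restriction-site positions are 1-based at the first base of the
  recognition sequence, within whichever sequence was searched (so a
  primer's annotation `NdeI @11` means primer bases 11–16).
* Reverse primers are reported 5'→3' on the antisense strand, with site
  positions indexed in their own sequence.
* Non-palindromic recognition sequences are searched and inserted in both
  orientations; minus-strand hits are flagged `(-)`.  Degenerate patterns
  with more than 256 realizations are skipped for insertion (with a
  warning) to bound the search.
* The report is tab-separated, 15 columns, ASCII minus signs, scores and
  3'-GC as integers, Tm/GC/ΔG with two decimals; identical inputs give
  byte-identical files.

## Synthetic data

`generate_fixture(seed, n_codons, n_mutations)` draws codons uniformly
from the 61 sense codons and places substitution requests with at least
three codons of flank.  This emulates the *combinatorial* structure of
real design problems (degeneracy, frame, site placement) but none of the
compositional biases of real genes — codon-usage bias, GC gradients,
repetitive stretches.  Tests passing on these fixtures therefore validate
the search and bookkeeping, not performance on any particular genome.
The packaged worked example is a reconstruction of the *Arabidopsis*
AKT1 potassium-channel pore region (the TTVGYGD signature), rebuilt in
code from its published mutagenic primers; it is synthetic in the sense
that only the primer-spanned region is faithful.

The correctness of the silent-engineering core is established against
exhaustive oracles: on windows of up to 6 codons (200 seeded fixtures),
brute-force enumeration of *all* synonymous codon assignments confirms
that removal attains the minimum Hamming distance that destroys the
site, and that insertion reports a site at a position exactly when some
assignment realizes one there.  Window sizes are kept at 4–6 codons so
the oracle space (up to ~5,000 assignments) stays exhaustively
enumerable.

## Known limitations

* The Tm scale is model-dependent; against an independent published
  design it tracks within ~3 °C, and no exact reproduction of any
  particular tool's Tm column is claimed.
* Uniqueness of the introduced site is enforced only within the mutation
  window; occurrences elsewhere in the insert or vector should be checked
  against the full construct (the whole-sequence site count of
  `find_sites()` on the full CDS is the tool for that).
* Substitutions only — no insertions or deletions.
* Silent changes can still matter in vivo (codon usage, mRNA structure);
  forced codons exist precisely so the user can impose a preferred codon.
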