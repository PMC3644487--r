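akt1_run_parts <- function() {
  fx <- akt1_region()
  w <- build_window(fx$cds, fx$mutations)
  pool <- survey_candidates(w, ndei_catalog())
  tab <- preselect(pool)
  sel <- tab[nzchar(tab$sites_gained), ][1, ]
  list(fx = fx, w = w, sel = sel)
}

test_that("template mismatch counting is strand-symmetric", {
  cds <- as_cds("ATGGCAGCTTGCAAGGCGTTGGAAGAGTAA")
  # identical primer: zero changes
  expect_equal(count_nt_changes(substr(cds, 4, 18), cds, 4, "forward"), 0)
  # constructed 3-substitution primer
  p <- "GCTGCTTGCATGGAG"   # vs GCAGCTTGCAAGGCG at 4..18: pos 3, 11, 14
  expect_equal(count_nt_changes(p, cds, 4, "forward"), 3)
  # the same mutated duplex counted from the antisense strand
  rc <- revcomp(p)
  rc_start <- nchar(cds) - 18 + 1
  expect_equal(count_nt_changes(rc, cds, rc_start, "reverse"), 3)
  expect_error(count_nt_changes("ACGTACGTACGT", cds, 25, "forward"),
               "overhangs")
})

test_that("the pore-region fixture yields the published forward series", {
  parts <- akt1_run_parts()
  rep <- design_primer_pairs(parts$fx$cds, parts$sel$bases, parts$w,
                             catalog = ndei_catalog())
  fwd <- rep[rep$orientation == "forward", ]
  rev <- rep[rep$orientation == "reverse", ]
  expect_equal(fwd$nt, 29:33)
  expect_equal(nrow(rev), 5)
  expect_true(all(startsWith(fwd$primer, "ACCACTGTTGCATATG")))
  expect_equal(fwd$primer[fwd$nt == 29], "ACCACTGTTGCATATGCTGATCTGCATCC")
  expect_equal(fwd$comments[fwd$nt == 29], "RE sites: NdeI @11")
  expect_equal(fwd$nt_changes, rep_len(3L, 5))
  # shorter forward primers are prefixes of longer ones (fixed 5' anchor)
  for (i in 1:4)
    expect_true(startsWith(fwd$primer[i + 1], fwd$primer[i]))
  # primer counts equal the 3' extension range
  prm <- design_params()
  expect_equal(nrow(fwd), prm$three_max - prm$three_min + 1L)
})

test_that("annotated restriction sites round-trip through find_sites", {
  parts <- akt1_run_parts()
  rep <- design_primer_pairs(parts$fx$cds, parts$sel$bases, parts$w,
                             catalog = ndei_catalog())
  for (i in seq_len(nrow(rep))) {
    found <- find_sites(rep$primer[i], ndei_catalog())
    expect_equal(nrow(found), rep$re_sites[i])
    if (nrow(found))
      expect_equal(rep$comments[i],
                   paste0("RE sites: ", sdmprimer:::fmt_sites(found)))
  }
  # every primer covers all changed bases and the mutated core translates
  # to the target residues
  expect_true(all(grepl("CATATGCT", rep$primer[rep$orientation == "forward"])))
  expect_true(all(grepl(revcomp("GCATATGCT"),
                        rep$primer[rep$orientation == "reverse"])))
})

test_that("degenerate extension ranges give exactly one primer pair", {
  parts <- akt1_run_parts()
  rep <- design_primer_pairs(parts$fx$cds, parts$sel$bases, parts$w,
                             params = design_params(three_min = 12,
                                                    three_max = 12),
                             catalog = ndei_catalog())
  expect_equal(table(rep$orientation)[["forward"]], 1)
  expect_equal(table(rep$orientation)[["reverse"]], 1)
})

test_that("mutations too close to a template end are refused with the shortfall", {
  parts <- akt1_run_parts()
  short <- substr(parts$fx$cds, 1, 36)  # drop the last codon
  w <- build_window(short, parts$fx$mutations)
  expect_error(
    design_primer_pairs(short, parts$sel$bases, w, catalog = ndei_catalog()),
    "3' end.*needs [0-9]+ nt more")
  expect_error(
    design_primer_pairs(parts$fx$cds, parts$sel$bases, parts$w,
                        params = design_params(five_anchor = 25),
                        catalog = ndei_catalog()),
    "5' end")
})
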