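test_that("site search uses 1-based starts and reports overlaps and strands", {
  nde <- ndei_catalog()
  hits <- find_sites("ACCACTGTTGCATATGCTGATCTGCATCC", nde)
  expect_equal(hits$start, 11L)
  expect_equal(hits$strand, "+")
  hits2 <- find_sites("GCAGATCAGCATATGCAACAGTGGTTAGAGTAG", nde)
  expect_equal(hits2$start, 10L)
  expect_equal(nrow(find_sites("AAAA", nde)), 0)
  # overlapping matches are all reported
  ata <- parse_enzyme_list("Hypo ATAT")
  expect_equal(find_sites("ATATAT", ata)$start, c(1L, 3L))
  # non-palindromic site found on the minus strand
  bsa <- parse_enzyme_list("BsaI GGTCTC")
  minus <- find_sites(revcomp("AAGGTCTCAA"), bsa)
  expect_equal(minus$strand, "-")
  expect_equal(minus$site, revcomp("GGTCTC"))
  # degenerate pattern (HinfI GANTC)
  hin <- parse_enzyme_list("HinfI GANTC")
  expect_equal(find_sites("GGATTCGACTC", hin)$start, c(2L, 7L))
})

test_that("site search agrees with Biostrings matchPattern on random input", {
  set.seed(99)
  cat <- select_enzymes(default_catalog(),
                        c("NdeI", "EcoRI", "TaqI", "HinfI", "StyI", "BsaI"))
  enz <- enabled_enzymes(cat)
  for (i in 1:15) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
    mine <- find_sites(s, cat)
    for (j in seq_len(nrow(enz))) {
      ref_fwd <- BiocGenerics::start(Biostrings::matchPattern(
        Biostrings::DNAString(enz$recognition[[j]]), Biostrings::DNAString(s),
        fixed = "subject"))
      got <- mine[mine$enzyme == enz$name[[j]] & mine$strand == "+", "start"]
      expect_equal(sort(got), sort(ref_fwd))
    }
  }
})

test_that("silent removal finds the minimal edit and flags unremovable sites", {
  # Glu-Phe window carrying an EcoRI site: one change suffices
  eco <- parse_enzyme_list("EcoRI GAATTC")
  w <- identity_window("GAATTC")
  cand <- wt_candidate(w)
  res <- remove_sites_silently(w, cand, catalog = eco)
  expect_equal(res$status, "ok")
  expect_equal(res$edit$n_changes, 1L)
  expect_equal(translate_cds(res$candidate$bases), "EF")
  expect_equal(nrow(find_sites(res$candidate$bases, eco)), 0)
  expect_equal(res$edit$n_changes, oracle_removal_min("GAATTC", "GAATTC"))
  # nothing to remove: identity
  res0 <- remove_sites_silently(w, cand, catalog = ndei_catalog())
  expect_equal(res0$status, "no_sites")
  expect_identical(res0$candidate$bases, cand$bases)
  # Met-Trp window: both codons non-degenerate, site cannot be destroyed
  hypo <- parse_enzyme_list("Hypo ATGTGG")
  w2 <- identity_window("ATGTGG")
  res2 <- remove_sites_silently(w2, wt_candidate(w2), catalog = hypo)
  expect_equal(res2$status, "unremovable")
})

test_that("frame-split realization enumeration has the expected cardinality", {
  expect_length(site_frame_realizations("CATATG", 1), 64)  # NN/NNN/N split
  expect_length(site_frame_realizations("CATATG", 2), 64)
  expect_length(site_frame_realizations("CATATG", 0), 1)   # in-frame 6-mer
  expect_length(site_frame_realizations("GANTC", 0), 16)   # 4 x N x flank
  # every realization contains the site at the stated offset
  expect_true(all(substr(site_frame_realizations("CATATG", 1), 2, 7) == "CATATG"))
})

test_that("silent insertion realizes sites in place, translation intact", {
  # His-Met already encodes CATATG: zero additional changes
  w <- identity_window("CATATG")
  got <- insert_sites_silently(w, wt_candidate(w), ndei_catalog())
  bases <- vapply(got, function(x) x$candidate$bases, "")
  expect_true("CATATG" %in% bases)
  self <- got[[which(bases == "CATATG")]]
  expect_equal(self$site$start, 1L)
  expect_equal(self$candidate$n_changes, 0L)
  # the pore-region double mutant gains NdeI across Ala-Tyr-Ala
  fx <- akt1_region()
  ww <- build_window(fx$cds, fx$mutations)
  cands <- enumerate_candidates(ww)
  ins <- unlist(lapply(cands, function(cand)
    insert_sites_silently(ww, cand, ndei_catalog())), recursive = FALSE)
  ibase <- vapply(ins, function(x) x$candidate$bases, "")
  hit <- ins[[match("ACCACTGTTGCATATGCTGATCTGCAT", ibase)]]
  expect_equal(hit$site$enzyme, "NdeI")
  expect_equal(hit$site$start, 11L)
  expect_equal(hit$candidate$residues, "TTVAYADLH")
  # every emitted site is re-verifiable on the output string
  for (x in ins) {
    found <- find_sites(x$candidate$bases, ndei_catalog())
    expect_true(any(found$start == x$site$start & found$strand == x$site$strand))
    expect_equal(x$candidate$residues, "TTVAYADLH")
  }
})

test_that("insertion respects forced codons", {
  fx <- akt1_region()
  # forcing GCG at codon 6 blocks the GCA needed for the NdeI overlap
  wf <- build_window(fx$cds, c("G6A=GCG", "G8A"))
  cands <- enumerate_candidates(wf)
  ins <- unlist(lapply(cands, function(cand)
    insert_sites_silently(wf, cand, ndei_catalog())), recursive = FALSE)
  expect_length(ins, 0)
})

test_that("the uniqueness filter drops edits that spawn extra sites", {
  # every BamHI insertion (GGATCC) necessarily realizes BstYI (RGATCY) at
  # the same spot, so with both enzymes enabled BamHI is never offered;
  # with the filter off it is
  cat2 <- parse_enzyme_list(c("BamHI GGATCC", "BstYI RGATCY"))
  w <- identity_window("GGAAGCCTGCAT")   # G S L H
  cand <- wt_candidate(w)
  strict <- insert_sites_silently(w, cand, cat2, unique_only = TRUE)
  loose <- insert_sites_silently(w, cand, cat2, unique_only = FALSE)
  strict_enz <- vapply(strict, function(x) x$site$enzyme, "")
  loose_enz <- vapply(loose, function(x) x$site$enzyme, "")
  expect_false("BamHI" %in% strict_enz)
  expect_true("BamHI" %in% loose_enz)
})

test_that("preselect sorts deterministically by changes, GC, then bases", {
  fx <- akt1_region()
  w <- build_window(fx$cds, fx$mutations)
  pool <- survey_candidates(w, ndei_catalog())
  tab <- preselect(pool)
  expect_true(all(diff(tab$n_changes) >= 0))
  # comparator oracle: explicit re-sort of the emitted rows
  ord <- order(tab$n_changes, abs(tab$gc - 50), tab$bases)
  expect_equal(ord, seq_len(nrow(tab)))
  expect_error(preselect(list()), "no candidate")
  # single candidate in, single row out
  single <- preselect(pool[1])
  expect_equal(nrow(single), 1)
})

test_that("silent edits never change the translation (randomized)", {
  set.seed(1234)
  enzymes <- c("CATATG", "GAATTC", "GANTC", "TCGA")
  for (i in 1:25) {
    fx <- generate_fixture(sample.int(1e6, 1), 12, 1)
    w <- build_window(fx$cds, fx$specs)
    cand <- enumerate_candidates(w)[[1]]
    pat <- sample(enzymes, 1)
    cat1 <- parse_enzyme_list(paste("Enz", pat))
    res <- remove_sites_silently(w, cand, catalog = cat1)
    expect_equal(translate_cds(res$candidate$bases), translate_cds(cand$bases))
    ins <- insert_sites_silently(w, cand, cat1)
    for (x in ins)
      expect_equal(translate_cds(x$candidate$bases), translate_cds(cand$bases))
  }
})
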