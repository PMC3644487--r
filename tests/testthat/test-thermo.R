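random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

test_that("GC content and terminal GC window", {
  expect_equal(round(gc_percent("ACCACTGTTGCATATGCTGATCTGCATCC"), 2), 48.28)
  expect_equal(gc_percent("GGCC"), 100)
  expect_equal(round(gc_percent("ATGCAGATCAGCATATGCAACAGTGGTTAGAGTAG"), 2), 42.86)
  expect_error(gc_percent(""), "single character string|empty")
  expect_equal(gc3_percent("ACCACTGTTGCATATGCTGATCTGCATCCTG"), 75)  # ...CCTG
  expect_equal(gc3_percent("GCAGATCAGCATATGCAACAGTGGTTAGAGTA"), 25) # ...AGTA
  expect_equal(gc3_percent("GGGGATAT"), 0)
  expect_error(gc3_percent("ACG"), "shorter than")
})

test_that("melting temperature matches an independent summation oracle", {
  # frozen reference values from an independent implementation of the same
  # model (Breslauer stacks, 250 nM primer, 50 mM Na+, entropic salt term)
  frozen <- c(ACCACTGTTGCATATGCTGATCTGCATCC = 75.057115,
              GCAGATCAGCATATGCAACAGTGGTTAGAGTAG = 72.517384,
              ATGGCAGGTACCTTGAAC = 58.751414,
              GCGCGCATTATTGCGCGC = 78.370979,
              AAGGTTCCAACCGGTTGGAACCTT = 73.894827)
  for (s in names(frozen))
    expect_equal(melting_temperature(s), frozen[[s]], tolerance = 1e-6)
  set.seed(21)
  for (i in 1:25) {
    s <- random_seq(sample(8:45, 1))
    expect_equal(melting_temperature(s), oracle_tm(s), tolerance = 1e-9)
    # duplex symmetry
    expect_equal(melting_temperature(s), melting_temperature(revcomp(s)))
  }
  expect_error(melting_temperature("ACGT"), "too short")
})

test_that("Tm rises when GC pairs are appended", {
  set.seed(5)
  for (i in 1:10) {
    s <- random_seq(20)
    expect_gt(melting_temperature(paste0(s, "GC")), melting_temperature(s))
  }
})

test_that("terminal delta-G matches the oracle and strand identities", {
  set.seed(31)
  for (i in 1:25) {
    s <- random_seq(sample(5:40, 1))
    dg <- end_stability(s)
    expect_equal(dg[["dg5"]], oracle_dg(substr(s, 1, 5)), tolerance = 1e-9)
    expect_equal(dg[["dg3"]],
                 oracle_dg(substr(s, nchar(s) - 4, nchar(s))), tolerance = 1e-9)
    # the two terminal duplexes swap under reverse complement
    rc <- end_stability(revcomp(s))
    expect_equal(dg[["dg3"]], rc[["dg5"]])
    expect_equal(dg[["dg5"]], rc[["dg3"]])
    expect_lt(dg[["dg5"]], 0)
    expect_lt(dg[["dg3"]], 0)
  }
  # AT-only pentamer is less stable (less negative) than GC-only
  expect_gt(end_stability("ATATA")[["dg3"]], end_stability("GCGCG")[["dg3"]])
  expect_error(end_stability("ACGT"), "shorter than")
})

test_that("runs and repeats are counted at the 4-unit thresholds", {
  expect_equal(count_runs("ACCACTGTTGCATATGCTGATCTGCATCC"), 0)
  expect_equal(count_runs("AAAAT"), 1)
  expect_equal(count_runs("AAATTT"), 0)
  expect_equal(count_runs("GAAAAACCCCG"), 2)
  expect_equal(count_runs("AAATTT", min_len = 3), 2)
  expect_equal(count_repeats("GCAGATCAGCATATGCAACAGTGGTTAGAGTAG"), 0)
  expect_equal(count_repeats("ATATATAT"), 1)
  expect_equal(count_repeats("ATATAT"), 0)
  expect_equal(count_repeats("GACACACACAG"), 1)
})

test_that("the metric panel is self-consistent", {
  p <- "ACCACTGTTGCATATGCTGATCTGCATCC"
  m <- primer_metrics(p, n_changes = 3)
  expect_equal(m$length_nt, nchar(p))
  expect_equal(m$gc_pct, gc_percent(p))
  expect_equal(m$gc3_pct, gc3_percent(p))
  expect_equal(m$tm_c, melting_temperature(p))
  expect_equal(m$dg3_kcal, end_stability(p)[["dg3"]])
  expect_equal(m$n_changes, 3L)
})
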