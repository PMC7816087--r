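test_that("minimal_variant reproduces the documented single-site edits", {
  # Pro-Gly: one silent change creates the XmaI site
  expect_identical(minimal_variant("CCTGGG", "CCCGGG", 1, "forward"),
                   list(variant = "CCCGGG", n_subs = 1L, substitutions = 3L))
  # Asp-Leu-Arg -> AflII site with one substitution outside the motif
  expect_identical(minimal_variant("GATCTTCGT", "CTTAAG", 3, "forward"),
                   list(variant = "GACTTAAGA", n_subs = 5L,
                        substitutions = c(3L, 4L, 6L, 7L, 9L)))
  # already present: zero substitutions
  expect_identical(minimal_variant("CCCGGG", "CCCGGG", 1, "forward"),
                   list(variant = "CCCGGG", n_subs = 0L,
                        substitutions = integer(0)))
  # infeasible placement returns NULL
  expect_null(minimal_variant("TGGTGGTGG", "AAGCTT", 1, "forward"))
  expect_error(minimal_variant("CCTGGG", "CCCGGG", 2, "forward"), "start")
})

test_that("minimal_variant respects orientation via the reverse complement", {
  # GGTCTC (BsaI) is non-palindromic; reverse orientation matches GAGACC on top
  seq <- "GAAACC"  # Glu-Thr; GAGACC is a silent double? no: check engine below
  fwd <- minimal_variant(seq, "GGTCTC", 1, "forward")
  rev <- minimal_variant(seq, "GGTCTC", 1, "reverse")
  # reverse orientation requires the top strand to read GAGACC
  expect_identical(rev$variant, "GAGACC")
  expect_true(is_synonymous(seq, rev$variant))
  # forward would need GGTCTC on top, which cannot encode Glu-Thr silently
  expect_null(fwd)
})

test_that("find_sites reproduces the Pro-Gly worked example", {
  lib <- fixture_library()
  rep4 <- find_sites("CCTGGG", lib, min_cutter = 4)
  key <- paste(rep4$enzyme, rep4$start, rep4$strand, rep4$variant, rep4$n_subs)
  expect_setequal(key, c("BsoBI 1 both CCCGGG 1", "XmaI 1 both CCCGGG 1",
                         "HpaII 2 both CCCGGG 1", "HpaII 1 both CCGGGG 1"))
  expect_true(all(rep4$substitutions == "3"))
  # summary over the four reports
  st <- summarize_sites(rep4)
  expect_identical(st$distinct_sequences, 2L)
  expect_identical(st$total_reported_res, 4L)
  expect_identical(st$palindromic_fraction, 1)
  # at min_cutter 6 the 4-bp cutter HpaII drops out
  rep6 <- find_sites("CCTGGG", lib, min_cutter = 6)
  expect_false("HpaII" %in% rep6$enzyme)
  expect_setequal(rep6$enzyme, c("BsoBI", "XmaI"))
})

test_that("find_sites reports pre-existing sites only on request, flagged", {
  lib <- lib1("XmaI", "CCCGGG")
  expect_identical(nrow(find_sites("CCCGGG", lib, 4)), 0L)
  rep <- find_sites("CCCGGG", lib, 4, include_existing = TRUE)
  expect_identical(nrow(rep), 1L)
  expect_true(rep$existing)
  expect_identical(rep$n_subs, 0L)
  # existing sites never enter the summary counts
  st <- summarize_sites(rep)
  expect_identical(st$total_reported_res, 0L)
  expect_true(st$no_new_sites)
})

test_that("co-minimal variants are emitted only when requested", {
  # Thr-Trp against ACRTGG: ACA and ACG both cost 1 at codon 1
  lib <- lib1("FakeI", "ACRTGG")
  one <- find_sites("ACCTGG", lib, 6)
  expect_identical(nrow(one), 1L)
  expect_identical(one$variant, "ACATGG")  # lexicographic tie-break
  both <- find_sites("ACCTGG", lib, 6, emit_co_minimal = TRUE)
  expect_identical(sort(both$variant), c("ACATGG", "ACGTGG"))
  expect_identical(unique(both$n_subs), 1L)
})

test_that("strand is 'both' exactly for palindromic motifs", {
  lib <- enzyme_library(c("BsaI", "EcoRI"), c("GGTCTC", "GAATTC"))
  set.seed(3)
  for (i in 1:10) {
    seq <- generate_random_cds(6, seed = i)
    rep <- find_sites(seq, lib, 6, include_existing = TRUE)
    if (!nrow(rep)) next
    expect_identical(rep$strand == "both", is_palindrome(rep$motif))
  }
  # non-palindromic motif never reports "both", even when top and bottom
  # candidates coincide at one start
  expect_false(any(find_sites(generate_random_cds(8, 5),
                              lib1("BsaI", "GGTCTC"), 6,
                              include_existing = TRUE)$strand == "both"))
})

test_that("every reported variant preserves the encoded peptide", {
  lib <- fixture_library()
  for (i in 1:10) {
    seq <- generate_random_cds(7, seed = 100 + i, forbid_internal_stops = FALSE)
    rep <- find_sites(seq, lib, 4, include_existing = TRUE)
    for (v in rep$variant)
      expect_identical(translate_cds(v), translate_cds(seq))
  }
})

test_that("raising the cutter cutoff can only shrink the report set", {
  lib <- fixture_library()
  for (i in 1:10) {
    seq <- generate_random_cds(8, seed = 200 + i)
    r4 <- find_sites(seq, lib, 4)
    r6 <- find_sites(seq, lib, 6)
    key <- function(r) paste(r$enzyme, r$start, r$strand, r$variant)
    expect_true(all(key(r6) %in% key(r4)))
  }
})

test_that("reports are deterministically ordered 5' to 3', strand, enzyme", {
  lib <- fixture_library()
  seq <- generate_random_cds(10, seed = 31)
  a <- find_sites(seq, lib, 4)
  b <- find_sites(seq, lib, 4)
  expect_identical(a, b)
  expect_true(all(diff(a$start) >= 0))
  within_start <- split(a, a$start)
  for (g in within_start) {
    r <- match(g$strand, c("both", "top", "bottom"))
    expect_true(all(diff(r) >= 0))
  }
})

test_that("engine agrees with the exhaustive oracle on small sequences", {
  lib <- fixture_library()
  expect_identical(find_sites("CCTGGG", lib, 4),
                   oracle_find_sites("CCTGGG", lib, 4))
  expect_identical(find_sites("GATCTTCGT", lib1("AflII", "CTTAAG"), 6),
                   oracle_find_sites("GATCTTCGT", lib1("AflII", "CTTAAG"), 6))
  # Trp codons admit no synonymous change
  expect_identical(find_sites("TGGTGGTGG", lib, 4),
                   oracle_find_sites("TGGTGGTGG", lib, 4))
  # sequences with stop codons exercise the 3-codon interchange class
  expect_identical(
    find_sites("CATTAA", lib1("FakeI", "TTGA"), 4),
    oracle_find_sites("CATTAA", lib1("FakeI", "TTGA"), 4))
  expect_error(oracle_find_sites(generate_random_cds(8, 1), lib, 4),
               "7 codons")
})

test_that("segment scan equals whole-sequence scan at full length and never exceeds it", {
  lib <- fixture_library()
  seq <- generate_random_cds(22, seed = 17)  # 66 bp
  whole <- find_sites(seq, lib, 4)
  full <- segment_scan(seq, nchar(seq), lib, 4)
  expect_identical(length(full), 1L)
  expect_identical(full[[1L]]$reports, whole)

  segs <- segment_scan(seq, 33, lib, 4)
  expect_identical(vapply(segs, `[[`, integer(1L), "offset"), c(1L, 34L))
  seg_total <- sum(vapply(segs, function(s) s$stats$total_reported_res,
                          integer(1L)))
  seg_distinct <- sum(vapply(segs, function(s) s$stats$distinct_sequences,
                             integer(1L)))
  whole_stats <- summarize_sites(whole)
  expect_lte(seg_total, whole_stats$total_reported_res)
  expect_lte(seg_distinct, whole_stats$distinct_sequences)
  # every segment-local site maps onto a whole-sequence site
  for (s in segs) {
    if (!nrow(s$reports)) next
    key <- paste(s$reports$enzyme, s$reports$start + s$offset - 1L,
                 s$reports$strand)
    expect_true(all(key %in% paste(whole$enzyme, whole$start, whole$strand)))
  }
  expect_error(segment_scan(seq, 32, lib, 4), "multiple of 3")
})

test_that("summary statistics follow their definitions on edge cases", {
  st0 <- summarize_sites(empty_df <- find_sites("TGGTGG", lib1("NotI", "GCGGCCGC"), 6))
  expect_identical(st0$distinct_sequences, 0L)
  expect_identical(st0$total_reported_res, 0L)
  expect_true(st0$no_new_sites)
  # all reports sharing one variant string count as one distinct sequence
  rep <- find_sites("CCTGGG", enzyme_library(c("XmaI", "TspMI"),
                                             c("CCCGGG", "CCCGGG")), 6)
  expect_identical(nrow(rep), 2L)
  expect_identical(summarize_sites(rep)$distinct_sequences, 1L)
})

test_that("window-based scanning is equivalent to the direct positional scan", {
  lib <- fixture_library()
  for (i in 1:5) {
    seq <- generate_random_cds(11, seed = 300 + i)  # 33 bp
    expect_identical(find_sites_windowed(seq, lib, 4),
                     find_sites(seq, lib, 4))
  }
})
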