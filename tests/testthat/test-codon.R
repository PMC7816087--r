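test_that("translation follows the standard genetic code with '*' for stops", {
  expect_identical(translate_cds("CCTGGG"), "PG")
  expect_identical(translate_cds("GATCTTCGT"), "DLR")
  expect_identical(translate_cds("TAA"), "*")
  expect_identical(translate_cds("atgTGGtaa"), "MW*")
  expect_error(translate_cds("ATGC"), "multiple of 3")
  expect_error(translate_cds("ATN"), "invalid base 'N'")
})

test_that("synonymous codon sets form the 21 classes of the standard code", {
  expect_identical(synonymous_codons("TAA"), c("TAA", "TAG", "TGA"))
  expect_identical(synonymous_codons("TGG"), "TGG")
  expect_identical(synonymous_codons("CGT"),
                   sort(c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG")))
  classes <- unique(lapply(mkAllCodons(), synonymous_codons))
  expect_identical(length(classes), 21L)
  expect_identical(sum(lengths(classes)), 64L)
  # each codon is a member of its own class
  for (c in mkAllCodons()) expect_true(c %in% synonymous_codons(c))
})

test_that("is_synonymous compares encoded peptides", {
  expect_true(is_synonymous("CCTGGG", "CCCGGG"))
  expect_true(is_synonymous("GATCTTCGT", "GACTTAAGA"))
  expect_false(is_synonymous("ATG", "CTG"))
  expect_error(is_synonymous("ATG", "ATGATG"), "equal length")
})

test_that("min_change_codon solves the documented constrained cases", {
  # Arg forced to start AG: AGA and AGG both cost 2; lexicographic tie-break
  res <- min_change_codon("CGT", list(`1` = "A", `2` = "G"))
  expect_identical(res, list(codon = "AGA", n_subs = 2L))
  all_res <- min_change_codon("CGT", list(`1` = "A", `2` = "G"), all = TRUE)
  expect_identical(all_res$codon, c("AGA", "AGG"))
  # Asp forced to end in C: single substitution
  expect_identical(min_change_codon("GAT", list(`3` = "C")),
                   list(codon = "GAC", n_subs = 1L))
  # Trp has no synonym: any constraint excluding TGG is infeasible
  expect_null(min_change_codon("TGG", list(`1` = "A")))
  # stop interchange: TAA can become TGA when offset 2 must be G
  expect_identical(min_change_codon("TAA", list(`2` = "G")),
                   list(codon = "TGA", n_subs = 1L))
})

test_that("min_change_codon with no constraint returns the codon unchanged", {
  for (c in c("ATG", "TGG", "TAA", "CGT", "GGG"))
    expect_identical(min_change_codon(c, list()), list(codon = c, n_subs = 0L))
})

test_that("min_change_codon matches exhaustive enumeration over random constraints", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  all64 <- mkAllCodons()
  for (i in 1:150) {
    codon <- sample(all64, 1L)
    offs <- sample(1:3, sample(0:3, 1L))
    constraint <- stats::setNames(
      lapply(offs, function(o) sample(bases, sample(1:3, 1L))),
      as.character(offs))
    assert_codon_minimal(codon, constraint,
                         min_change_codon(codon, constraint))
  }
})

test_that("constraint validation rejects malformed constraints", {
  expect_error(min_change_codon("ATG", list(`4` = "A")), "offsets")
  expect_error(min_change_codon("ATG", list(`1` = character(0))), "non-empty")
  expect_error(min_change_codon("ATG", list(`1` = "Z")), "non-empty")
})
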