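# Shared fixtures: the bundled 12-enzyme library and a tiny hand-rolled one.

fixture_library <- function() read_enzyme_library(bundled_enzymes())

# single-enzyme library helper
lib1 <- function(name, motif) enzyme_library(name, motif)

# independent brute-force check that `codon` has no cheaper synonymous
# replacement satisfying `constraint` than cost `n_subs` (enumerates all 64
# codons; does not go through synonymous_codons / min_change_codon)
assert_codon_minimal <- function(codon, constraint, result) {
  all64 <- mkAllCodons()
  aa <- vapply(all64, function(c) translate_cds(c), character(1L))
  feasible <- all64[aa == translate_cds(codon)]
  feasible <- feasible[vapply(feasible, function(c) {
    ok <- TRUE
    for (off in names(constraint)) {
      i <- as.integer(off)
      ok <- ok && substr(c, i, i) %in% constraint[[off]]
    }
    ok
  }, logical(1L))]
  if (!length(feasible)) {
    expect_null(result)
    return(invisible())
  }
  d <- vapply(feasible, function(c)
    sum(substring(c, 1:3, 1:3) != substring(codon, 1:3, 1:3)), integer(1L))
  expect_false(is.null(result))
  expect_identical(result$n_subs, min(d))
  best <- sort(feasible[d == min(d)], method = "radix")[[1L]]
  expect_identical(result$codon, best)
}

mkAllCodons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}
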