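# Genetic-code machinery: coding-sequence validation, translation,
# synonymous-codon classes (stop codons form one interchange class), and the
# constrained minimal-change codon solver at the heart of site engineering.

# Standard genetic code (NCBI table 1); Biostrings encodes stop as "*",
# which is exactly the 21st residue class this tool needs.
.GENETIC_CODE <- Biostrings::GENETIC_CODE

# amino acid -> character vector of codons, precomputed once
.SYNONYM_SETS <- split(names(.GENETIC_CODE), .GENETIC_CODE)

#' Validate an in-frame coding sequence
#'
#' Accepts a plain character string over A/C/G/T (case-insensitive), checks
#' that the length is a positive multiple of 3, and returns it uppercased.
#' Ambiguity codes are rejected: the input must be a concrete sequence.
#'
#' @param x A single character string.
#' @return The validated, uppercase coding sequence.
#' @export
as_coding_sequence <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("coding sequence must be a single character string", call. = FALSE)
  s <- toupper(gsub("\\s", "", x))
  n <- nchar(s)
  if (n < 3L || n %% 3L != 0L)
    stop(sprintf("coding sequence length (%d) must be a multiple of 3 and >= 3",
                 n), call. = FALSE)
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0L)
    stop(sprintf("invalid base '%s' at position %d: coding sequence must contain only A, C, G, T",
                 substr(s, bad, bad), bad), call. = FALSE)
  s
}

# split a validated CDS into its codons
codons_of <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
}

#' Translate a coding sequence
#'
#' Standard genetic code; stop codons translate to `"*"`.
#'
#' @param seq An in-frame coding sequence (see [as_coding_sequence()]).
#' @return Peptide string of length `nchar(seq) / 3` over the 20 amino-acid
#'   letters plus `"*"`.
#' @examples
#' translate_cds("CCTGGG")     # "PG"
#' translate_cds("GATCTTCGT")  # "DLR"
#' @export
translate_cds <- function(seq) {
  seq <- as_coding_sequence(seq)
  paste(.GENETIC_CODE[codons_of(seq)], collapse = "")
}

#' Synonymous codons of a codon
#'
#' All codons encoding the same amino acid under the standard genetic code,
#' including the input itself. The three stop codons (TAA, TAG, TGA) form a
#' single interchange class, treated exactly like an amino acid.
#'
#' @param codon A single triplet over A/C/G/T.
#' @return Character vector of synonymous codons, lexicographic order.
#' @examples
#' synonymous_codons("TAA")  # "TAA" "TAG" "TGA"
#' synonymous_codons("TGG")  # "TGG" (Trp is unique)
#' @export
synonymous_codons <- function(codon) {
  codon <- as_coding_sequence(codon)
  if (nchar(codon) != 3L)
    stop("codon must be a single triplet", call. = FALSE)
  sort(.SYNONYM_SETS[[.GENETIC_CODE[[codon]]]], method = "radix")
}

#' Do two coding sequences encode the same peptide?
#'
#' @param a,b In-frame coding sequences of equal length.
#' @return `TRUE` iff `translate_cds(a) == translate_cds(b)`.
#' @examples
#' is_synonymous("CCTGGG", "CCCGGG")  # TRUE (both Pro-Gly)
#' @export
is_synonymous <- function(a, b) {
  a <- as_coding_sequence(a)
  b <- as_coding_sequence(b)
  if (nchar(a) != nchar(b))
    stop("sequences must have equal length", call. = FALSE)
  translate_cds(a) == translate_cds(b)
}

# --- constrained minimal-change codon solver -------------------------------

# A codon constraint is a list mapping codon offsets "1","2","3" to non-empty
# allowed-base subsets of {A,C,G,T}; absent offsets are unconstrained.
check_constraint <- function(constraint) {
  if (!is.list(constraint))
    stop("constraint must be a list keyed by codon offset", call. = FALSE)
  if (length(constraint)) {
    off <- names(constraint)
    if (is.null(off) || !all(off %in% c("1", "2", "3")) || anyDuplicated(off))
      stop("constraint offsets must be unique and in {1, 2, 3}", call. = FALSE)
    ok <- vapply(constraint, function(s)
      length(s) >= 1L && all(s %in% c("A", "C", "G", "T")), logical(1L))
    if (!all(ok))
      stop("each allowed-base set must be a non-empty subset of {A, C, G, T}",
           call. = FALSE)
  }
  constraint
}

# does codon (3-char string) satisfy constraint?
satisfies_constraint <- function(codon, constraint) {
  for (off in names(constraint)) {
    i <- as.integer(off)
    if (!(substr(codon, i, i) %in% constraint[[off]])) return(FALSE)
  }
  TRUE
}

hamming3 <- function(a, b) {
  sum(substring(a, 1:3, 1:3) != substring(b, 1:3, 1:3))
}

#' Minimal synonymous codon change under a positional constraint
#'
#' Among the synonymous codons of `codon` whose bases satisfy the allowed
#' set at every constrained offset, returns the one at minimal Hamming
#' distance from `codon`. Ties are broken deterministically by lexicographic
#' codon order (A < C < G < T). If no synonymous codon satisfies the
#' constraint, returns `NULL` (infeasibility is a value, not an error).
#'
#' @param codon A triplet over A/C/G/T.
#' @param constraint A list mapping codon offsets (`"1"`, `"2"`, `"3"`) to
#'   non-empty allowed-base character vectors; offsets absent from the list
#'   are unconstrained. An empty list means no constraint.
#' @param all If `TRUE`, return every co-minimal satisfying codon rather
#'   than just the tie-break winner.
#' @return `NULL` if infeasible; otherwise a list with elements `codon`
#'   (the chosen triplet, or a character vector when `all = TRUE`) and
#'   `n_subs` (its Hamming distance from the input).
#' @examples
#' # force an Arg codon to start "AG": AGA wins the AGA/AGG tie
#' min_change_codon("CGT", list(`1` = "A", `2` = "G"))
#' @export
min_change_codon <- function(codon, constraint = list(), all = FALSE) {
  codon <- as_coding_sequence(codon)
  if (nchar(codon) != 3L)
    stop("codon must be a single triplet", call. = FALSE)
  constraint <- check_constraint(constraint)
  syn <- synonymous_codons(codon)
  ok <- vapply(syn, satisfies_constraint, logical(1L), constraint)
  syn <- syn[ok]
  if (!length(syn)) return(NULL)
  d <- vapply(syn, hamming3, integer(1L), codon)
  best <- syn[d == min(d)]           # already lexicographic from synonymous_codons
  list(codon = if (all) best else best[[1L]], n_subs = min(d))
}
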