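# IUPAC degenerate-motif algebra: validation, matching, reverse complement,
# palindromy, effective ("cutter") length.

#' IUPAC nucleotide alphabet
#'
#' The 15 one-letter nucleotide codes (4 concrete bases plus 11 degenerate
#' symbols) accepted in recognition motifs, and the set of concrete bases
#' each denotes.
#'
#' @format `IUPAC_ALPHABET` is a character vector of the 15 symbols;
#'   `IUPAC_BASES` is a named list mapping each symbol to the character
#'   vector of concrete bases it matches (e.g. `R` -> `c("A", "G")`,
#'   `N` -> all four).
#' @name iupac-alphabet
NULL

#' @rdname iupac-alphabet
#' @export
IUPAC_ALPHABET <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N")

#' @rdname iupac-alphabet
#' @export
IUPAC_BASES <- local({
  map <- Biostrings::IUPAC_CODE_MAP[IUPAC_ALPHABET]
  lapply(strsplit(unname(map), ""), sort)
})
names(IUPAC_BASES) <- IUPAC_ALPHABET

# 4 x 15 logical lookup: does concrete base b match symbol s?
.IUPAC_MATCH <- local({
  m <- vapply(IUPAC_BASES, function(set) c("A", "C", "G", "T") %in% set,
              logical(4))
  rownames(m) <- c("A", "C", "G", "T")
  m
})

# symbol-wise complement over the full IUPAC alphabet
.IUPAC_FROM <- "ACGTRYSWKMBDHVN"
.IUPAC_TO   <- "TGCAYRSWMKVHDBN"

#' Validate and normalize a degenerate recognition motif
#'
#' Checks that every character of `text` is one of the 15 IUPAC nucleotide
#' codes and returns the motif uppercased. Lowercase input is accepted.
#'
#' @param text A single character string, length >= 1.
#' @return The normalized (uppercase) motif string.
#' @examples
#' validate_motif("ggnncc")  # "GGNNCC"
#' @export
validate_motif <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("motif must be a single character string", call. = FALSE)
  m <- toupper(text)
  if (nchar(m) < 1L)
    stop("motif must contain at least one symbol", call. = FALSE)
  sym <- strsplit(m, "", fixed = TRUE)[[1L]]
  bad <- which(!(sym %in% IUPAC_ALPHABET))
  if (length(bad))
    stop(sprintf("invalid IUPAC symbol '%s' at position %d in motif '%s'",
                 sym[bad[1L]], bad[1L], m), call. = FALSE)
  m
}

#' Does a concrete base match an IUPAC symbol?
#'
#' @param base A concrete nucleotide, one of `"A"`, `"C"`, `"G"`, `"T"`
#'   (vectorized).
#' @param symbol An IUPAC code (vectorized, recycled against `base`).
#' @return Logical: `TRUE` iff `base` is in the set denoted by `symbol`
#'   (`N` denotes all four bases).
#' @examples
#' iupac_match("A", "R")  # TRUE:  R = A or G
#' iupac_match("C", "R")  # FALSE
#' @export
iupac_match <- function(base, symbol) {
  base <- toupper(base)
  symbol <- toupper(symbol)
  if (!all(base %in% c("A", "C", "G", "T")))
    stop("base must be a concrete nucleotide (A, C, G or T)", call. = FALSE)
  if (!all(symbol %in% IUPAC_ALPHABET))
    stop("symbol must be an IUPAC nucleotide code", call. = FALSE)
  n <- max(length(base), length(symbol))
  .IUPAC_MATCH[cbind(rep_len(base, n), rep_len(symbol, n))]
}

#' Reverse complement of a degenerate motif
#'
#' Complements symbol-wise over the full IUPAC alphabet
#' (A<->T, C<->G, R<->Y, K<->M, B<->V, D<->H; S, W and N are self-
#' complementary) and reverses. Vectorized over motifs.
#'
#' @param m Character vector of IUPAC motifs.
#' @return Character vector of reverse-complemented motifs.
#' @examples
#' reverse_complement("GGTCTC")  # "GAGACC"
#' reverse_complement("CTTAAG")  # "CTTAAG" (palindrome)
#' @export
reverse_complement <- function(m) {
  comp <- chartr(.IUPAC_FROM, .IUPAC_TO, toupper(m))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1L))
}

#' Is a motif palindromic (an inverted repeat)?
#'
#' A palindromic motif equals its own reverse complement symbol-for-symbol;
#' such a site is present on both strands at the same locus.
#'
#' @param m Character vector of IUPAC motifs.
#' @return Logical vector.
#' @examples
#' is_palindrome("CCCGGG")  # TRUE
#' is_palindrome("GGTCTC")  # FALSE
#' @export
is_palindrome <- function(m) {
  toupper(m) == reverse_complement(m)
}

#' Effective ("cutter") length of a recognition motif
#'
#' The number of specified positions in the motif: every symbol other than
#' `N` counts as one, including degenerate symbols such as `R` or `Y`; the
#' fully non-specific `N` does not count. A motif of effective length 6 is
#' called a 6-bp cutter.
#'
#' @param m Character vector of IUPAC motifs.
#' @return Integer vector.
#' @examples
#' effective_length("GGNNCC")    # 4
#' effective_length("GRGCYC")    # 6
#' effective_length("GCGGCCGC")  # 8
#' @export
effective_length <- function(m) {
  nchar(gsub("N", "", toupper(m), fixed = TRUE))
}

# Expand a degenerate motif into every concrete instance (used in tests and
# the matching oracle). Returns a character vector of A/C/G/T strings.
#' Enumerate the concrete instances of a degenerate motif
#'
#' @param m A single IUPAC motif.
#' @return Character vector of all concrete (A/C/G/T) sequences matching
#'   `m`, in lexicographic order.
#' @examples
#' expand_motif("CYCG")  # "CCCG" "CTCG"
#' @export
expand_motif <- function(m) {
  m <- validate_motif(m)
  sets <- IUPAC_BASES[strsplit(m, "", fixed = TRUE)[[1L]]]
  grid <- expand.grid(rev(sets), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  out <- do.call(paste0, rev(grid))
  sort(out, method = "radix")
}
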