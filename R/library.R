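# Enzyme libraries: ordered tables of (name, recognition motif).
# Two enzymes sharing a motif are isoschizomers and remain separate entries.

new_enzyme_library <- function(name, motif) {
  lib <- data.frame(name = as.character(name), motif = as.character(motif),
                    stringsAsFactors = FALSE)
  class(lib) <- c("enzyme_library", "data.frame")
  lib
}

#' Construct an enzyme library from name and motif vectors
#'
#' @param name Character vector of enzyme names (unique, non-empty).
#' @param motif Character vector of IUPAC recognition motifs, parallel to
#'   `name`.
#' @return An `enzyme_library`: a data frame with columns `name` and
#'   `motif`, in the given order.
#' @examples
#' enzyme_library(c("XmaI", "HpaII"), c("CCCGGG", "CCGG"))
#' @export
enzyme_library <- function(name, motif) {
  if (length(name) != length(motif))
    stop("name and motif must have the same length", call. = FALSE)
  if (length(name) == 0L)
    stop("enzyme library is empty", call. = FALSE)
  name <- as.character(name)
  if (any(is.na(name) | !nzchar(name)))
    stop("enzyme names must be non-empty", call. = FALSE)
  dup <- name[duplicated(name)]
  if (length(dup))
    stop(sprintf("duplicate enzyme name(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  motif <- vapply(motif, validate_motif, character(1L), USE.NAMES = FALSE)
  new_enzyme_library(name, motif)
}

#' @export
print.enzyme_library <- function(x, ...) {
  cat(sprintf("Enzyme library: %d enzymes (%d distinct motifs)\n",
              nrow(x), length(unique(x$motif))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read an enzyme library from a two-column TSV file
#'
#' The file carries one enzyme per line as `name<TAB>motif`; lines starting
#' with `#` and blank lines are skipped. Motifs are validated as IUPAC
#' patterns and uppercased; file order is preserved. Duplicate names are an
#' error (isoschizomers are distinct names with identical motifs, which are
#' kept as separate entries).
#'
#' @param path Path to the TSV file.
#' @return An [enzyme_library()].
#' @seealso [write_enzyme_library()], [read_rebase_library()],
#'   [bundled_enzymes()]
#' @export
read_enzyme_library <- function(path) {
  if (!file.exists(path))
    stop(sprintf("enzyme library file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep))
    stop(sprintf("enzyme library is empty: %s", path), call. = FALSE)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop(sprintf("malformed enzyme library row at line %d of %s: %s",
                 keep[bad[1L]], path, lines[keep[bad[1L]]]), call. = FALSE)
  enzyme_library(vapply(fields, `[[`, character(1L), 1L),
                 vapply(fields, `[[`, character(1L), 2L))
}

#' Write an enzyme library as a two-column TSV file
#'
#' Inverse of [read_enzyme_library()]: `read_enzyme_library(write_enzyme_library(lib, f))`
#' reproduces `lib` exactly.
#'
#' @param lib An [enzyme_library()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_enzyme_library <- function(lib, path) {
  writeLines(paste(lib$name, lib$motif, sep = "\t"), path)
  invisible(path)
}

#' Read a REBASE-style flat enzyme file
#'
#' Accepts lines of the form `name  recognition-sequence`, where the
#' recognition sequence may carry cut-position annotation: `^` carets inside
#' the motif and `(m/n)` offsets after it, both of which are stripped (cut
#' positions are irrelevant for site engineering). Any further whitespace-
#' separated annotation after the recognition sequence is ignored. Lines not
#' yielding a valid IUPAC motif after stripping are an error.
#'
#' @param path Path to the flat file.
#' @return An [enzyme_library()].
#' @export
read_rebase_library <- function(path) {
  if (!file.exists(path))
    stop(sprintf("enzyme file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep))
    stop(sprintf("enzyme library is empty: %s", path), call. = FALSE)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s", keep[bad[1L]], path),
         call. = FALSE)
  name <- vapply(fields, `[[`, character(1L), 1L)
  recog <- vapply(fields, `[[`, character(1L), 2L)
  recog <- gsub("\\([-0-9/]+\\)", "", recog)   # trailing (m/n) cut offsets
  recog <- gsub("^", "", recog, fixed = TRUE)  # cut-position carets
  enzyme_library(name, recog)
}

#' Path to the bundled demonstration enzyme library
#'
#' A compact 12-enzyme library of well-known restriction enzymes spanning
#' 4-bp to 8-bp cutters, degenerate motifs (BsoBI, BanII, BaeGI, AflIII)
#' and an N-containing motif (NlaIV), shipped as plain TSV; all twelve
#' motifs happen to be palindromic. Useful for examples and as a small search library; for
#' production screening load a full REBASE-derived library with
#' [read_rebase_library()].
#'
#' @return File path of the bundled TSV.
#' @examples
#' lib <- read_enzyme_library(bundled_enzymes())
#' nrow(lib)  # 12
#' @export
bundled_enzymes <- function() {
  system.file("extdata", "demo_enzymes.tsv", package = "silentsites",
              mustWork = TRUE)
}

#' Filter an enzyme library by minimum cutter length
#'
#' Keeps enzymes whose motif has [effective_length()] at least `n`
#' (degenerate symbols count, `N` does not), preserving order. With `n = 6`
#' this is the conventional ">= 6-bp cutter" restriction.
#'
#' @param lib An [enzyme_library()].
#' @param n Integer >= 1, minimum effective motif length.
#' @return The filtered `enzyme_library` (possibly zero rows).
#' @export
filter_min_cutter <- function(lib, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L)
    stop("minimum cutter length must be an integer >= 1", call. = FALSE)
  out <- lib[effective_length(lib$motif) >= n, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enzyme_library", "data.frame")
  out
}
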