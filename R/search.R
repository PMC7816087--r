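# Core engine: find every (enzyme, position, strand) where a minimal
# synonymous edit creates a recognition site; summary statistics; segmented
# scans; a brute-force oracle; a sliding-window scan used for verification.
#
# Coordinates are 1-based, inclusive, on the top strand; `start` is the
# motif's leftmost base. Bottom-strand candidates are found by matching the
# reverse complement of the motif against the top-strand text, so `start`
# stays a top-strand coordinate. Palindromic motifs are evaluated once and
# reported with strand "both"; non-palindromic motifs yield separate top
# (forward) and bottom (reverse) candidates.
#
# Minimality argument: a motif placement constrains each overlapped codon
# independently (the allowed-base sets never couple two codons), so solving
# each codon with min_change_codon and leaving the rest untouched is globally
# minimal; the exhaustive oracle cross-checks this on small inputs.

.STRAND_LEVELS <- c("both", "top", "bottom")

empty_reports <- function() {
  data.frame(enzyme = character(0), motif = character(0),
             start = integer(0), strand = character(0),
             n_subs = integer(0), substitutions = character(0),
             variant = character(0), existing = logical(0),
             stringsAsFactors = FALSE)
}

# canonical report ordering: start, strand (both < top < bottom), enzyme
# name (byte order), then variant for co-minimal multiplicities
sort_reports <- function(reports) {
  if (!nrow(reports)) return(reports)
  o <- order(reports$start, match(reports$strand, .STRAND_LEVELS),
             reports$enzyme, reports$variant, method = "radix")
  out <- reports[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

make_report <- function(enzyme, motif, start, strand, input, variant) {
  pos <- which(strsplit(input, "")[[1L]] != strsplit(variant, "")[[1L]])
  data.frame(enzyme = enzyme, motif = motif, start = as.integer(start),
             strand = strand, n_subs = length(pos),
             substitutions = paste(pos, collapse = ","),
             variant = variant, existing = length(pos) == 0L,
             stringsAsFactors = FALSE)
}

#' Minimal synonymous variant creating a motif match at one position
#'
#' Projects the motif (or, for the reverse orientation, its reverse
#' complement) onto the codons it overlaps as per-codon allowed-base
#' constraints, solves each overlapped codon independently with
#' [min_change_codon()], and leaves all other codons untouched. Because the
#' constraints never couple codons, per-codon minimality is global
#' minimality. Substitutions may fall outside the motif footprint when a
#' codon's only suitable synonym differs at an unconstrained offset.
#'
#' @param seq An in-frame coding sequence.
#' @param motif An IUPAC recognition motif.
#' @param start 1-based top-strand position of the motif's leftmost base;
#'   must satisfy `1 <= start <= nchar(seq) - nchar(motif) + 1`.
#' @param orientation `"forward"` (motif on the top strand) or `"reverse"`
#'   (motif on the bottom strand, i.e. its reverse complement on the top).
#' @param all If `TRUE`, `variant` holds every co-minimal variant.
#' @return `NULL` if no synonymous variant can match; otherwise a list with
#'   `variant` (full-length altered sequence), `n_subs`, and
#'   `substitutions` (integer positions where the variant differs).
#' @examples
#' minimal_variant("CCTGGG", "CCCGGG", 1, "forward")
#' # $variant "CCCGGG", $n_subs 1, $substitutions 3
#' @export
minimal_variant <- function(seq, motif, start, orientation = c("forward", "reverse"),
                            all = FALSE) {
  seq <- as_coding_sequence(seq)
  motif <- validate_motif(motif)
  orientation <- match.arg(orientation)
  start <- as.integer(start)
  L <- nchar(motif)
  if (is.na(start) || start < 1L || start > nchar(seq) - L + 1L)
    stop(sprintf("start must be in [1, %d]", nchar(seq) - L + 1L),
         call. = FALSE)
  pattern <- if (orientation == "reverse") reverse_complement(motif) else motif
  psym <- strsplit(pattern, "", fixed = TRUE)[[1L]]

  cods <- codons_of(seq)
  # group motif positions by the codon they fall in
  pos <- start:(start + L - 1L)
  ci <- (pos - 1L) %/% 3L + 1L          # codon index
  off <- (pos - 1L) %% 3L + 1L          # offset within codon
  new_cods <- as.list(cods)
  for (k in unique(ci)) {
    sel <- ci == k
    constraint <- stats::setNames(IUPAC_BASES[psym[sel]],
                                  as.character(off[sel]))
    sol <- min_change_codon(cods[[k]], constraint, all = all)
    if (is.null(sol)) return(NULL)
    new_cods[[k]] <- sol$codon
  }
  variants <- do.call(paste0, expand.grid(new_cods, KEEP.OUT.ATTRS = FALSE,
                                          stringsAsFactors = FALSE))
  variants <- sort(unique(variants), method = "radix")
  in_ch <- strsplit(seq, "")[[1L]]
  subs <- lapply(variants, function(v) which(strsplit(v, "")[[1L]] != in_ch))
  list(variant = if (all) variants else variants[[1L]],
       n_subs = length(subs[[1L]]),
       substitutions = if (all) subs else subs[[1L]])
}

#' Find all engineerable restriction sites in a coding sequence
#'
#' For every enzyme passing the minimum-cutter filter, every placement of
#' its motif, and every orientation, computes the minimal synonymous variant
#' creating the site ([minimal_variant()]). Palindromic motifs are evaluated
#' once and reported with strand `"both"`; other motifs give separate
#' `"top"` and `"bottom"` candidates. Reports are sorted 5' to 3' by
#' position, then strand (both, top, bottom), then enzyme name. Sites
#' already present in the input (zero substitutions) are flagged `existing`
#' and included only on request; isoschizomers appear as separate lines.
#'
#' @param seq An in-frame coding sequence.
#' @param lib An [enzyme_library()].
#' @param min_cutter Minimum effective motif length (>= 1); default 6.
#' @param include_existing Report zero-substitution (pre-existing) sites?
#' @param emit_co_minimal Emit one line per co-minimal variant instead of
#'   only the lexicographic tie-break winner?
#' @return A data frame of site reports with columns `enzyme`, `motif`,
#'   `start`, `strand`, `n_subs`, `substitutions` (comma-joined 1-based
#'   positions), `variant` (full-length altered sequence) and `existing`.
#' @examples
#' lib <- read_enzyme_library(bundled_enzymes())
#' find_sites("CCTGGG", lib, min_cutter = 4)
#' @export
find_sites <- function(seq, lib, min_cutter = 6L, include_existing = FALSE,
                       emit_co_minimal = FALSE) {
  seq <- as_coding_sequence(seq)
  flib <- filter_min_cutter(lib, min_cutter)
  if (!nrow(flib)) {
    warning("no enzymes pass the minimum-cutter filter; empty result",
            call. = FALSE)
    return(empty_reports())
  }
  out <- list()
  for (i in seq_len(nrow(flib))) {
    nm <- flib$name[[i]]
    motif <- flib$motif[[i]]
    L <- nchar(motif)
    if (L > nchar(seq)) next
    orients <- if (is_palindrome(motif)) c(both = "forward")
               else c(top = "forward", bottom = "reverse")
    for (start in seq_len(nchar(seq) - L + 1L)) {
      for (strand in names(orients)) {
        sol <- minimal_variant(seq, motif, start, orients[[strand]],
                               all = emit_co_minimal)
        if (is.null(sol)) next
        if (sol$n_subs == 0L && !include_existing) next
        for (v in sol$variant)
          out[[length(out) + 1L]] <- make_report(nm, motif, start, strand, seq, v)
      }
    }
  }
  if (!length(out)) return(empty_reports())
  sort_reports(do.call(rbind, out))
}

#' Summary statistics over a set of site reports
#'
#' Considers only engineered (>= 1 substitution) reports: pre-existing sites
#' are excluded from all "new site" counts.
#'
#' @param reports A report data frame from [find_sites()] (one sequence).
#' @return A list of class `site_summary` with `distinct_sequences` (number
#'   of distinct altered full-length sequences), `total_reported_res`
#'   (number of engineered reports, isoschizomers counted separately),
#'   `palindromic_fraction` (fraction of engineered reports whose motif is
#'   palindromic; 0 with `no_new_sites = TRUE` when there are none).
#' @export
summarize_sites <- function(reports) {
  new <- reports[reports$n_subs >= 1L, , drop = FALSE]
  total <- nrow(new)
  out <- list(
    distinct_sequences = length(unique(new$variant)),
    total_reported_res = total,
    palindromic_fraction = if (total) mean(is_palindrome(new$motif)) else 0,
    no_new_sites = total == 0L)
  class(out) <- "site_summary"
  out
}

#' @export
print.site_summary <- function(x, ...) {
  cat(sprintf("Distinct new sequences: %d\n", x$distinct_sequences))
  cat(sprintf("Total reported REs:     %d\n", x$total_reported_res))
  cat(sprintf("Palindromic fraction:   %s\n",
              if (x$no_new_sites) "NA (no engineered sites)"
              else sprintf("%.3f", x$palindromic_fraction)))
  invisible(x)
}

#' Scan a coding sequence in non-overlapping in-frame segments
#'
#' Splits the sequence into consecutive segments of `segment_len` bases
#' (a multiple of 3; a shorter trailing segment of at least one codon is
#' also scanned) and runs [find_sites()] independently on each. Sites
#' spanning a segment boundary are necessarily absent, so per-segment counts
#' can only fall short of the whole-sequence scan.
#'
#' @param seq An in-frame coding sequence.
#' @param segment_len Segment length in bases, a positive multiple of 3.
#' @inheritParams find_sites
#' @return A list with one element per segment: `offset` (1-based position
#'   of the segment's first base in `seq`), `end`, `reports` (segment-local
#'   coordinates) and `stats` ([summarize_sites()] of the reports).
#' @export
segment_scan <- function(seq, segment_len, lib, min_cutter = 6L,
                         include_existing = FALSE, emit_co_minimal = FALSE) {
  seq <- as_coding_sequence(seq)
  segment_len <- as.integer(segment_len)
  if (is.na(segment_len) || segment_len < 3L || segment_len %% 3L != 0L)
    stop("segment_len must be a positive multiple of 3", call. = FALSE)
  starts <- seq.int(1L, nchar(seq), by = segment_len)
  lapply(starts, function(s) {
    e <- min(s + segment_len - 1L, nchar(seq))
    sub <- substr(seq, s, e)
    reports <- find_sites(sub, lib, min_cutter, include_existing,
                          emit_co_minimal)
    list(offset = s, end = e, reports = reports,
         stats = summarize_sites(reports))
  })
}

# --- exhaustive oracle ------------------------------------------------------

#' Brute-force reference implementation of the site search
#'
#' Enumerates every synonymous full-length sequence (Cartesian product of
#' per-codon synonym sets), scans each against every motif at every position
#' and orientation, and keeps, for each (enzyme, start, strand), the
#' minimum-Hamming-distance variant with lexicographic tie-break. Identical
#' report contract and ordering as [find_sites()]; exists to verify the
#' constrained per-codon solver by independent exhaustive search. Refuses
#' sequences longer than 7 codons (the synonym product grows as fast as
#' 6^k).
#'
#' @inheritParams find_sites
#' @return A report data frame as in [find_sites()].
#' @export
oracle_find_sites <- function(seq, lib, min_cutter = 6L,
                              include_existing = FALSE) {
  seq <- as_coding_sequence(seq)
  n <- nchar(seq)
  cods <- codons_of(seq)
  if (length(cods) > 7L)
    stop("oracle refuses sequences longer than 7 codons", call. = FALSE)
  flib <- filter_min_cutter(lib, min_cutter)
  if (!nrow(flib)) {
    warning("no enzymes pass the minimum-cutter filter; empty result",
            call. = FALSE)
    return(empty_reports())
  }

  syn <- lapply(cods, synonymous_codons)
  grid <- expand.grid(rev(syn), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  variants <- do.call(paste0, rev(grid))
  mat <- do.call(rbind, strsplit(variants, "", fixed = TRUE))
  in_ch <- strsplit(seq, "")[[1L]]
  dist <- rowSums(mat != matrix(in_ch, nrow(mat), n, byrow = TRUE))

  out <- list()
  for (i in seq_len(nrow(flib))) {
    nm <- flib$name[[i]]
    motif <- flib$motif[[i]]
    L <- nchar(motif)
    if (L > n) next
    pats <- if (is_palindrome(motif)) list(both = motif)
            else list(top = motif, bottom = reverse_complement(motif))
    for (strand in names(pats)) {
      psym <- strsplit(pats[[strand]], "", fixed = TRUE)[[1L]]
      for (start in seq_len(n - L + 1L)) {
        ok <- rep(TRUE, nrow(mat))
        for (j in seq_len(L))
          ok <- ok & .IUPAC_MATCH[cbind(mat[, start + j - 1L], psym[[j]])]
        if (!any(ok)) next
        d <- dist[ok]
        md <- min(d)
        if (md == 0L && !include_existing) next
        cand <- variants[ok][d == md]
        best <- cand[order(cand, method = "radix")[1L]]
        out[[length(out) + 1L]] <- make_report(nm, motif, start, strand, seq, best)
      }
    }
  }
  if (!length(out)) return(empty_reports())
  sort_reports(do.call(rbind, out))
}

#' Sliding-window scan (verification aid)
#'
#' Scans the sequence as a series of `window`-bp windows offset by `offset`
#' bp (defaults 15 and 3, i.e. five codons advanced one codon at a time),
#' restricting motif placements to lie entirely within some window, then
#' deduplicates. For motif footprints up to `window - 2` this reaches every
#' placement and is equivalent to the direct positional scan of
#' [find_sites()]; it exists to demonstrate that equivalence.
#'
#' @inheritParams find_sites
#' @param window Window width in bases.
#' @param offset Offset between successive windows in bases.
#' @return A report data frame as in [find_sites()].
#' @export
find_sites_windowed <- function(seq, lib, min_cutter = 6L,
                                include_existing = FALSE, window = 15L,
                                offset = 3L) {
  seq <- as_coding_sequence(seq)
  n <- nchar(seq)
  flib <- filter_min_cutter(lib, min_cutter)
  if (!nrow(flib)) return(empty_reports())
  win_starts <- seq.int(1L, max(1L, n - window + 1L), by = offset)
  out <- list()
  seen <- character(0)
  for (w in win_starts) {
    w_end <- min(w + window - 1L, n)
    for (i in seq_len(nrow(flib))) {
      nm <- flib$name[[i]]
      motif <- flib$motif[[i]]
      L <- nchar(motif)
      if (w + L - 1L > w_end) next
      orients <- if (is_palindrome(motif)) c(both = "forward")
                 else c(top = "forward", bottom = "reverse")
      for (start in w:(w_end - L + 1L)) {
        for (strand in names(orients)) {
          key <- paste(nm, start, strand, sep = "\r")
          if (key %in% seen) next
          seen <- c(seen, key)
          sol <- minimal_variant(seq, motif, start, orients[[strand]])
          if (is.null(sol)) next
          if (sol$n_subs == 0L && !include_existing) next
          out[[length(out) + 1L]] <- make_report(nm, motif, start, strand,
                                                 seq, sol$variant)
        }
      }
    }
  }
  if (!length(out)) return(empty_reports())
  sort_reports(do.call(rbind, out))
}
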