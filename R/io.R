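# Sequence input (inline or FASTA), report rendering (TSV and human-readable
# text), the seedable synthetic coding-sequence generator, and the command-
# line entry point.

#' Read and validate a coding sequence
#'
#' Accepts either an inline sequence string or a FASTA file. By default the
#' supported input range of the interactive tool is enforced: 15 to 99 bases
#' and a multiple of 3; the engine itself only needs a codon multiple, so
#' the bounds can be lifted. An internal stop codon (a `*` before the last
#' residue) triggers a warning, not an error: the final-exon case
#' legitimately ends in a stop, and the engine treats stops as a synonym
#' class like any amino acid.
#'
#' @param sequence Inline sequence string (mutually exclusive with `fasta`).
#' @param fasta Path to a FASTA file. With more than one record, all records
#'   are returned (batch mode).
#' @param enforce_bounds Enforce the 15-99 bp supported range?
#' @return A named character vector of validated, uppercased coding
#'   sequences (one element for inline input, named `""`).
#' @export
read_coding_sequence <- function(sequence = NULL, fasta = NULL,
                                 enforce_bounds = TRUE) {
  if (is.null(sequence) == is.null(fasta))
    stop("provide exactly one of `sequence` or `fasta`", call. = FALSE)
  if (!is.null(fasta)) {
    if (!file.exists(fasta))
      stop(sprintf("FASTA file not found: %s", fasta), call. = FALSE)
    set <- Biostrings::readDNAStringSet(fasta)
    if (!length(set))
      stop(sprintf("no records in FASTA file: %s", fasta), call. = FALSE)
    seqs <- stats::setNames(as.character(set), names(set))
  } else {
    seqs <- stats::setNames(as.character(sequence), "")
  }
  out <- vapply(seqs, function(s) {
    s <- as_coding_sequence(s)
    if (enforce_bounds && (nchar(s) < 15L || nchar(s) > 99L))
      stop(sprintf("sequence length %d outside the supported range of 15-99 bases (use enforce_bounds = FALSE / --no-length-bounds to lift)",
                   nchar(s)), call. = FALSE)
    pep <- translate_cds(s)
    if (grepl("\\*", substr(pep, 1L, nchar(pep) - 1L)))
      warning("internal stop codon in coding sequence", call. = FALSE)
    s
  }, character(1L))
  out
}

#' Render site reports as TSV or annotated text
#'
#' TSV mode writes one machine-readable row per report with columns
#' `enzyme`, `motif`, `start`, `strand`, `n_subs`, `substitution_positions`
#' (comma-joined), `variant_sequence`, `existing`. Text mode renders each
#' variant with substituted bases in lowercase and the motif footprint
#' delimited by square brackets, followed by a summary block. Ordering is
#' byte-stable, exactly as produced by [find_sites()].
#'
#' @param reports Report data frame from [find_sites()].
#' @param stats Optional [summarize_sites()] result appended in text mode
#'   (computed from `reports` when `NULL`).
#' @param format `"tsv"` or `"text"`.
#' @param file Connection or file path passed to [writeLines()]; `""`
#'   prints to stdout.
#' @return The rendered lines, invisibly.
#' @export
write_reports <- function(reports, stats = NULL, format = c("tsv", "text"),
                          file = "") {
  format <- match.arg(format)
  lines <- if (format == "tsv") render_tsv(reports)
           else render_text(reports,
                            if (is.null(stats)) summarize_sites(reports) else stats)
  if (is.character(file) && length(file) == 1L && !nzchar(file))
    file <- stdout()
  writeLines(lines, file)
  invisible(lines)
}

render_tsv <- function(reports) {
  header <- paste(c("enzyme", "motif", "start", "strand", "n_subs",
                    "substitution_positions", "variant_sequence", "existing"),
                  collapse = "\t")
  if (!nrow(reports)) return(header)
  c(header,
    paste(reports$enzyme, reports$motif, reports$start, reports$strand,
          reports$n_subs, reports$substitutions, reports$variant,
          tolower(as.character(reports$existing)), sep = "\t"))
}

# lowercase the substituted bases and bracket the motif footprint
mark_variant <- function(variant, substitutions, start, motif_len) {
  ch <- strsplit(variant, "")[[1L]]
  if (nzchar(substitutions)) {
    pos <- as.integer(strsplit(substitutions, ",", fixed = TRUE)[[1L]])
    ch[pos] <- tolower(ch[pos])
  }
  end <- start + motif_len - 1L
  paste0(paste(ch[seq_len(start - 1L)], collapse = ""), "[",
         paste(ch[start:end], collapse = ""), "]",
         paste(ch[seq_len(length(ch) - end) + end], collapse = ""))
}

render_text <- function(reports, stats) {
  lines <- character(0)
  if (nrow(reports)) {
    marked <- vapply(seq_len(nrow(reports)), function(i)
      mark_variant(reports$variant[[i]], reports$substitutions[[i]],
                   reports$start[[i]], nchar(reports$motif[[i]])),
      character(1L))
    lines <- sprintf("%-10s %-10s %4d  %-6s %d sub%s  %s%s",
                     reports$enzyme, reports$motif, reports$start,
                     reports$strand, reports$n_subs,
                     ifelse(reports$n_subs == 1L, " ", "s"), marked,
                     ifelse(reports$existing, "  (existing site)", ""))
  } else {
    lines <- "No sites reported."
  }
  c(lines, "",
    sprintf("Distinct new sequences: %d", stats$distinct_sequences),
    sprintf("Total reported REs:     %d", stats$total_reported_res),
    sprintf("Palindromic fraction:   %s",
            if (stats$no_new_sites) "NA"
            else sprintf("%.3f", stats$palindromic_fraction)))
}

#' Read back a TSV report file
#'
#' Inverse of the TSV mode of [write_reports()]: reconstructs the report
#' data frame exactly, including column types.
#'
#' @param path Path to a TSV report file.
#' @return A report data frame as produced by [find_sites()].
#' @export
read_reports <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(enzyme = "character",
                                         motif = "character",
                                         start = "integer",
                                         strand = "character",
                                         n_subs = "integer",
                                         substitution_positions = "character",
                                         variant_sequence = "character",
                                         existing = "character"),
                          comment.char = "#")
  data.frame(enzyme = df$enzyme, motif = df$motif, start = df$start,
             strand = df$strand, n_subs = df$n_subs,
             substitutions = ifelse(is.na(df$substitution_positions), "",
                                    df$substitution_positions),
             variant = df$variant_sequence,
             existing = df$existing == "true",
             stringsAsFactors = FALSE)
}

#' Generate a random in-frame coding sequence
#'
#' Draws each codon uniformly from the 64 codons of the standard code (or
#' the 61 sense codons when internal stops are forbidden) with a seeded,
#' deterministic generator: the same seed always yields the same sequence.
#' The caller's random-number state is left untouched. Used as the
#' synthetic-sequence source for property tests and examples; uniform codon
#' usage deliberately ignores real codon bias.
#'
#' @param n_codons Number of codons (>= 1).
#' @param seed Integer seed.
#' @param forbid_internal_stops Exclude the three stop codons from the draw?
#' @return A coding sequence of `3 * n_codons` bases.
#' @examples
#' generate_random_cds(5, seed = 7)
#' @export
generate_random_cds <- function(n_codons, seed, forbid_internal_stops = TRUE) {
  n_codons <- as.integer(n_codons)
  if (is.na(n_codons) || n_codons < 1L)
    stop("n_codons must be an integer >= 1", call. = FALSE)
  pool <- names(.GENETIC_CODE)
  if (forbid_internal_stops) pool <- pool[.GENETIC_CODE != "*"]
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  paste(sample(pool, n_codons, replace = TRUE), collapse = "")
}

# --- command-line interface -------------------------------------------------

cli_options <- function() {
  list(
    optparse::make_option("--sequence", type = "character", default = NULL,
      help = "Inline coding sequence (mutually exclusive with --fasta)"),
    optparse::make_option("--fasta", type = "character", default = NULL,
      help = "FASTA file; multiple records are processed independently"),
    optparse::make_option("--enzymes", type = "character", default = NULL,
      help = "Enzyme library TSV (name<TAB>motif) [default: bundled 12-enzyme library]"),
    optparse::make_option("--min-cutter", type = "integer", default = 6L,
      dest = "min_cutter", help = "Minimum effective motif length [default %default]"),
    optparse::make_option("--include-existing", action = "store_true",
      default = FALSE, dest = "include_existing",
      help = "Also report sites already present in the input"),
    optparse::make_option("--segment-length", type = "integer", default = NULL,
      dest = "segment_length",
      help = "Scan in non-overlapping segments of this many bases (multiple of 3)"),
    optparse::make_option("--format", type = "character", default = "tsv",
      help = "Output format: tsv or text [default %default]"),
    optparse::make_option("--output", type = "character", default = NULL,
      help = "Output file [default: stdout]"),
    optparse::make_option("--no-length-bounds", action = "store_true",
      default = FALSE, dest = "no_length_bounds",
      help = "Lift the 15-99 bp input length bounds"),
    optparse::make_option("--verbose", action = "store_true", default = FALSE,
      help = "Log library and report counts to stderr"))
}

cli_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Command-line entry point
#'
#' Orchestrates read, filter, search (whole-sequence or segmented) and
#' write. Validation failures exit with status 1, input/output failures
#' with status 2, success with 0; diagnostics go to stderr. A thin wrapper
#' script is installed at `system.file("scripts", "silentsites",
#' package = "silentsites")`.
#'
#' @param args Character vector of command-line arguments.
#' @return The exit status, invisibly (0 success, 1 validation error,
#'   2 I/O error).
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  parser <- optparse::OptionParser(
    usage = "%prog --sequence SEQ | --fasta FILE [options]",
    description = "Report minimal silent substitutions that create restriction-enzyme sites in a coding sequence.",
    option_list = cli_options())
  opts <- tryCatch(optparse::parse_args(parser, args = args),
                   error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts))
    optparse::print_help(parser)
    return(invisible(1L))
  }
  status <- tryCatch({
    if (is.null(opts$sequence) == is.null(opts$fasta))
      stop("provide exactly one of --sequence or --fasta", call. = FALSE)
    lib_path <- if (is.null(opts$enzymes)) bundled_enzymes() else opts$enzymes
    lib <- read_enzyme_library(lib_path)
    cli_log(opts$verbose, "enzyme library: %d enzymes (%s)", nrow(lib), lib_path)
    flib <- filter_min_cutter(lib, opts$min_cutter)
    cli_log(opts$verbose, ">= %d-bp cutters: %d enzymes",
            opts$min_cutter, nrow(flib))
    seqs <- read_coding_sequence(sequence = opts$sequence, fasta = opts$fasta,
                                 enforce_bounds = !opts$no_length_bounds)
    if (!(opts$format %in% c("tsv", "text")))
      stop("--format must be 'tsv' or 'text'", call. = FALSE)

    sink_file <- if (is.null(opts$output)) stdout() else opts$output
    all_lines <- character(0)
    for (i in seq_along(seqs)) {
      seq <- seqs[[i]]
      nm <- names(seqs)[[i]]
      if (nzchar(nm) || length(seqs) > 1L)
        all_lines <- c(all_lines, sprintf("# record: %s", nm))
      if (is.null(opts$segment_length)) {
        reports <- find_sites(seq, lib, opts$min_cutter,
                              opts$include_existing)
        cli_log(opts$verbose, "%s: %d reports",
                if (nzchar(nm)) nm else "sequence", nrow(reports))
        all_lines <- c(all_lines,
                       if (opts$format == "tsv") render_tsv(reports)
                       else render_text(reports, summarize_sites(reports)))
      } else {
        segs <- segment_scan(seq, opts$segment_length, lib, opts$min_cutter,
                             opts$include_existing)
        for (sg in segs) {
          all_lines <- c(all_lines,
                         sprintf("# segment: %d-%d", sg$offset, sg$end),
                         if (opts$format == "tsv") render_tsv(sg$reports)
                         else render_text(sg$reports, sg$stats))
        }
      }
    }
    writeLines(all_lines, sink_file)
    0L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("not found|cannot open|No such file", conditionMessage(e))) 2L
    else 1L
  })
  invisible(status)
}
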