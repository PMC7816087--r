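---
title: "Engineering restriction sites with silent substitutions: method and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engineering restriction sites with silent substitutions: method and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silentsites)
```

## The problem

A common CRISPR/Cas9 editing workflow introduces, alongside the edit of
interest, a new restriction-endonuclease (RE) recognition site into the
homology-directed-repair template. Edited clones are then screened by PCR
followed by a restriction digest (an RFLP assay). Within a coding region
the engineered site must be created purely by *silent* substitutions: the
altered DNA has to encode exactly the original peptide. `silentsites`
enumerates, for a given enzyme library, every position at which that is
possible and the cheapest set of substitutions that achieves it.

## The model

**Inputs.** An in-frame coding sequence over A/C/G/T whose length is a
multiple of 3, and an ordered enzyme library of (name, motif) pairs where
motifs are written in the 15-letter IUPAC alphabet. Two enzymes may share
a motif (isoschizomers); they are deliberately kept as separate report
lines, and the isoschizomer relation is derivable (identical motif
strings) rather than stored.

**Matching.** A concrete base $b$ matches an IUPAC symbol $s$ iff
$b \in \beta(s)$, where $\beta$ is the standard code-to-base-set map
($\beta(R) = \{A,G\}$, $\beta(N) = \{A,C,G,T\}$, …). Bottom-strand sites
are found by matching the *reverse complement* of the motif against the
top-strand text, so all reported coordinates are 1-based top-strand
positions of the motif's leftmost base. A motif equal to its own reverse
complement is palindromic; such a site exists on both strands at once and
is evaluated once and reported with strand `both`. `both` is reserved
strictly for palindromes: in the rare corner where a non-palindromic
motif's forward and reverse minimal variants coincide at one start, two
lines (`top`, `bottom`) are kept.

**Cutter length.** The effective length of a motif counts every symbol
except `N`; degenerate symbols count fully. NlaIV (`GGNNCC`) is therefore
a 4-bp cutter while BanII (`GRGCYC`) and BaeGI (`GKGCMC`) are 6-bp
cutters, even though the degenerate motifs occur more often in a genome
than fully specified ones of the same length. The `min_cutter` filter is
applied to this effective length.

**The solver.** A placement of a motif (length $L$) at position $s$
projects onto the codons it overlaps: each overlapped codon receives an
allowed-base set at one, two or three of its offsets. Offsets outside the
footprint are unconstrained — which is exactly how substitutions *outside*
the motif arise: a codon may have no synonym that satisfies the constraint
without also changing an unconstrained position (e.g. Arg `CGT` forced to
start `AG` must become `AGA` or `AGG`, changing offset 3 as a side
effect). Each overlapped codon is solved independently:

$$c_j^\* \;=\; \arg\min_{c' \sim c_j,\ c' \models K_j} d_H(c_j, c'),$$

minimizing Hamming distance over the synonymous codons satisfying the
constraint. Because a placement constrains codons through independent
per-offset sets — never jointly — the sum of per-codon minima is the global
minimum, and infeasibility of any one codon (e.g. Trp or Met under an
incompatible constraint) makes the placement infeasible. This argument is
not merely asserted: an exhaustive oracle (`oracle_find_sites()`)
recomputes every report by brute-force enumeration of the full synonymous
sequence space and the test suite demands byte-identical output on
hundreds of seeded random sequences.

**Stop codons** form a 21st synonym class \{TAA, TAG, TGA\}, interchanged
exactly like amino-acid synonyms. Internal stops in an input are accepted
by the engine and flagged with a warning at the I/O layer, since a
final-exon fragment legitimately ends in a stop.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_cutter` | 6 | minimum effective motif length (bases); 6 targets the conventional "6-bp cutter and up" set whose sites are rare enough for screening, 4 includes frequent cutters |
| `include_existing` | `FALSE` | also report zero-substitution sites already present (flagged `existing`; never counted in "new site" summaries) |
| `emit_co_minimal` | `FALSE` | emit every co-minimal variant instead of only the tie-break winner |
| `segment_len` | — | optional non-overlapping in-frame segment scan (multiple of 3) |
| input bounds | 15–99 bp | enforced by the CLI/reader to mirror the interactive use case; liftable (`enforce_bounds = FALSE`), the engine itself only needs a codon multiple |

## Numerical and design choices

* **Tie-break.** When several synonymous codons are co-minimal the
  lexicographically smallest (A < C < G < T) is reported, making output
  deterministic; `emit_co_minimal = TRUE` reports all of them, for users
  who want to pick by codon-usage preference instead. The tie-break is a
  package convention, not a biological claim.
* **Scan strategy.** The scanner visits every start position directly. A
  15-bp sliding window advanced one codon at a time is provided as
  `find_sites_windowed()` and proven equivalent (after deduplication) for
  motif footprints up to 13 bp in the test suite; the positional scan is
  simpler to verify and also covers footprints longer than a window.
* **Ordering.** Reports are sorted by start, then strand
  (`both` < `top` < `bottom`), then enzyme name in C-locale byte order —
  byte-stable across runs and platforms.
* **Summary statistics** consider only engineered reports
  (≥ 1 substitution): `distinct_sequences` counts distinct altered
  full-length sequences, `total_reported_res` counts report lines
  (isoschizomers and degenerate-motif overlaps inflate this relative to
  distinct sequences, by design), `palindromic_fraction` is the fraction
  of engineered reports with palindromic motifs. With no engineered
  reports the fraction is reported as 0 with a `no_new_sites` flag.
* **Segmented scans** run each segment independently; sites spanning a
  boundary are structurally absent, so per-segment totals can only fall
  short of the whole-sequence scan — a property the tests assert.
* **Degenerate inputs.** Empty filtered libraries warn and return an
  empty report; a motif longer than the sequence is skipped; infeasible
  placements are silent non-results, not errors.

## The synthetic-sequence generator

`generate_random_cds()` draws each codon uniformly from the 64 codons of
the standard code (61 when internal stops are forbidden, the default)
under a caller-supplied seed, leaving the session RNG untouched. It
emulates only the combinatorial structure of coding DNA — frame, synonym
classes, stop placement — and none of the compositional features of real
genes: codon-usage bias, GC content, dinucleotide structure, or splice-
site context. Passing tests on such sequences therefore demonstrates
algorithmic correctness (minimality, completeness, strand handling), not
that site yields on real genes will match any particular organism; yields
depend strongly on sequence composition and on the enzyme library used.

## Problem sizes used in the tests

Oracle-equivalence runs use 200 seeded 5-codon sequences (the exhaustive
synonym product grows as fast as $6^k$, so the oracle refuses more than 7
codons); framing equivalence uses 50 seeded 33-codon (99-bp) sequences;
the acceptance script surveys five 99-bp sequences and 100 oracle
comparisons. These sizes were chosen to exercise every code path many
times over while keeping the exhaustive enumerations well-conditioned.

## Known limitations

* The bundled library has 12 enzymes for demonstration and testing;
  absolute site counts are meaningful only relative to the library in
  use. A full REBASE-style table (several hundred motifs) can be loaded
  with `read_rebase_library()`; this package does not claim equivalence
  between any two libraries.
* Codon-usage bias, guide-RNA efficiency, PAM proximity and other repair-
  template design criteria are out of scope; the tool's output should be
  combined with those considerations downstream.
* Existing sites are reported (on request) but the tool never suggests
  *ablating* them.
* Only the standard nuclear genetic code is supported.
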