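# silentsites

Find every way a **minimal set of silent (synonymous) nucleotide
substitutions** creates a new restriction-endonuclease (RE) recognition site
in an in-frame coding sequence.

CRISPR/Cas9 homology-directed-repair designs routinely place an engineered
RE site next to the edit of interest, so that edited clones can be detected
by a quick PCR + digest (RFLP) screen. Designing such sites by hand is
error-prone: there are hundreds of candidate enzymes, many with degenerate
(IUPAC) recognition motifs, sites can sit on either strand, and every change
must leave the encoded peptide untouched. `silentsites` automates the
search and guarantees three properties for every reported site:

* **peptide preservation** — the altered sequence translates to exactly the
  input's peptide (stop codons are treated as a 21st residue class, so
  `TAA` may become `TAG` or `TGA`);
* **minimality** — no synonymous variant creates the same site with fewer
  substitutions (each codon overlapped by a motif placement is solved
  independently, which is globally optimal because placements never couple
  codons; an exhaustive brute-force oracle cross-checks this in the tests);
* **completeness** — every enzyme in the library, every placement, both
  strands. Palindromic motifs are reported once with strand `both`;
  substitutions may fall *outside* the motif footprint when a codon's only
  suitable synonym differs at an unconstrained position.

The formal core: for input codons $c_1 \dots c_k$ and a motif placement
covering positions $[s, s+L-1]$, each overlapped codon $c_j$ is replaced by

$$\arg\min_{c' \sim c_j,\; c' \models K_j} d_H(c_j, c'),$$

the synonymous codon ($c' \sim c_j$, standard genetic code) of minimal
Hamming distance satisfying the placement's allowed-base constraint $K_j$
(IUPAC sets projected onto codon offsets), ties broken lexicographically.
If some codon has no feasible synonym the placement is infeasible.

An enzyme's *cutter length* is the effective motif length: degenerate
symbols (`R`, `Y`, …) count as one position each, the fully unspecific `N`
counts as zero — so NlaIV (`GGNNCC`) is a 4-bp cutter and BanII (`GRGCYC`)
a 6-bp cutter.

## Worked example

```r
library(silentsites)
lib <- read_enzyme_library(bundled_enzymes())   # 12-enzyme demo library
rep <- find_sites("ATGGATCTTCGTCCTGGG", lib, min_cutter = 6)
write_reports(rep, format = "text")
```

```
AflII      CTTAAG        6  both   5 subs  ATGGA[ctTaaG]aCCTGGG
BsoBI      CYCGRG       12  both   2 subs  ATGGATCTTCG[cCCgGG]G
XmaI       CCCGGG       12  both   2 subs  ATGGATCTTCG[cCCgGG]G
BsoBI      CYCGRG       13  both   1 sub   ATGGATCTTCGT[CCcGGG]
XmaI       CCCGGG       13  both   1 sub   ATGGATCTTCGT[CCcGGG]

Distinct new sequences: 3
Total reported REs:     5
Palindromic fraction:   1.000
```

Reading the output: lowercase letters are the substituted bases, square
brackets delimit the new recognition site, and reports run 5′→3′. The
AflII line shows a 5-substitution edit whose last change (position 9, the
`a` after the bracket) lies *outside* the motif — the Arg codon `CGT` must
become `AGA` so that the site's final `AG` is in place. The XmaI site at
position 13 costs a single Pro wobble change (`CCT`→`CCC`), and the same
altered sequence simultaneously creates the BsoBI site (`CYCGRG` is
degenerate), which is why "total reported REs" exceeds "distinct new
sequences". All motifs here are palindromes, hence strand `both` and a
palindromic fraction of 1.

A machine-readable TSV (`format = "tsv"`) carries the same rows with
explicit substitution positions, and `summarize_sites()` returns the
summary block as a value. `segment_scan()` repeats the search in
non-overlapping in-frame segments; `read_rebase_library()` loads a full
REBASE-style enzyme table for production screening.

From a shell:

```sh
Rscript inst/scripts/silentsites --sequence ATGGATCTTCGTCCTGGG \
    --no-length-bounds --min-cutter 6 --format text
```

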