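---
title: "Functional characterization of coding SNPs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional characterization of coding SNPs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpchar)
```

`snpchar` characterizes single nucleotide polymorphisms located in open
reading frames, in the setting of a resequencing comparison between two
yeast strains: a reference strain (the S288c-style genome the reads were
mapped against) and a query strain (a CEN.PK-style industrial isolate).
This vignette is the package's account of the methods: what each stage
computes, the assumptions behind it, the parameters that matter, and where
the open design choices were settled.

## Coordinates and inputs

All SNP coordinates are 1-based, ORF-relative, on the coding strand. The
supplied ORF sequences are assumed to be spliced coding sequences beginning
at the ATG; translation is always frame 1. Genomic coordinates enter only
through `map_genomic_to_orf()`, which handles contiguous (intron-free) ORFs
on either strand, complementing bases on the minus strand. Alignment gap
characters are normalized to `-` on read (`.` is accepted), sequences are
uppercased, and `U` is rejected because inputs are DNA.

## Quality-filter cascade

Candidate SNP calls from short-read consensus calling carry five quality
fields: read depth `d`, maximum-depth context `D` (a guard against
collapsed repeats), region uniqueness `w`, consensus quality `Q` and
best-neighbour read quality `n` (phred-scaled). The default cascade is

    d > 5,  D < 255,  w < 1.5,  Q > 50,  n > 40,  not ambiguous.

All comparisons are **strict**: a candidate with `d = 5` or `Q = 50` is
rejected. The thresholds are written with strict operators in the filtering
tools this cascade mirrors, and we read them literally; an
`inclusive_bounds` switch is provided for sensitivity analysis. Rejected
candidates report *all* violated rule codes, not just the first, so a
filtering run can be audited column by column. The consensus-calling step
itself (read mapping, pileup) is out of scope: candidates enter this module
already called, from file or from the synthetic generator, and `w` is
treated as an opaque supplied score.

## Codon-effect classification

For a SNP at ORF position $p$, the codon index is $\lceil p/3 \rceil$ and
the within-codon offset $((p-1) \bmod 3) + 1$. The reference codon is read
from the ORF (after checking that the ORF base at $p$ equals the recorded
reference base — a mismatch is a hard consistency error naming gene,
position and both bases), the alternate base is substituted, and both
codons are translated under the standard nuclear genetic code. The effect
class is:

* `silent` — identical residues (including a stop codon mutating to a
  different stop codon, by the same equality rule);
* `nonsynonymous_missense` — different non-stop residues;
* `nonsynonymous_nonsense` — a new premature stop;
* `stop_loss` — the reference stop read through.

Reports that need the two-way split used in strain-comparison tables
aggregate the last three as "nonsynonymous" (`is_nonsynonymous()`); the
four-way class is kept in per-record output. Only the standard nuclear code
is wired in — the genes of interest are nuclear — but the translation table
is a single named vector internally, so an alternative table is a small
change. Batch classification collects per-record errors (reference
mismatches, `N` in the affected codon, length not a multiple of three) into
an `error` column and continues by default; `strict = TRUE` aborts on the
first error. The default suits large SNP batches where a handful of
malformed records should not abort the run.

Multi-nucleotide variants, indels, frameshifts and splice effects are out
of scope.

## Amino-acid property scheme

The packaged scheme (`inst/extdata/aa_property_scheme.tsv`) is an
overlapping Taylor / Livingstone–Barton classification: `polar` is
{C,D,E,H,K,N,Q,R,S,T,W,Y}, `non-polar` its complement, with further labels
`hydrophobic`, `hydrophilic`, `hydroxylic` {S,T,Y}, `charged`, `positive`,
`negative`, `aliphatic` {I,L,V}, `aromatic` {F,H,W,Y}, `small`, `tiny`,
`sulphur-containing` {C,M} and `amidic` {N,Q}. `polar`/`non-polar` are
mutually exclusive per residue; the stop symbol carries no labels. One
deliberate adjustment: serine is classified hydroxylic and polar but **not**
hydrophobic, although some published hydrophobicity sets include it. This
keeps the canonical alanine-to-serine narrative clean — the substitution
loses {non-polar, hydrophobic} and gains {polar, hydroxylic} — and makes a
serine-rich alignment column read, e.g., 75% polar / 25% non-polar / 25%
hydrophobic / 75% hydroxylic when six of eight ungapped homologue residues
are serine and two are alanine. The scheme is a data file and can be
replaced wholesale via `default_property_scheme(path)`.

Column profiles (`column_property_frequencies`) exclude gapped rows from
the denominator and, by default, the reference row too: the frequencies
describe the homologues, against which the reference is then compared.
Because labels overlap, fractions do not sum to one.

## Conservation statistics

For a nonsynonymous SNP with reference residue $r$ and variant residue $v$
at reference-protein position $i$, the aligned column is located by
counting non-gap characters in the reference row. Over the $n$ ungapped
homologue residues at that column (the reference row is excluded from all
denominators):

* reference match frequency $f_r$ = fraction equal to $r$;
* variant match frequency $f_v$ = fraction equal to $v$;
* dominant-residue frequency = the maximum residue frequency (ties broken
  alphabetically for the reported residue; the frequency itself is
  tie-invariant);
* **Conservation Distance** $= f_r - f_v \in [-1, +1]$.

The distance is $+1$ when every homologue carries the reference residue and
none the variant (the substitution looks disruptive), $-1$ in the opposite
extreme (the variant is the conserved state), and $0$ for a silent change
or an even split. It is antisymmetric under swapping $r$ and $v$, and
fully-gapped homologue rows never affect it. The subtraction form is our
interpretation: it is the simplest definition bounded in $[-1, 1]$ that
attains $+1$/$-1$ at exactly the two uniform extremes; published summaries
of the statistic state the bounds and extremes but not the formula.

Homologue sets are taken as the alignment file provides them;
`top_k_homologs()` truncates to the first $k$ (default 10, the usual
"top 10 homologues" convention) in file order, since family-database rank
criteria are not part of the alignment format. Whether the query strain
itself should be counted among the homologues is a corpus-construction
question; the package's convention is that the reference row never is.

`mean_conservation_distance()` reports the arithmetic mean and sample
standard deviation ($n-1$); with a single value the deviation is undefined
and reported as 0 with `sd_defined = FALSE`.

## Enrichment

`hypergeom_upper_tail(k, n, K, N)` is $P(X \ge k)$ for
$X \sim \mathrm{Hypergeometric}(N, K, n)$, the standard one-sided
over-representation probability, evaluated through `phyper(..., lower.tail
= FALSE)`, which computes in log space and is stable for genome-scale
counts. The tail includes $k$. `enrich()` tests every term, adjusts across
terms by Benjamini–Hochberg (Bonferroni available), sorts by raw p-value
and flags `p_adj < alpha` (default 0.01). The universe defaults to all
annotated genes plus the study genes — the "complete gene set" convention —
and is overridable; terms with no gene in the universe are skipped rather
than reported with $K = 0$. Gene-ontology graph propagation and
conditional/eliminating enrichment variants are out of scope.

## Synthetic-data generator

The generator emulates the inputs of a strain-resequencing comparison at
desk scale, with ground truth recorded at generation time:

* **ORFs** — start codon, stop codon, no internal stop; internal codons
  uniform over the 61 non-stop codons (no codon-usage model — the analysis
  stages are composition-agnostic, so this simplification costs nothing
  downstream).
* **SNPs** — Poisson count per gene; each SNP is assigned a silent or
  nonsynonymous target label so the realized nonsynonymous fraction is the
  closest achievable to `target_nonsyn_fraction`, then position and
  alternate base are rejection-sampled until the true codon consequence
  matches the label. Default target 0.233, the nonsynonymous share
  characteristic of metabolic-gene SNP sets in laboratory-strain
  comparisons.
* **Quality fields** — drawn so that a candidate passes the default
  cascade exactly when its recorded `pass` flag is true; the failing draws
  violate one or two randomly chosen rules. Default pass fraction 0.56,
  the approximate filtered-to-non-ambiguous ratio seen in such comparisons.
* **Alignments** — the reference row is the translated ORF; each homologue
  residue copies the reference with probability `column_conservation`
  (default 0.5, i.e. no built-in bias toward either strain) or is a
  uniformly drawn different residue; optional gap injection. Column
  overrides force `all_ref` (+1 distance), `all_variant` (−1) or an even
  `mix` composition at chosen positions, for extreme-case fixtures.
* **Annotations** — a handful of terms with gene sets sampled from the
  generated genes.

Each artifact draws from its own sub-stream of the master seed, so
regenerating one artifact never perturbs the others, and identical
configurations yield byte-identical files. The shipped demo fixture
(`demo_dataset_dir()`) is exactly `simulate_dataset(demo_config())` — 20
genes, ~100 SNPs, 10 homologues, 5 terms — and a test asserts that
equality.

What the generator does **not** emulate: sequencing reads and error
models, phylogenetically structured homologues (residues are i.i.d. per
column), codon usage, linkage between nearby SNPs, and real annotation
topology. Passing tests on generated data therefore demonstrate the
correctness of the analysis logic — classification, counting, set algebra,
tail probabilities — not robustness to read-level artifacts, which are
upstream of this package's inputs.

## Numerical conventions and problem sizes

* Percentages are stored at full precision and displayed to one decimal
  (`format_pct_nonsyn`), so 219 of 939 prints as 23.3 and 3 of 36 as 8.3.
* Filter comparisons are strict; the generator deliberately avoids drawing
  values on the thresholds so pass/fail flags are unambiguous.
* Dominant-residue ties break alphabetically, affecting only the reported
  residue, never the frequency.
* The test suite sizes its simulations for sub-minute runs: ~1,000 spiked
  SNPs for fraction-recovery checks, 219 columns for the symmetric
  conservation-mean check, 10,000 candidates for filter properties, full
  enumeration (576 codon substitutions; all hypergeometric instances with
  $N \le 12$) where exhaustiveness is cheap.

## Known limitations

The Conservation Distance formula is an anchored interpretation (see
above); alternative definitions agreeing at the extremes but differing in
between would need their own validation. The property scheme is one
defensible overlapping classification among several; conclusions sensitive
to, e.g., threonine's hydrophobicity should re-run with a custom scheme
file. Headline counts from real strain comparisons (tens of thousands of
filtered SNPs) depend on raw reads and database snapshots outside this
package's scope; the package reproduces the analytic machinery, not those
datasets.
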