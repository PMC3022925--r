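# snpchar

Functional characterization of coding SNPs between yeast strains.

When two *Saccharomyces cerevisiae* strains — say the S288c reference and an
industrial laboratory strain such as CEN.PK113-7D — are compared by whole
genome resequencing, the raw product is a long list of candidate single
nucleotide polymorphisms. The biological questions come after: which calls
are trustworthy, which coding SNPs actually change the protein, how unusual
the substituted residue is among homologous proteins, and whether the
affected genes pile up in particular pathways. `snpchar` implements that
downstream analysis as a tested, reusable pipeline:

1. **Quality filtering** (`filter_candidates`) — the MAQ-style threshold
   cascade on candidate calls: read depth *d* > 5, depth context *D* < 255,
   region uniqueness *w* < 1.5, consensus quality *Q* > 50 and best-neighbour
   quality *n* > 40, all strict, plus removal of ambiguous consensus calls.
2. **Codon-effect classification** (`classify_snp_effect`, `classify_all`) —
   each ORF-relative SNP is mapped to its codon (index ⌈pos/3⌉, offset
   ((pos−1) mod 3)+1), both codons translated under the standard nuclear
   genetic code, and the effect called silent, missense, nonsense or
   stop-loss.
3. **Amino-acid property profiling** (`property_change`,
   `column_property_frequencies`) — an overlapping Taylor/Livingstone–Barton
   classification (polar, non-polar, hydrophobic, hydroxylic, charged, …)
   describes what a substitution changes, and how the properties are
   distributed down a homologue alignment column.
4. **Conservation statistics** (`conservation_stats`) — at the aligned column
   of a nonsynonymous SNP, over the ungapped homologue residues: the
   reference (S288c) match frequency *f_ref*, the variant (CEN.PK) match
   frequency *f_var*, the dominant-residue frequency, and the

   **Conservation Distance** = *f_ref* − *f_var* ∈ [−1, +1],

   +1 when the homologues uniformly support the reference residue, −1 when
   they uniformly support the variant.
5. **Term enrichment** (`enrich`) — upper-tail hypergeometric
   over-representation P(X ≥ k) of a study gene set against a background
   universe, Benjamini–Hochberg corrected (Bonferroni optional).
6. **Reporting** (`summarize_snp_effects`, `per_gene_rollup`) — summary
   counts with the percent-nonsynonymous displayed to one decimal.
7. **Synthetic data** (`sim_config`, `simulate_dataset`) — a fully seeded
   generator producing ORFs, candidate SNPs with known effect labels and
   MAQ-like quality fields, homologue alignments with controlled per-column
   conservation, and annotation tables, so every stage is testable offline.

The intended users are strain engineers and genome analysts who have per-ORF
SNP tables and homologue alignments in hand and want the characterization
steps to be reproducible and unit-tested rather than spreadsheet-bound.

## Worked example

The package ships a deterministic demonstration dataset (20 synthetic genes,
~100 candidate SNPs, 10 homologues per gene; see `demo_config()`):

```r
library(snpchar)
dir <- demo_dataset_dir()
orfs <- read_orf_fasta(file.path(dir, "orfs.fasta"))
cand <- read_candidate_table(file.path(dir, "candidates.tsv"))

filt <- filter_candidates(cand)
eff  <- classify_all(orfs, filt$passed)
summarize_snp_effects(eff, orfs$gene_id)
```

```
SNP summary
  Genes considered:               20
  SNPs detected:                  52
  Nonsynonymous SNPs:             12
  Percent nonsynonymous (%):      23.1
  Genes containing SNP:           17
  Genes with nonsynonymous SNP:   9
```

Of 107 candidates, 52 survive the quality cascade; 12 of those change the
protein, and the one-decimal percentage (23.1%) is the figure a strain
comparison table would report. Profiling the first nonsynonymous SNP of gene
G001 against its homologue alignment:

```r
aln <- read_alignment(file.path(dir, "alignments", "G001.afa"),
                      "aligned-fasta", reference_row_id = "G001_S288c",
                      gene_id = "G001")
conservation_stats(aln, 31, "G", "A")
```

```
  gene_id protein_position ref_aa variant_aa s288c_match_freq cenpk_match_freq
1    G001               31      G          A              0.5              0.1
  dominant_aa dominant_aa_freq conservation_distance n_homologs
1           G              0.5                   0.4         10
```

Half the homologues carry the reference glycine and only one carries the
variant alanine, giving a Conservation Distance of +0.4: the reference
residue is the better-conserved choice at this position. A substitution that
does change residue class prints its label movement explicitly:

```r
property_change("A", "S")
```

```
A -> S
  lost:   non-polar, hydrophobic
  gained: polar, hydroxylic
  shared: small, tiny
```

Finally, hypergeometric enrichment of the nonsynonymous-SNP genes against
the demo annotation returns per-term p-values and BH-adjusted q-values
(nothing is enriched in this null-like demo, as expected):

```r
ann   <- read_annotation_table(file.path(dir, "annotations.tsv"))
study <- unique(eff$gene_id[is_nonsynonymous(eff$effect_class)])
enrich(study, ann, universe = orfs$gene_id, alpha = 0.05)
```

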