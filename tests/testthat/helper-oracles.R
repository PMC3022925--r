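# Independent oracles and small fixture builders used across the suite.

# Translate a codon with seqinr (independent of the package's codon table).
oracle_translate <- function(codon) {
  seqinr::translate(strsplit(tolower(codon), "", fixed = TRUE)[[1]])
}

# Exhaustive-draw hypergeometric oracle: enumerate every C(N, n) subset of a
# universe whose first K elements are annotated; P(X >= k) is the fraction of
# draws containing at least k annotated elements.
oracle_hyper_tail_counts <- function(N, n, K) {
  draws <- utils::combn(N, n)
  colSums(draws <= K)
}

# Build an alignment whose single interesting column (at protein position
# `pos` of an all-M reference of length `len`) holds `column` residues.
column_alignment <- function(column, pos = 3L, len = 6L, gene = "GENE1") {
  ref <- strrep("M", len)
  rows <- vapply(column, function(r) {
    row <- ref
    substr(row, pos, pos) <- r
    row
  }, character(1))
  names(rows) <- sprintf("hom%02d", seq_along(rows))
  homolog_alignment(gene, "ref", c(ref = ref, rows))
}

# 729-nt ORF whose codon 98 is TAT, mirroring a premature-stop worked example.
pad1_like_orf <- function() {
  codons <- rep("GGT", 243)
  codons[1] <- "ATG"
  codons[98] <- "TAT"
  codons[243] <- "TAA"
  list(gene_id = "PAD1", sequence = paste(codons, collapse = ""))
}

# All 576 single-base codon substitutions (64 codons x 3 offsets x 3 alts).
all_codon_substitutions <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1L, paste, collapse = "")
  out <- expand.grid(codon = codons, offset = 1:3, alt = bases,
                     stringsAsFactors = FALSE)
  out$ref <- substr(out$codon, out$offset, out$offset)
  out[out$ref != out$alt, ]
}
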