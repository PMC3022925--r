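EFFECT_CLASSES <- c("silent", "nonsynonymous_missense",
                    "nonsynonymous_nonsense", "stop_loss")

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  if (anyNA(aa)) {
    stop("indeterminate codon (non-ACGT base): ",
         paste(codon[is.na(aa)], collapse = ", "), call. = FALSE)
  }
  unname(aa)
}

#' Classify the codon-level effect of a single SNP
#'
#' Locates the codon containing the SNP (frame-1 reading of the supplied
#' coding sequence), substitutes the alternate base, translates both codons
#' under the standard nuclear genetic code, and classifies the effect:
#' `silent` (identical residues, including stop-to-stop), `nonsynonymous_missense`,
#' `nonsynonymous_nonsense` (new premature stop) or `stop_loss` (reference
#' stop read through).
#'
#' @param orf A single-row `orf_set`, or any list/row with `gene_id` and
#'   `sequence`.
#' @param snp A single-row `snp_table`, or a list with `gene_id`, `position`,
#'   `ref`, `alt`.
#' @return A one-row data frame of class `codon_effects` with columns
#'   `gene_id`, `position`, `ref`, `alt`, `codon_index`, `codon_offset`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `effect_class`.
#' @examples
#' orf <- list(gene_id = "DEMO", sequence = "ATGGCTTAA")
#' snp <- list(gene_id = "DEMO", position = 6, ref = "T", alt = "C")
#' classify_snp_effect(orf, snp)
#' @export
classify_snp_effect <- function(orf, snp) {
  seq <- toupper(orf$sequence[[1]])
  gene <- orf$gene_id[[1]]
  pos <- as.integer(snp$position[[1]])
  ref <- toupper(snp$ref[[1]])
  alt <- toupper(snp$alt[[1]])
  len <- nchar(seq)
  if (len %% 3L != 0L) {
    stop("frame error: ORF ", gene, " length ", len, " is not a multiple of 3",
         call. = FALSE)
  }
  if (pos < 1L || pos > len) {
    stop("position ", pos, " outside ORF ", gene, " (length ", len, ")",
         call. = FALSE)
  }
  found <- substr(seq, pos, pos)
  if (found != ref) {
    stop("reference base mismatch in ", gene, " at position ", pos,
         ": expected ", ref, ", found ", found, call. = FALSE)
  }
  codon_index <- (pos - 1L) %/% 3L + 1L
  codon_offset <- (pos - 1L) %% 3L + 1L
  start <- (codon_index - 1L) * 3L + 1L
  ref_codon <- substr(seq, start, start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, codon_offset, codon_offset) <- alt
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  effect <- if (ref_aa == alt_aa) "silent"
    else if (alt_aa == "*") "nonsynonymous_nonsense"
    else if (ref_aa == "*") "stop_loss"
    else "nonsynonymous_missense"
  out <- data.frame(gene_id = gene, position = pos, ref = ref, alt = alt,
                    codon_index = codon_index, codon_offset = codon_offset,
                    ref_codon = ref_codon, alt_codon = alt_codon,
                    ref_aa = ref_aa, alt_aa = alt_aa, effect_class = effect,
                    stringsAsFactors = FALSE)
  class(out) <- c("codon_effects", "data.frame")
  out
}

#' Classify codon effects for a batch of SNPs
#'
#' One `codon_effects` row per input SNP, in input order. By default,
#' per-record errors (reference-base mismatch, indeterminate codon, frame
#' error) are collected in an `error` column and the batch continues; with
#' `strict = TRUE` the first error aborts.
#'
#' @param orfs An `orf_set` covering every referenced gene.
#' @param snps A `snp_table` (or compatible data frame).
#' @param strict Abort on the first record-level error instead of collecting.
#' @return A data frame of class `codon_effects`; failed records (non-strict
#'   mode) have `NA` effect fields and a message in `error`.
#' @export
classify_all <- function(orfs, snps, strict = FALSE) {
  idx <- match(snps$gene_id, orfs$gene_id)
  if (anyNA(idx)) {
    stop("unknown gene_id in SNP input: ",
         paste(unique(snps$gene_id[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  rows <- vector("list", nrow(snps))
  errors <- character(nrow(snps))
  for (i in seq_len(nrow(snps))) {
    res <- tryCatch(classify_snp_effect(orfs[idx[i], ], snps[i, ]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      if (strict) stop(res)
      errors[i] <- conditionMessage(res)
      rows[[i]] <- data.frame(gene_id = snps$gene_id[i],
                              position = as.integer(snps$position[i]),
                              ref = snps$ref[i], alt = snps$alt[i],
                              codon_index = NA_integer_, codon_offset = NA_integer_,
                              ref_codon = NA_character_, alt_codon = NA_character_,
                              ref_aa = NA_character_, alt_aa = NA_character_,
                              effect_class = NA_character_,
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- as.data.frame(res)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      codon_index = integer(0), codon_offset = integer(0),
                      ref_codon = character(0), alt_codon = character(0),
                      ref_aa = character(0), alt_aa = character(0),
                      effect_class = character(0), stringsAsFactors = FALSE)
  }
  if (any(nzchar(errors))) out$error <- errors
  class(out) <- c("codon_effects", "data.frame")
  out
}

#' Test whether an effect class counts as nonsynonymous
#'
#' The two-way silent/nonsynonymous rollup groups missense, nonsense and
#' stop-loss together; the four-way class is kept in per-record output.
#'
#' @param effect_class Character vector of effect classes.
#' @return Logical vector.
#' @export
is_nonsynonymous <- function(effect_class) {
  effect_class %in% c("nonsynonymous_missense", "nonsynonymous_nonsense",
                      "stop_loss")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Map a genomic coordinate onto an ORF-relative coordinate
#'
#' For a contiguous (intron-free) ORF spanning `[orf_start, orf_end]` on a
#' chromosome: on the `+` strand the ORF position is the offset from
#' `orf_start` and bases are unchanged; on the `-` strand positions count
#' back from `orf_end` and both bases are complemented.
#'
#' @param genomic_pos 1-based chromosome coordinate.
#' @param orf_start,orf_end 1-based genomic span of the ORF.
#' @param strand `"+"` or `"-"`.
#' @param ref_base,alt_base Bases as reported on the genomic forward strand.
#' @return A list with `orf_position`, `ref` and `alt` (coding-strand
#'   oriented).
#' @export
map_genomic_to_orf <- function(genomic_pos, orf_start, orf_end, strand,
                               ref_base, alt_base) {
  strand <- match.arg(strand, c("+", "-"))
  if (genomic_pos < orf_start || genomic_pos > orf_end) {
    stop("genomic position ", genomic_pos, " outside ORF span [",
         orf_start, ", ", orf_end, "]", call. = FALSE)
  }
  if (strand == "+") {
    list(orf_position = genomic_pos - orf_start + 1L,
         ref = toupper(ref_base), alt = toupper(alt_base))
  } else {
    list(orf_position = orf_end - genomic_pos + 1L,
         ref = unname(COMPLEMENT[toupper(ref_base)]),
         alt = unname(COMPLEMENT[toupper(alt_base)]))
  }
}

#' Write a codon-effect table as TSV
#'
#' @param effects A `codon_effects` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(effects, path) {
  write.table(as.data.frame(effects), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = ".")
  invisible(path)
}
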