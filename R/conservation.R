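#' Locate the aligned column for a reference protein position
#'
#' Returns the alignment column holding the `protein_position`-th non-gap
#' character of the reference row, so ungapped (protein) coordinates can be
#' carried into a gapped multiple alignment.
#'
#' @param alignment A `homolog_alignment`.
#' @param protein_position 1-based ungapped residue index in the reference
#'   row.
#' @return Integer aligned column index.
#' @export
locate_alignment_column <- function(alignment, protein_position) {
  ref <- strsplit(alignment$rows[[alignment$reference_row_id]], "", fixed = TRUE)[[1]]
  nongap <- cumsum(ref != "-")
  hit <- which(ref != "-" & nongap == protein_position)
  if (length(hit) == 0L) {
    stop("protein position ", protein_position,
         " beyond reference ungapped length ", max(nongap), call. = FALSE)
  }
  hit[1]
}

#' Per-SNP conservation statistics over a homologue alignment column
#'
#' At the alignment column of the affected residue, over the ungapped
#' homologue residues (the reference row is excluded from denominators):
#' the reference-strain match frequency (fraction equal to `ref_aa`, the
#' S288c-style reference residue), the variant match frequency (fraction
#' equal to `variant_aa`, the CEN.PK-style variant), the dominant-residue
#' frequency, and the Conservation Distance, defined as reference match
#' frequency minus variant match frequency. The distance is bounded in
#' `[-1, 1]`: +1 when every homologue carries the reference residue and none
#' the variant, -1 in the opposite extreme.
#'
#' @param alignment A `homolog_alignment` whose reference row is the
#'   reference-strain protein.
#' @param protein_position 1-based residue index in the (ungapped) reference
#'   protein.
#' @param ref_aa Reference residue; checked against the reference row.
#' @param variant_aa Variant residue encoded by the nonsynonymous SNP.
#' @return A one-row data frame of class `conservation_stats` with columns
#'   `gene_id`, `protein_position`, `ref_aa`, `variant_aa`,
#'   `s288c_match_freq`, `cenpk_match_freq`, `dominant_aa`,
#'   `dominant_aa_freq`, `conservation_distance`, `n_homologs`.
#' @export
conservation_stats <- function(alignment, protein_position, ref_aa, variant_aa) {
  column <- locate_alignment_column(alignment, protein_position)
  ref_row <- alignment$rows[[alignment$reference_row_id]]
  found <- substr(ref_row, column, column)
  if (found != ref_aa) {
    stop("reference residue mismatch in ", alignment$gene_id,
         " at protein position ", protein_position, ": expected ", ref_aa,
         ", alignment has ", found, call. = FALSE)
  }
  homologs <- alignment$rows[names(alignment$rows) != alignment$reference_row_id]
  residues <- substr(homologs, column, column)
  residues <- residues[residues != "-"]
  n <- length(residues)
  if (n == 0L) {
    stop("no ungapped homologue residues at column ", column, " of ",
         alignment$gene_id, call. = FALSE)
  }
  s288c <- sum(residues == ref_aa) / n
  cenpk <- sum(residues == variant_aa) / n
  freq <- table(residues) / n
  dom_freq <- max(freq)
  dom_aa <- sort(names(freq)[freq == dom_freq])[1]  # ties: alphabetical
  out <- data.frame(gene_id = alignment$gene_id,
                    protein_position = as.integer(protein_position),
                    ref_aa = ref_aa, variant_aa = variant_aa,
                    s288c_match_freq = s288c, cenpk_match_freq = cenpk,
                    dominant_aa = dom_aa, dominant_aa_freq = as.numeric(dom_freq),
                    conservation_distance = s288c - cenpk,
                    n_homologs = n, stringsAsFactors = FALSE)
  class(out) <- c("conservation_stats", "data.frame")
  out
}

#' Truncate a homologue alignment to its first k homologues
#'
#' Keeps the reference row plus the first `top_k` homologue rows in file
#' order, mirroring a "top 10 homologues" selection from a family-database
#' query.
#'
#' @param alignment A `homolog_alignment`.
#' @param top_k Number of homologue rows to keep (default 10).
#' @return A `homolog_alignment`.
#' @export
top_k_homologs <- function(alignment, top_k = 10L) {
  hom_ids <- setdiff(alignment$row_ids, alignment$reference_row_id)
  keep <- c(alignment$reference_row_id, utils::head(hom_ids, top_k))
  new_homolog_alignment(alignment$gene_id, alignment$reference_row_id,
                        alignment$rows[alignment$row_ids[alignment$row_ids %in% keep]])
}

#' Mean and spread of Conservation Distance values
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of a set
#' of per-SNP Conservation Distances. With a single value the standard
#' deviation is undefined and reported as 0, flagged by `sd_defined = FALSE`.
#'
#' @param x A numeric vector of Conservation Distances, or a
#'   `conservation_stats` data frame (its `conservation_distance` column is
#'   used).
#' @return A list with `mean`, `sd`, `n` and `sd_defined`.
#' @export
mean_conservation_distance <- function(x) {
  if (is.data.frame(x)) x <- x$conservation_distance
  x <- as.numeric(x)
  if (length(x) == 0L) stop("no Conservation Distance values supplied", call. = FALSE)
  n <- length(x)
  list(mean = mean(x),
       sd = if (n > 1L) stats::sd(x) else 0,
       n = n,
       sd_defined = n > 1L)
}

#' Conservation statistics for a batch of classified SNPs
#'
#' Runs [conservation_stats()] for every nonsynonymous effect whose gene has
#' a homologue alignment. The protein position is the codon index; the
#' reference and variant residues come from the effect classification.
#'
#' @param effects A `codon_effects` data frame.
#' @param alignments A named list of `homolog_alignment` objects keyed by
#'   `gene_id`.
#' @param nonsynonymous_only Restrict to nonsynonymous effects
#'   (default `TRUE`; silent SNPs have distance 0 by construction).
#' @return A `conservation_stats` data frame with one row per profiled SNP.
#' @export
conservation_profile <- function(effects, alignments, nonsynonymous_only = TRUE) {
  eff <- as.data.frame(effects)
  if ("error" %in% names(eff)) eff <- eff[!nzchar(eff$error), , drop = FALSE]
  if (nonsynonymous_only) {
    eff <- eff[is_nonsynonymous(eff$effect_class), , drop = FALSE]
  }
  rows <- vector("list", nrow(eff))
  for (i in seq_len(nrow(eff))) {
    aln <- alignments[[eff$gene_id[i]]]
    if (is.null(aln)) {
      stop("no homologue alignment supplied for gene ", eff$gene_id[i],
           call. = FALSE)
    }
    rows[[i]] <- as.data.frame(
      conservation_stats(aln, eff$codon_index[i], eff$ref_aa[i], eff$alt_aa[i]))
    rows[[i]]$snp_position <- eff$position[i]
  }
  out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
         else data.frame()
  class(out) <- c("conservation_stats", "data.frame")
  out
}

#' Write a conservation-statistics table as TSV
#'
#' @param stats A `conservation_stats` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_conservation_table <- function(stats, path) {
  write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = ".")
  invisible(path)
}
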