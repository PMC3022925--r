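#' Build a summary-count record from raw counts
#'
#' Container for per-strain SNP summary counts in the style of a
#' "metabolism-focused detection" table: genes considered, SNPs detected,
#' nonsynonymous SNPs, and gene-level tallies. The nonsynonymous percentage
#' is stored at full precision and displayed to one decimal, so totals of
#' 939 SNPs with 219 nonsynonymous display as 23.3 and 36 with 3 as 8.3.
#'
#' @param n_snps_total Total SNPs detected.
#' @param n_snps_nonsyn Nonsynonymous SNPs (missense + nonsense + stop-loss).
#' @param n_genes_considered Genes queried (0 if unknown).
#' @param n_genes_with_snp Genes carrying at least one SNP.
#' @param n_genes_with_nonsyn Genes carrying at least one nonsynonymous SNP.
#' @return A list of class `snp_summary`.
#' @examples
#' s <- snp_summary(939, 219, n_genes_considered = 782,
#'                  n_genes_with_snp = 158, n_genes_with_nonsyn = 85)
#' format_pct_nonsyn(s)
#' @export
snp_summary <- function(n_snps_total, n_snps_nonsyn, n_genes_considered = 0L,
                        n_genes_with_snp = 0L, n_genes_with_nonsyn = 0L) {
  if (n_snps_nonsyn > n_snps_total) {
    stop("nonsynonymous count exceeds total SNP count", call. = FALSE)
  }
  if (n_genes_with_nonsyn > n_genes_with_snp) {
    stop("genes with nonsynonymous SNP exceed genes with SNP", call. = FALSE)
  }
  structure(list(n_genes_considered = as.integer(n_genes_considered),
                 n_snps_total = as.integer(n_snps_total),
                 n_snps_nonsyn = as.integer(n_snps_nonsyn),
                 pct_nonsyn = if (n_snps_total > 0)
                   100 * n_snps_nonsyn / n_snps_total else 0,
                 n_genes_with_snp = as.integer(n_genes_with_snp),
                 n_genes_with_nonsyn = as.integer(n_genes_with_nonsyn)),
            class = "snp_summary")
}

#' Display-format the nonsynonymous percentage
#'
#' @param x A `snp_summary`.
#' @return Character scalar, one decimal place.
#' @export
format_pct_nonsyn <- function(x) {
  sprintf("%.1f", x$pct_nonsyn)
}

#' @export
print.snp_summary <- function(x, ...) {
  cat("SNP summary\n")
  cat(sprintf("  Genes considered:               %d\n", x$n_genes_considered))
  cat(sprintf("  SNPs detected:                  %d\n", x$n_snps_total))
  cat(sprintf("  Nonsynonymous SNPs:             %d\n", x$n_snps_nonsyn))
  cat(sprintf("  Percent nonsynonymous (%%):      %s\n", format_pct_nonsyn(x)))
  cat(sprintf("  Genes containing SNP:           %d\n", x$n_genes_with_snp))
  cat(sprintf("  Genes with nonsynonymous SNP:   %d\n", x$n_genes_with_nonsyn))
  invisible(x)
}

#' Summarize classified SNP effects
#'
#' Rolls a batch of codon effects up to summary counts. "Nonsynonymous"
#' aggregates missense, nonsense and stop-loss (the two-way
#' silent/nonsynonymous split); records that failed classification are
#' excluded.
#'
#' @param effects A `codon_effects` data frame.
#' @param considered_genes Gene ids of the query set (every effect's gene
#'   must be among them).
#' @return A `snp_summary`.
#' @export
summarize_snp_effects <- function(effects, considered_genes) {
  eff <- as.data.frame(effects)
  if ("error" %in% names(eff)) eff <- eff[!nzchar(eff$error), , drop = FALSE]
  unknown <- setdiff(unique(eff$gene_id), considered_genes)
  if (length(unknown)) {
    stop("effect(s) reference gene(s) outside the considered set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  nonsyn <- is_nonsynonymous(eff$effect_class)
  snp_summary(n_snps_total = nrow(eff),
              n_snps_nonsyn = sum(nonsyn),
              n_genes_considered = length(unique(considered_genes)),
              n_genes_with_snp = length(unique(eff$gene_id)),
              n_genes_with_nonsyn = length(unique(eff$gene_id[nonsyn])))
}

#' Per-gene SNP counts
#'
#' @param effects A `codon_effects` data frame.
#' @return A data frame with one row per gene carrying at least one SNP and
#'   columns `gene_id`, `n_snps`, `n_nonsyn`; column sums equal the global
#'   totals.
#' @export
per_gene_rollup <- function(effects) {
  eff <- as.data.frame(effects)
  if ("error" %in% names(eff)) eff <- eff[!nzchar(eff$error), , drop = FALSE]
  if (nrow(eff) == 0L) {
    return(data.frame(gene_id = character(0), n_snps = integer(0),
                      n_nonsyn = integer(0), stringsAsFactors = FALSE))
  }
  genes <- unique(eff$gene_id)
  nonsyn <- is_nonsynonymous(eff$effect_class)
  data.frame(gene_id = genes,
             n_snps = vapply(genes, function(g) sum(eff$gene_id == g), integer(1)),
             n_nonsyn = vapply(genes, function(g)
               sum(nonsyn[eff$gene_id == g]), integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a summary report
#'
#' @param x A `snp_summary`.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  fields <- list(n_genes_considered = x$n_genes_considered,
                 n_snps_total = x$n_snps_total,
                 n_snps_nonsyn = x$n_snps_nonsyn,
                 pct_nonsyn = x$pct_nonsyn,
                 pct_nonsyn_display = format_pct_nonsyn(x),
                 n_genes_with_snp = x$n_genes_with_snp,
                 n_genes_with_nonsyn = x$n_genes_with_nonsyn)
  if (format == "json") {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  } else {
    write.table(data.frame(field = names(fields),
                           value = vapply(fields, as.character, ""),
                           stringsAsFactors = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
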