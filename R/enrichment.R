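#' Upper-tail hypergeometric probability
#'
#' The probability of drawing at least `k` annotated genes when `n` genes are
#' sampled without replacement from a universe of `N` genes of which `K`
#' carry the annotation: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. The
#' upper tail includes `k` itself (the standard over-representation
#' convention) and is evaluated through `stats::phyper`, which works in log
#' space and is numerically stable for large counts.
#'
#' @param k Observed annotated genes in the study set.
#' @param n Study set size.
#' @param K Annotated genes in the universe.
#' @param N Universe size.
#' @return The tail probability, a number in `[0, 1]`.
#' @examples
#' hypergeom_upper_tail(4, 4, 5, 10)  # C(5,4)*C(5,0)/C(10,4) = 5/210
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || K > N || n > N || k > min(n, K)) {
    stop("hypergeometric bounds violated: need 0 <= k <= min(n, K), n <= N, K <= N",
         call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric term enrichment with multiple-testing correction
#'
#' Tests each annotation term for over-representation in a study gene set
#' (for example, the genes carrying nonsynonymous SNPs) against a background
#' universe, using the upper-tail hypergeometric probability, and corrects
#' across terms (Benjamini-Hochberg by default, Bonferroni optionally).
#' Terms with no annotated gene in the universe are skipped.
#'
#' @param study Character vector of study gene ids (must lie in `universe`).
#' @param annotations Long-format annotation data frame with columns
#'   `gene_id`, `term_id`, `term_name` (see [read_annotation_table()]).
#' @param universe Background gene ids; defaults to all annotated genes plus
#'   all study genes.
#' @param alpha Significance threshold on the adjusted p-value
#'   (default 0.01).
#' @param correction `"BH"` or `"bonferroni"`.
#' @return A data frame of class `enrichment_results`, one row per term,
#'   sorted by ascending p-value, with columns `term_id`, `term_name`, `k`,
#'   `n`, `K`, `N`, `p_value`, `p_adj`, `enriched`.
#' @export
enrich <- function(study, annotations, universe = NULL, alpha = 0.01,
                   correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  study <- unique(as.character(study))
  if (is.null(universe)) {
    universe <- union(unique(annotations$gene_id), study)
  }
  universe <- unique(as.character(universe))
  missing <- setdiff(study, universe)
  if (length(missing)) {
    stop("study gene(s) absent from universe: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n <- length(study)
  terms <- split(annotations$gene_id, annotations$term_id)
  term_names <- tapply(annotations$term_name, annotations$term_id,
                       function(x) x[1])
  rows <- lapply(names(terms), function(tid) {
    genes <- intersect(unique(terms[[tid]]), universe)
    K <- length(genes)
    if (K == 0L) return(NULL)
    k <- length(intersect(genes, study))
    data.frame(term_id = tid, term_name = unname(term_names[tid]),
               k = k, n = n, K = K, N = N,
               p_value = hypergeom_upper_tail(k, n, K, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    out <- data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p_value = numeric(0),
                      p_adj = numeric(0), enriched = logical(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("enrichment_results", "data.frame")
    return(out)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_adj <- stats::p.adjust(out$p_value,
                               method = if (correction == "BH") "BH" else "bonferroni")
  out$enriched <- out$p_adj < alpha
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_results", "data.frame")
  out
}

#' Write an enrichment result table as TSV
#'
#' @param results An `enrichment_results` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(results, path) {
  write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = ".")
  invisible(path)
}
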