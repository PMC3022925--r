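#' Default SNP quality-filter thresholds
#'
#' The threshold cascade applied to candidate SNP calls from short-read
#' mapping: minimum read depth `d`, maximum read depth `D` (repeat/collapsed
#' regions), maximum region-uniqueness score `w`, minimum consensus quality
#' `Q` and minimum best-neighbour read quality `n` (both phred-scaled). All
#' comparisons are strict by default: a candidate passes when
#' `d > d_min`, `D < D_max`, `w < w_max`, `Q > Q_min`, `n > n_min` and it is
#' not flagged ambiguous.
#'
#' @param d_min,D_max,w_max,Q_min,n_max Threshold values; defaults 5, 255,
#'   1.5, 50 and 40.
#' @param n_min Minimum best-neighbour quality (default 40).
#' @return A list of class `filter_thresholds`.
#' @export
default_filter_thresholds <- function(d_min = 5L, D_max = 255L, w_max = 1.5,
                                      Q_min = 50, n_min = 40) {
  if (!(d_min < D_max)) stop("d_min must be below D_max", call. = FALSE)
  structure(list(d_min = d_min, D_max = D_max, w_max = w_max,
                 Q_min = Q_min, n_min = n_min),
            class = "filter_thresholds")
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat(sprintf("SNP filter thresholds: d > %s, D < %s, w < %s, Q > %s, n > %s\n",
              x$d_min, x$D_max, x$w_max, x$Q_min, x$n_min))
  invisible(x)
}

#' Read a candidate SNP table with quality fields
#'
#' Tab-separated with header
#' `gene_id position ref alt d D w Q n ambiguous`.
#'
#' @param path Path to the candidate table.
#' @return A data frame of class `candidate_table`.
#' @export
read_candidate_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  need <- c("gene_id", "position", "ref", "alt", "d", "D", "w", "Q", "n", "ambiguous")
  if (!all(need %in% names(tab))) {
    stop("candidate table must have header columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  tab <- tab[, need]
  tab$position <- as.integer(tab$position)
  for (col in c("d", "D", "w", "Q", "n")) tab[[col]] <- as.numeric(tab[[col]])
  amb <- as.logical(tab$ambiguous)
  if (anyNA(amb)) amb <- as.logical(as.integer(tab$ambiguous))
  tab$ambiguous <- amb
  validate_candidates(tab)
}

#' Write a candidate SNP table
#'
#' @param candidates A `candidate_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  write.table(as.data.frame(candidates), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

validate_candidates <- function(candidates) {
  stopifnot(is.data.frame(candidates))
  with(candidates, {
    if (any(d < 0) || any(Q < 0) || any(n < 0) || any(w < 0))
      stop("quality fields d, w, Q, n must be non-negative", call. = FALSE)
    if (any(D < d))
      stop("maximum-depth context D must be >= read depth d", call. = FALSE)
  })
  class(candidates) <- unique(c("candidate_table", class(candidates)))
  candidates
}

#' Apply the quality-filter cascade to candidate SNPs
#'
#' Partitions candidates into passed and rejected sets. A candidate passes
#' only if every rule holds; a rejected candidate carries the codes of *all*
#' violated rules (`d`, `D`, `w`, `Q`, `n`, `ambiguous`), not just the first.
#' Input order is preserved in both partitions.
#'
#' @param candidates A data frame with columns `gene_id`, `position`, `ref`,
#'   `alt`, `d`, `D`, `w`, `Q`, `n`, `ambiguous`.
#' @param thresholds A `filter_thresholds` object
#'   (default [default_filter_thresholds()]).
#' @param inclusive_bounds If `TRUE`, boundary values pass (`>=`/`<=`
#'   comparisons) for sensitivity analysis; the default is strict.
#' @return A list with `passed` (a `snp_table` of the surviving records) and
#'   `rejected` (the failing candidate rows plus a `reasons` column of
#'   comma-joined rule codes).
#' @examples
#' cand <- data.frame(gene_id = "GAL1", position = 10, ref = "A", alt = "G",
#'                    d = 6, D = 100, w = 1.0, Q = 60, n = 50,
#'                    ambiguous = FALSE)
#' filter_candidates(cand)
#' @export
filter_candidates <- function(candidates, thresholds = default_filter_thresholds(),
                              inclusive_bounds = FALSE) {
  candidates <- validate_candidates(candidates)
  gt <- if (inclusive_bounds) `>=` else `>`
  lt <- if (inclusive_bounds) `<=` else `<`
  viol <- cbind(d = !gt(candidates$d, thresholds$d_min),
                D = !lt(candidates$D, thresholds$D_max),
                w = !lt(candidates$w, thresholds$w_max),
                Q = !gt(candidates$Q, thresholds$Q_min),
                n = !gt(candidates$n, thresholds$n_min),
                ambiguous = as.logical(candidates$ambiguous))
  pass <- rowSums(viol) == 0L
  passed <- data.frame(gene_id = candidates$gene_id[pass],
                       position = candidates$position[pass],
                       ref = candidates$ref[pass],
                       alt = candidates$alt[pass],
                       strain = if ("strain" %in% names(candidates))
                         candidates$strain[pass] else rep("", sum(pass)),
                       stringsAsFactors = FALSE)
  class(passed) <- c("snp_table", "data.frame")
  rejected <- as.data.frame(candidates)[!pass, , drop = FALSE]
  rejected$reasons <- apply(viol[!pass, , drop = FALSE], 1L, function(v)
    paste(colnames(viol)[v], collapse = ","))
  rownames(passed) <- NULL
  rownames(rejected) <- NULL
  list(passed = passed, rejected = rejected)
}

#' Drop candidates with ambiguous alternate calls
#'
#' A candidate is ambiguous when its alternate call is not a single
#' unambiguous nucleotide (IUPAC degeneracy in the consensus), recorded in the
#' `ambiguous` flag.
#'
#' @param candidates A candidate data frame with an `ambiguous` column.
#' @return The non-ambiguous candidate rows, order preserved.
#' @export
filter_ambiguous <- function(candidates) {
  out <- candidates[!as.logical(candidates$ambiguous), , drop = FALSE]
  rownames(out) <- NULL
  out
}
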