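#' Load an amino-acid physicochemical property scheme
#'
#' A property scheme maps each of the 20 standard residues (plus `*`, which
#' carries no labels) to a set of overlapping class labels such as `polar`,
#' `non-polar`, `hydrophobic`, `hydroxylic`, `charged`, `aromatic`. The
#' packaged default follows the Taylor / Livingstone-Barton overlapping
#' classification, with serine treated as polar + hydroxylic and not
#' hydrophobic. `polar` and `non-polar` are mutually exclusive per residue.
#'
#' The file format is tab-separated with header `residue<TAB>labels`, labels
#' comma-separated; pass a path to substitute a custom scheme.
#'
#' @param path Optional path to a scheme file; default is the packaged scheme.
#' @return A named list of class `property_scheme`: residue -> character
#'   vector of labels.
#' @export
default_property_scheme <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_property_scheme.tsv", package = "snpchar")
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = character(0),
                    colClasses = "character")
  scheme <- lapply(tab$labels, function(s) {
    s <- trimws(s)
    if (!nzchar(s) || is.na(s)) character(0)
    else strsplit(s, ",", fixed = TRUE)[[1]]
  })
  names(scheme) <- tab$residue
  validate_property_scheme(structure(scheme, class = "property_scheme"))
}

validate_property_scheme <- function(scheme) {
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  missing <- setdiff(std, names(scheme))
  if (length(missing)) {
    stop("property scheme missing residue(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  empty <- std[vapply(scheme[std], length, integer(1)) == 0L]
  if (length(empty)) {
    stop("standard residue(s) with empty label set: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  both <- std[vapply(scheme[std], function(l)
    all(c("polar", "non-polar") %in% l), logical(1))]
  if (length(both)) {
    stop("polar and non-polar are mutually exclusive; violated by: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  if (!"*" %in% names(scheme)) scheme[["*"]] <- character(0)
  scheme
}

scheme_labels <- function(scheme) {
  sort(unique(unlist(scheme, use.names = FALSE)))
}

#' Characterize the property change between two residues
#'
#' Computes the property labels gained, lost and shared when the reference
#' residue is replaced by the variant residue, e.g. an alanine-to-serine
#' substitution loses `non-polar` and `hydrophobic` and gains `polar` and
#' `hydroxylic`.
#'
#' @param ref_aa,alt_aa Single-letter residues (or `*`) present in the scheme.
#' @param scheme A `property_scheme` (default packaged scheme).
#' @return A list of class `property_change` with elements `ref_aa`, `alt_aa`,
#'   `ref_labels`, `alt_labels`, `gained`, `lost`, `shared`.
#' @examples
#' property_change("A", "S")
#' @export
property_change <- function(ref_aa, alt_aa, scheme = default_property_scheme()) {
  for (aa in c(ref_aa, alt_aa)) {
    if (!aa %in% names(scheme)) {
      stop("residue '", aa, "' not present in property scheme", call. = FALSE)
    }
  }
  ref_labels <- scheme[[ref_aa]]
  alt_labels <- scheme[[alt_aa]]
  structure(list(ref_aa = ref_aa, alt_aa = alt_aa,
                 ref_labels = ref_labels, alt_labels = alt_labels,
                 gained = setdiff(alt_labels, ref_labels),
                 lost = setdiff(ref_labels, alt_labels),
                 shared = intersect(ref_labels, alt_labels)),
            class = "property_change")
}

#' @export
print.property_change <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "(none)"
  cat(sprintf("%s -> %s\n  lost:   %s\n  gained: %s\n  shared: %s\n",
              x$ref_aa, x$alt_aa, fmt(x$lost), fmt(x$gained), fmt(x$shared)))
  invisible(x)
}

#' Property-label frequencies down an alignment column
#'
#' For one aligned column, the fraction of ungapped residues carrying each
#' property label. Gapped positions are excluded from the denominator, and by
#' default so is the reference row, so the fractions describe the homologues
#' only. Because labels overlap, fractions need not sum to 1.
#'
#' @param alignment A `homolog_alignment`.
#' @param column 1-based aligned column index.
#' @param scheme A `property_scheme`.
#' @param exclude_reference Drop the reference row from the counts
#'   (default `TRUE`).
#' @return Named numeric vector over every label in the scheme, each in
#'   `[0, 1]`.
#' @export
column_property_frequencies <- function(alignment, column,
                                        scheme = default_property_scheme(),
                                        exclude_reference = TRUE) {
  width <- nchar(alignment$rows[[1]])
  if (column < 1L || column > width) {
    stop("column ", column, " outside aligned width ", width, call. = FALSE)
  }
  rows <- alignment$rows
  if (exclude_reference) {
    rows <- rows[names(rows) != alignment$reference_row_id]
  }
  residues <- substr(rows, column, column)
  residues <- residues[residues != "-"]
  if (length(residues) == 0L) {
    stop("column ", column, " entirely gapped among counted rows", call. = FALSE)
  }
  labels <- scheme_labels(scheme)
  counts <- vapply(labels, function(lab) {
    sum(vapply(residues, function(r) lab %in% scheme[[r]], logical(1)))
  }, numeric(1))
  counts / length(residues)
}
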