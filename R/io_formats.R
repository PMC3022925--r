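#' @importFrom utils read.delim write.table head
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
SNP_BASES <- c("A", "C", "G", "T")

#' Read a set of ORF coding sequences from a FASTA file
#'
#' Each record becomes one row of an `orf_set` data frame. Sequences are
#' uppercased and restricted to the DNA alphabet `A,C,G,T,N`; `U` is rejected
#' (DNA only). Record order follows file order and gene identifiers must be
#' unique.
#'
#' @param path Path to a FASTA file of coding (spliced) nucleotide sequences.
#' @return A data frame of class `orf_set` with columns `gene_id`,
#'   `sequence`, `description` and one row per FASTA record.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">YDR538W demo", "ATGGCTTAA"), fa)
#' read_orf_fasta(fa)
#' @export
read_orf_fasta <- function(path) {
  recs <- read_fasta_records(path)
  seqs <- toupper(recs$sequence)
  bad <- vapply(seqs, function(s) {
    ch <- unique(strsplit(s, "", fixed = TRUE)[[1]])
    length(setdiff(ch, DNA_ALPHABET)) > 0L || nchar(s) == 0L
  }, logical(1))
  if (any(bad)) {
    stop("invalid nucleotide sequence (allowed: A,C,G,T,N; DNA only) in record(s): ",
         paste(recs$id[bad], collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(recs$id)
  if (any(dup)) {
    stop("duplicate gene_id in FASTA: ",
         paste(unique(recs$id[dup]), collapse = ", "), call. = FALSE)
  }
  new_orf_set(gene_id = recs$id, sequence = seqs, description = recs$desc)
}

new_orf_set <- function(gene_id, sequence, description = character(length(gene_id))) {
  out <- data.frame(gene_id = as.character(gene_id),
                    sequence = as.character(sequence),
                    description = as.character(description),
                    stringsAsFactors = FALSE)
  class(out) <- c("orf_set", "data.frame")
  out
}

#' @export
print.orf_set <- function(x, ...) {
  cat(sprintf("ORF set: %d sequence(s), lengths %s nt\n", nrow(x),
              if (nrow(x)) paste(range(nchar(x$sequence)), collapse = "-") else "0-0"))
  if (nrow(x)) print(head(data.frame(gene_id = x$gene_id, length = nchar(x$sequence)), 10))
  invisible(x)
}

# Minimal FASTA scan. Biostrings does the heavy lifting for well-formed files;
# the pre-scan exists so malformed input fails with a line number.
read_fasta_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(list(id = character(0), desc = character(0), sequence = character(0)))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop(sprintf("FASTA parse error at line %d: expected '>' header", nonblank[1]),
         call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  full <- names(set)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  list(id = id, desc = desc, sequence = as.character(set))
}

#' Write an ORF set to FASTA
#'
#' @param orfs An `orf_set` (see [read_orf_fasta()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_orf_fasta <- function(orfs, path) {
  hdr <- ifelse(nzchar(orfs$description),
                paste(orfs$gene_id, orfs$description),
                orfs$gene_id)
  writeLines(as.vector(rbind(paste0(">", hdr), orfs$sequence)), path)
  invisible(path)
}

#' Read a SNP table
#'
#' Two dialects are accepted: a headed tab-separated table with columns
#' `gene_id`, `position`, `ref`, `alt` (optionally `strain`), or a VCF 4.x
#' subset ("vcf-lite") where `CHROM` is interpreted as the gene identifier and
#' `POS` as the 1-based position in the ORF coding sequence. `INFO`/`FILTER`
#' fields are ignored. When an `orf_set` is supplied, positions are checked
#' against ORF bounds and reference bases against the ORF sequence.
#'
#' @param path Path to the table.
#' @param dialect `"tsv"` or `"vcf-lite"`.
#' @param orfs Optional `orf_set` used to validate records.
#' @return A data frame of class `snp_table` with columns `gene_id`,
#'   `position`, `ref`, `alt`, `strain`, rows in file order.
#' @export
read_snp_table <- function(path, dialect = c("tsv", "vcf-lite"), orfs = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character")
    need <- c("gene_id", "position", "ref", "alt")
    if (!all(need %in% names(tab))) {
      stop("SNP table must have header columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    snps <- data.frame(gene_id = as.character(tab$gene_id),
                       position = as.integer(tab$position),
                       ref = toupper(as.character(tab$ref)),
                       alt = toupper(as.character(tab$alt)),
                       strain = if ("strain" %in% names(tab))
                         as.character(tab$strain) else rep("", nrow(tab)),
                       stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    if (length(body) == 0L) {
      snps <- data.frame(gene_id = character(0), position = integer(0),
                         ref = character(0), alt = character(0),
                         strain = character(0), stringsAsFactors = FALSE)
    } else {
      parts <- strsplit(body, "\t", fixed = TRUE)
      nf <- vapply(parts, length, integer(1))
      if (any(nf < 5L)) {
        stop("vcf-lite record with fewer than 5 fields at data line ",
             which(nf < 5L)[1], call. = FALSE)
      }
      snps <- data.frame(gene_id = vapply(parts, `[`, "", 1L),
                         position = as.integer(vapply(parts, `[`, "", 2L)),
                         ref = toupper(vapply(parts, `[`, "", 4L)),
                         alt = toupper(vapply(parts, `[`, "", 5L)),
                         strain = "",
                         stringsAsFactors = FALSE)
    }
  }
  validate_snp_table(snps, orfs)
}

validate_snp_table <- function(snps, orfs = NULL) {
  if (nrow(snps)) {
    bad_base <- !(snps$ref %in% SNP_BASES) | !(snps$alt %in% SNP_BASES)
    if (any(bad_base)) {
      stop("ref/alt must be single unambiguous nucleotides (A,C,G,T); offending row(s): ",
           paste(which(bad_base), collapse = ", "), call. = FALSE)
    }
    same <- snps$ref == snps$alt
    if (any(same)) {
      stop("ref and alt base identical for ",
           paste(sprintf("%s:%d", snps$gene_id[same], snps$position[same]),
                 collapse = ", "), call. = FALSE)
    }
    if (any(is.na(snps$position)) || any(snps$position < 1L)) {
      stop("SNP positions must be 1-based positive integers", call. = FALSE)
    }
    if (!is.null(orfs)) {
      idx <- match(snps$gene_id, orfs$gene_id)
      if (anyNA(idx)) {
        stop("SNP references unknown gene_id: ",
             paste(unique(snps$gene_id[is.na(idx)]), collapse = ", "),
             call. = FALSE)
      }
      len <- nchar(orfs$sequence)[idx]
      out <- snps$position > len
      if (any(out)) {
        stop("SNP position out of ORF bounds: ",
             paste(sprintf("%s:%d (length %d)", snps$gene_id[out],
                           snps$position[out], len[out]), collapse = ", "),
             call. = FALSE)
      }
    }
  }
  class(snps) <- c("snp_table", "data.frame")
  snps
}

#' Write a SNP table as TSV
#'
#' @param snps A `snp_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(snps, path) {
  write.table(as.data.frame(snps)[, c("gene_id", "position", "ref", "alt", "strain")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a homologue multiple alignment
#'
#' Reads an aligned protein multiple alignment in aligned-FASTA or Stockholm
#' format. All rows must share the aligned length; `.` gap characters are
#' normalized to `-` and residues are uppercased. The designated reference row
#' (the reference-strain protein, e.g. the S288c sequence) must be present.
#'
#' @param path Path to the alignment file.
#' @param format `"aligned-fasta"` or `"stockholm"`.
#' @param reference_row_id Identifier of the reference protein row.
#' @param gene_id Gene identifier attached to the alignment (defaults to the
#'   reference row id).
#' @return A `homolog_alignment`: a list with elements `gene_id`,
#'   `reference_row_id`, `row_ids` and `rows` (named character vector of
#'   aligned sequences, in file order).
#' @export
read_alignment <- function(path, format = c("aligned-fasta", "stockholm"),
                           reference_row_id, gene_id = reference_row_id) {
  format <- match.arg(format)
  if (format == "aligned-fasta") {
    recs <- read_fasta_records(path)
    ids <- recs$id
    rows <- recs$sequence
  } else {
    sto <- read_stockholm_rows(path)
    ids <- sto$id
    rows <- sto$sequence
  }
  rows <- chartr(".", "-", toupper(rows))
  names(rows) <- ids
  new_homolog_alignment(gene_id, reference_row_id, rows)
}

#' Construct a homologue alignment in memory
#'
#' @param gene_id Gene identifier.
#' @param reference_row_id Identifier of the reference protein row; must be a
#'   name of `rows`.
#' @param rows Named character vector of aligned amino-acid strings of equal
#'   length (gap character `-`).
#' @return A `homolog_alignment`.
#' @examples
#' homolog_alignment("ERG8", "ref", c(ref = "MKV", hom1 = "MKV", hom2 = "M-V"))
#' @export
homolog_alignment <- function(gene_id, reference_row_id, rows) {
  new_homolog_alignment(gene_id, reference_row_id,
                        chartr(".", "-", toupper(rows)))
}

new_homolog_alignment <- function(gene_id, reference_row_id, rows) {
  if (length(rows) == 0L) stop("alignment has no rows", call. = FALSE)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: row lengths ", paste(unique(widths), collapse = ", "),
         call. = FALSE)
  }
  if (!reference_row_id %in% names(rows)) {
    stop("reference row '", reference_row_id, "' not found among row ids",
         call. = FALSE)
  }
  structure(list(gene_id = gene_id,
                 reference_row_id = reference_row_id,
                 row_ids = names(rows),
                 rows = rows),
            class = "homolog_alignment")
}

#' @export
print.homolog_alignment <- function(x, ...) {
  cat(sprintf("Homologue alignment for %s: %d row(s) (reference '%s' + %d homologue(s)), width %d\n",
              x$gene_id, length(x$rows), x$reference_row_id,
              length(x$rows) - 1L, nchar(x$rows[[1]])))
  invisible(x)
}

# Stockholm 1.0 subset: '#' annotation lines skipped, '//' terminates,
# interleaved blocks accumulated per sequence id.
read_stockholm_rows <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  acc <- list()
  order_ids <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (ln == "//") break
    fields <- strsplit(ln, "\\s+")[[1]]
    if (length(fields) != 2L) {
      stop(sprintf("Stockholm parse error at line %d: expected 'id sequence'", i),
           call. = FALSE)
    }
    id <- fields[1]
    if (!id %in% order_ids) order_ids <- c(order_ids, id)
    acc[[id]] <- paste0(if (is.null(acc[[id]])) "" else acc[[id]], fields[2])
  }
  list(id = order_ids, sequence = unlist(acc[order_ids], use.names = FALSE))
}

#' Write a homologue alignment
#'
#' @param alignment A `homolog_alignment`.
#' @param path Output file path.
#' @param format `"aligned-fasta"` or `"stockholm"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path, format = c("aligned-fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "aligned-fasta") {
    writeLines(as.vector(rbind(paste0(">", alignment$row_ids), unname(alignment$rows))),
               path)
  } else {
    writeLines(c("# STOCKHOLM 1.0",
                 sprintf("%-30s %s", alignment$row_ids, unname(alignment$rows)),
                 "//"), path)
  }
  invisible(path)
}

#' Read a gene-to-term annotation table
#'
#' Tab-separated, GAF-lite: columns `gene_id`, `term_id`, `term_name`.
#'
#' @param path Path to the annotation table.
#' @return A data frame with columns `gene_id`, `term_id`, `term_name`.
#' @export
read_annotation_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "term_id", "term_name")
  if (!all(need %in% names(tab))) {
    stop("annotation table must have header columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  tab[, need]
}
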