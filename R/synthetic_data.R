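STOP_CODONS <- c("TAA", "TAG", "TGA")

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sample() that never treats a length-1 vector as 1:n
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Independent sub-stream seeds per generated artifact, so regenerating one
# artifact never perturbs the others. Kept below 2^31.
sub_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(k) * 1009
  as.integer(s %% 2147483629) + 1L
}

#' Configuration for the synthetic-data generator
#'
#' Bundles every tunable of the seeded generator that stands in for the
#' strains' raw sequencing data: ORF count and codon-length range, SNP rate
#' per gene and target nonsynonymous fraction, homologue count and per-column
#' conservation probability, the fraction of candidates drawn to pass the
#' default quality filter, and the annotation layout.
#'
#' Defaults mirror a resequencing comparison of laboratory yeast strains at
#' demonstration scale: a nonsynonymous fraction of 0.233 among coding SNPs,
#' 10 homologues per gene as in a top-10 family-database query, a 0.56
#' quality-pass fraction, and a symmetric (0.5) per-column conservation
#' probability.
#'
#' @param seed Master seed; every artifact derives its own sub-stream.
#' @param n_genes Number of ORFs.
#' @param codon_length_range Min/max ORF length in codons (including start
#'   and stop).
#' @param snps_per_gene Expected SNPs per gene (Poisson rate).
#' @param target_nonsyn_fraction Target fraction of spiked SNPs that are
#'   nonsynonymous.
#' @param n_homologs Homologue rows per alignment.
#' @param column_conservation Probability a homologue residue copies the
#'   reference residue.
#' @param quality_pass_fraction Fraction of candidates drawn with
#'   all-passing quality fields.
#' @param annotation_terms Number of annotation terms.
#' @param genes_per_term_range Min/max genes per term.
#' @param gap_fraction Probability a homologue residue is replaced by a gap.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 20L, codon_length_range = c(100L, 300L),
                       snps_per_gene = 5, target_nonsyn_fraction = 0.233,
                       n_homologs = 10L, column_conservation = 0.5,
                       quality_pass_fraction = 0.56, annotation_terms = 5L,
                       genes_per_term_range = c(3L, 8L), gap_fraction = 0) {
  fracs <- c(target_nonsyn_fraction, column_conservation,
             quality_pass_fraction, gap_fraction)
  if (any(fracs < 0) || any(fracs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (n_genes < 1L) stop("n_genes must be at least 1", call. = FALSE)
  if (codon_length_range[1] > codon_length_range[2] ||
      genes_per_term_range[1] > genes_per_term_range[2]) {
    stop("ranges must be ordered (min <= max)", call. = FALSE)
  }
  if (codon_length_range[1] < 2L) {
    stop("ORFs need at least 2 codons (start + stop)", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 codon_length_range = as.integer(codon_length_range),
                 snps_per_gene = snps_per_gene,
                 target_nonsyn_fraction = target_nonsyn_fraction,
                 n_homologs = as.integer(n_homologs),
                 column_conservation = column_conservation,
                 quality_pass_fraction = quality_pass_fraction,
                 annotation_terms = as.integer(annotation_terms),
                 genes_per_term_range = as.integer(genes_per_term_range),
                 gap_fraction = gap_fraction),
            class = "sim_config")
}

#' Read a generator configuration from a flat YAML file
#'
#' Keys mirror the [sim_config()] arguments; absent keys keep their defaults.
#'
#' @param path Path to a flat key-value YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown sim_config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, vals)
}

#' Generate a set of synthetic ORF coding sequences
#'
#' Each ORF starts with ATG, ends with a stop codon, contains no internal
#' stop, and has a codon length drawn uniformly from the configured range.
#' Internal codons are sampled uniformly from the 61 non-stop codons.
#' Deterministic for a given configuration.
#'
#' @param config A `sim_config`.
#' @return An `orf_set`.
#' @export
generate_orfs <- function(config) {
  nonstop <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  with_seed(sub_seed(config$seed, 1L), {
    lens <- resample(seq(config$codon_length_range[1], config$codon_length_range[2]),
                     config$n_genes, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste0("ATG",
             paste(sample(nonstop, L - 2L, replace = TRUE), collapse = ""),
             sample(STOP_CODONS, 1L))
    }, character(1))
    new_orf_set(gene_id = sprintf("G%03d", seq_len(config$n_genes)),
                sequence = seqs,
                description = "synthetic ORF")
  })
}

# Binary consequence of substituting `alt` at `pos` of `seq` (frame 1).
snp_consequence <- function(seq, pos, alt) {
  ci <- (pos - 1L) %/% 3L + 1L
  off <- (pos - 1L) %% 3L + 1L
  start <- (ci - 1L) * 3L + 1L
  ref_codon <- substr(seq, start, start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- alt
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
  if (ref_aa == alt_aa) "silent"
  else if (alt_aa == "*") "nonsynonymous_nonsense"
  else if (ref_aa == "*") "stop_loss"
  else "nonsynonymous_missense"
}

draw_quality_fields <- function(pass) {
  d <- sample(6:60, 1L)
  D <- sample(d:254, 1L)
  w <- round(stats::runif(1, 0, 1.45), 3)
  Q <- round(stats::runif(1, 51, 97), 1)
  n <- round(stats::runif(1, 41, 97), 1)
  ambiguous <- FALSE
  if (!pass) {
    rules <- sample(c("d", "D", "w", "Q", "n", "ambiguous"),
                    sample(1:2, 1L))
    if ("d" %in% rules) d <- sample(0:5, 1L)
    if ("D" %in% rules) D <- sample(255:400, 1L)
    if ("w" %in% rules) w <- round(stats::runif(1, 1.5, 4), 3)
    if ("Q" %in% rules) Q <- round(stats::runif(1, 0, 49.9), 1)
    if ("n" %in% rules) n <- round(stats::runif(1, 0, 39.9), 1)
    if ("ambiguous" %in% rules) ambiguous <- TRUE
    if (D < d) D <- d  # keep the depth-context invariant
  }
  list(d = d, D = D, w = w, Q = Q, n = n, ambiguous = ambiguous)
}

#' Spike SNPs with known effect labels into synthetic ORFs
#'
#' Draws a Poisson number of SNP positions per gene, assigns each SNP a
#' silent or nonsynonymous target label so the realized nonsynonymous
#' fraction is the closest achievable to `target_nonsyn_fraction`
#' (substitutions are rejection-sampled by their true codon consequence),
#' and attaches MAQ-style quality fields drawn so that approximately
#' `quality_pass_fraction` of candidates pass [default_filter_thresholds()].
#' The truth table records every per-SNP label and intended pass/fail flag.
#'
#' @param orfs An `orf_set`, typically from [generate_orfs()].
#' @param config A `sim_config`.
#' @return A list with `candidates` (a `candidate_table`) and `truth` (a
#'   data frame with `gene_id`, `position`, `ref`, `alt`, `effect_class`,
#'   `nonsyn`, `pass`), rows aligned one-to-one.
#' @export
spike_snps <- function(orfs, config) {
  with_seed(sub_seed(config$seed, 2L), {
    lens <- nchar(orfs$sequence)
    counts <- stats::rpois(nrow(orfs), config$snps_per_gene)
    counts <- pmin(counts, lens %/% 3L)
    total <- sum(counts)
    if (total == 0L) {
      stop("no SNPs drawn; increase snps_per_gene or n_genes", call. = FALSE)
    }
    n_nonsyn <- round(total * config$target_nonsyn_fraction)
    want_nonsyn <- sample(rep(c(TRUE, FALSE), c(n_nonsyn, total - n_nonsyn)))
    rows <- vector("list", total)
    idx <- 0L
    for (g in seq_len(nrow(orfs))) {
      if (counts[g] == 0L) next
      seq <- orfs$sequence[g]
      len <- lens[g]
      used <- integer(0)
      for (s in seq_len(counts[g])) {
        idx <- idx + 1L
        want <- want_nonsyn[idx]
        placed <- FALSE
        for (try in 1:100) {
          pos <- resample(setdiff(seq_len(len), used), 1L)
          ref <- substr(seq, pos, pos)
          alts <- setdiff(SNP_BASES, ref)
          eff <- vapply(alts, function(a) snp_consequence(seq, pos, a),
                        character(1))
          ok <- if (want) eff != "silent" else eff == "silent"
          if (any(ok)) {
            hits <- which(ok)
            pick <- hits[sample.int(length(hits), 1L)]
            used <- c(used, pos)
            rows[[idx]] <- list(gene_id = orfs$gene_id[g], position = pos,
                                ref = ref, alt = alts[pick],
                                effect_class = eff[pick])
            placed <- TRUE
            break
          }
        }
        if (!placed) {  # fall back to whatever the last position offers
          pick <- sample(length(alts), 1L)
          used <- c(used, pos)
          rows[[idx]] <- list(gene_id = orfs$gene_id[g], position = pos,
                              ref = ref, alt = alts[pick],
                              effect_class = eff[pick])
        }
      }
    }
    truth <- do.call(rbind, lapply(rows, function(r)
      data.frame(r, stringsAsFactors = FALSE)))
    truth$nonsyn <- truth$effect_class != "silent"
    truth$pass <- stats::runif(total) < config$quality_pass_fraction
    qual <- lapply(truth$pass, draw_quality_fields)
    candidates <- data.frame(gene_id = truth$gene_id, position = truth$position,
                             ref = truth$ref, alt = truth$alt,
                             d = vapply(qual, `[[`, 0, "d"),
                             D = vapply(qual, `[[`, 0, "D"),
                             w = vapply(qual, `[[`, 0, "w"),
                             Q = vapply(qual, `[[`, 0, "Q"),
                             n = vapply(qual, `[[`, 0, "n"),
                             ambiguous = vapply(qual, `[[`, FALSE, "ambiguous"),
                             stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(candidates = validate_candidates(candidates), truth = truth)
  })
}

#' Generate a homologue alignment with controlled conservation
#'
#' The reference row is the translated ORF (trailing stop dropped). Each
#' homologue residue copies the reference residue with probability
#' `column_conservation`, otherwise a uniformly drawn different residue;
#' optional gap injection replaces homologue residues with `-`. Columns can
#' be overridden to force extreme compositions at SNP positions: all
#' homologues carrying the reference residue (`all_ref`, Conservation
#' Distance +1), all carrying the variant (`all_variant`, -1), or an even
#' reference/variant mixture (`mix`).
#'
#' @param orf A single-row `orf_set` (or list with `gene_id`, `sequence`).
#' @param config A `sim_config`.
#' @param override Optional data frame with columns `protein_position`,
#'   `mode` (`all_ref`, `all_variant` or `mix`) and `variant_aa`.
#' @param seed Optional explicit stream seed; defaults to a sub-stream of
#'   `config$seed` keyed by the gene id.
#' @return A `homolog_alignment` whose reference row id is
#'   `<gene_id>_S288c`.
#' @export
generate_homolog_alignment <- function(orf, config, override = NULL,
                                       seed = NULL) {
  gene <- orf$gene_id[[1]]
  seqs <- orf$sequence[[1]]
  if (is.null(seed)) {
    seed <- sub_seed(config$seed, 3000L + sum(utf8ToInt(gene)))
  }
  codons <- substring(seqs, seq(1, nchar(seqs) - 2, 3), seq(3, nchar(seqs), 3))
  protein <- paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
  protein <- sub("\\*$", "", protein)
  width <- nchar(protein)
  ref_chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  residues <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  over_cols <- if (is.null(override)) integer(0) else override$protein_position
  with_seed(seed, {
    homs <- matrix("", nrow = config$n_homologs, ncol = width)
    for (j in seq_len(width)) {
      copy <- stats::runif(config$n_homologs) < config$column_conservation
      other <- sample(setdiff(residues, ref_chars[j]),
                      config$n_homologs, replace = TRUE)
      homs[, j] <- ifelse(copy, ref_chars[j], other)
      if (config$gap_fraction > 0 && !(j %in% over_cols)) {
        gap <- stats::runif(config$n_homologs) < config$gap_fraction
        homs[gap, j] <- "-"
      }
    }
    if (!is.null(override)) {
      for (r in seq_len(nrow(override))) {
        j <- override$protein_position[r]
        homs[, j] <- switch(override$mode[r],
          all_ref = rep(ref_chars[j], config$n_homologs),
          all_variant = rep(override$variant_aa[r], config$n_homologs),
          mix = ifelse(stats::runif(config$n_homologs) < 0.5,
                       ref_chars[j], override$variant_aa[r]),
          stop("unknown override mode: ", override$mode[r], call. = FALSE))
      }
    }
    rows <- c(protein, apply(homs, 1L, paste, collapse = ""))
    names(rows) <- c(paste0(gene, "_S288c"),
                     sprintf("%s_hom%02d", gene, seq_len(config$n_homologs)))
    new_homolog_alignment(gene, paste0(gene, "_S288c"), rows)
  })
}

#' Generate a synthetic gene-to-term annotation table
#'
#' @param orfs An `orf_set` supplying the gene universe.
#' @param config A `sim_config`.
#' @return A long-format data frame `gene_id`, `term_id`, `term_name`.
#' @export
generate_annotations <- function(orfs, config) {
  with_seed(sub_seed(config$seed, 4L), {
    rows <- lapply(seq_len(config$annotation_terms), function(i) {
      size <- resample(seq(config$genes_per_term_range[1],
                           min(config$genes_per_term_range[2], nrow(orfs))), 1L)
      data.frame(gene_id = resample(orfs$gene_id, size),
                 term_id = sprintf("T%03d", i),
                 term_name = sprintf("synthetic process %d", i),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Generate and write a complete synthetic dataset
#'
#' Produces ORFs, spiked candidate SNPs with truth labels, per-gene homologue
#' alignments and an annotation table, and writes them under `dir` as
#' `orfs.fasta`, `candidates.tsv`, `truth.tsv`, `alignments/<gene>.afa` and
#' `annotations.tsv`. Fully deterministic per configuration.
#'
#' @param config A `sim_config`.
#' @param dir Output directory (created if absent). `NULL` skips writing.
#' @return Invisibly, a list with `orfs`, `candidates`, `truth`,
#'   `alignments` (named list) and `annotations`.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  orfs <- generate_orfs(config)
  spiked <- spike_snps(orfs, config)
  alignments <- lapply(seq_len(nrow(orfs)), function(i)
    generate_homolog_alignment(orfs[i, ], config))
  names(alignments) <- orfs$gene_id
  annotations <- generate_annotations(orfs, config)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "alignments"), recursive = TRUE, showWarnings = FALSE)
    write_orf_fasta(orfs, file.path(dir, "orfs.fasta"))
    write_candidate_table(spiked$candidates, file.path(dir, "candidates.tsv"))
    write.table(spiked$truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (g in names(alignments)) {
      write_alignment(alignments[[g]], file.path(dir, "alignments",
                                                 paste0(g, ".afa")))
    }
    write.table(annotations, file.path(dir, "annotations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(list(orfs = orfs, candidates = spiked$candidates,
                 truth = spiked$truth, alignments = alignments,
                 annotations = annotations))
}

#' Configuration of the packaged demonstration dataset
#'
#' The demo fixture under `inst/extdata/demo/` was written by
#' [simulate_dataset()] with exactly this configuration: 20 genes of 80-150
#' codons, about 100 spiked SNPs, 10 homologues per alignment and a 5-term
#' annotation table. Small enough to drive examples in well under a second.
#'
#' @return A `sim_config`.
#' @export
demo_config <- function() {
  sim_config(seed = 2010L, n_genes = 20L, codon_length_range = c(80L, 150L),
             snps_per_gene = 5, annotation_terms = 5L)
}

#' Path to the packaged demonstration dataset
#'
#' @return Directory containing `orfs.fasta`, `candidates.tsv`, `truth.tsv`,
#'   `annotations.tsv` and `alignments/`.
#' @export
demo_dataset_dir <- function() {
  system.file("extdata", "demo", package = "snpchar")
}
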