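test_that("configuration validation rejects infeasible settings", {
  expect_error(sim_config(codon_length_range = c(10, 5)), "ordered")
  expect_error(sim_config(target_nonsyn_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(codon_length_range = c(1, 1)), "2 codons")
})

test_that("generated ORFs have start/stop structure and no internal stops", {
  cfg <- sim_config(seed = 2, n_genes = 50, codon_length_range = c(5, 60))
  orfs <- generate_orfs(cfg)
  lens <- nchar(orfs$sequence)
  expect_true(all(lens %% 3 == 0))
  expect_true(all(lens >= 15 & lens <= 180))
  stops <- c("TAA", "TAG", "TGA")
  for (s in orfs$sequence) {
    codons <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    expect_identical(codons[1], "ATG")
    expect_true(codons[length(codons)] %in% stops)
    expect_false(any(codons[-length(codons)] %in% stops))
  }

  tiny <- generate_orfs(sim_config(seed = 2, n_genes = 5,
                                   codon_length_range = c(2, 2)))
  expect_true(all(nchar(tiny$sequence) == 6))
  expect_true(all(substr(tiny$sequence, 1, 3) == "ATG"))
})

test_that("identical configurations give byte-identical datasets", {
  cfg <- sim_config(seed = 8, n_genes = 6, snps_per_gene = 4,
                    gap_fraction = 0.05)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) >= 9)  # fasta, 2 tsv, annotations, 6 alignments
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("per-artifact sub-streams keep artifacts independent", {
  cfg <- sim_config(seed = 8, n_genes = 6, snps_per_gene = 4)
  orfs_alone <- generate_orfs(cfg)
  sim <- simulate_dataset(cfg)
  expect_identical(sim$orfs$sequence, orfs_alone$sequence)
  ann_alone <- generate_annotations(orfs_alone, cfg)
  expect_identical(sim$annotations, ann_alone)
})

test_that("spiked SNPs honour the target nonsynonymous fraction", {
  cfg <- sim_config(seed = 14, n_genes = 20, snps_per_gene = 50,
                    target_nonsyn_fraction = 0.233)
  orfs <- generate_orfs(cfg)
  spiked <- spike_snps(orfs, cfg)
  total <- nrow(spiked$truth)
  expect_gt(total, 800)
  expect_lt(abs(mean(spiked$truth$nonsyn) - 0.233), 0.03)

  all_nonsyn <- spike_snps(orfs, sim_config(seed = 14, n_genes = 20,
                                            snps_per_gene = 5,
                                            target_nonsyn_fraction = 1))
  expect_true(all(all_nonsyn$truth$nonsyn))
})

test_that("the classifier recovers the generator's effect labels exactly", {
  cfg <- sim_config(seed = 21, n_genes = 12, snps_per_gene = 10)
  sim <- simulate_dataset(cfg)
  eff <- classify_all(sim$orfs, sim$truth[, c("gene_id", "position", "ref", "alt")])
  expect_identical(eff$effect_class, sim$truth$effect_class)
})

test_that("candidate pass/fail flags agree with the default filter", {
  cfg <- sim_config(seed = 25, n_genes = 15, snps_per_gene = 20,
                    quality_pass_fraction = 0.56)
  sim <- simulate_dataset(cfg)
  res <- filter_candidates(sim$candidates)
  keys <- function(df) paste(df$gene_id, df$position)
  expect_setequal(keys(res$passed), keys(sim$truth[sim$truth$pass, ]))
  expect_lt(abs(mean(sim$truth$pass) - 0.56), 0.1)
})

test_that("homologue alignments track the conservation parameter", {
  cfg <- sim_config(seed = 33, n_genes = 1, codon_length_range = c(502, 502),
                    column_conservation = 0.5, n_homologs = 10)
  orfs <- generate_orfs(cfg)
  aln <- generate_homolog_alignment(orfs[1, ], cfg)
  ref <- strsplit(aln$rows[[aln$reference_row_id]], "")[[1]]
  homs <- do.call(rbind, strsplit(unname(aln$rows[-1]), ""))
  match_frac <- mean(sweep(homs, 2, ref, "==")[, seq_len(500)])
  expect_lt(abs(match_frac - 0.5), 3 * sqrt(0.25 / 5000))

  perfect <- generate_homolog_alignment(
    orfs[1, ], sim_config(seed = 33, n_genes = 1,
                          codon_length_range = c(502, 502),
                          column_conservation = 1))
  expect_true(all(perfect$rows == perfect$rows[[1]]))
  variant <- setdiff(c("W", "K"), ref[10])[1]
  s <- conservation_stats(perfect, 10L, ref[10], variant)
  expect_identical(s$conservation_distance, 1)
})

test_that("column overrides force the extreme compositions", {
  cfg <- sim_config(seed = 37, n_genes = 1, codon_length_range = c(30, 30))
  orfs <- generate_orfs(cfg)
  prot <- sub("\\*$", "", as.character(
    Biostrings::translate(Biostrings::DNAString(orfs$sequence[1]))))
  ref10 <- substr(prot, 10, 10)
  variant <- setdiff(c("W", "K"), ref10)[1]
  ov <- data.frame(protein_position = c(5L, 10L),
                   mode = c("all_ref", "all_variant"),
                   variant_aa = c(NA, variant), stringsAsFactors = FALSE)
  aln <- generate_homolog_alignment(orfs[1, ], cfg, override = ov)
  s5 <- conservation_stats(aln, 5L, substr(prot, 5, 5), variant)
  expect_identical(s5$conservation_distance, 1)
  s10 <- conservation_stats(aln, 10L, ref10, variant)
  expect_identical(s10$conservation_distance, -1)
})

test_that("simulated datasets re-read identically from disk", {
  cfg <- sim_config(seed = 44, n_genes = 5, snps_per_gene = 6)
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(cfg, dir)
  orfs <- read_orf_fasta(file.path(dir, "orfs.fasta"))
  expect_identical(orfs$sequence, sim$orfs$sequence)
  cand <- read_candidate_table(file.path(dir, "candidates.tsv"))
  expect_identical(cand$position, sim$candidates$position)
  expect_equal(cand$w, sim$candidates$w, tolerance = 1e-9)
  g <- sim$orfs$gene_id[1]
  aln <- read_alignment(file.path(dir, "alignments", paste0(g, ".afa")),
                        "aligned-fasta",
                        reference_row_id = paste0(g, "_S288c"), gene_id = g)
  expect_identical(aln$rows, sim$alignments[[g]]$rows)
})

test_that("flat YAML configurations are read back faithfully", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 99", "n_genes: 7", "target_nonsyn_fraction: 0.5"), path)
  cfg <- read_sim_config(path)
  expect_identical(cfg$seed, 99L)
  expect_identical(cfg$n_genes, 7L)
  expect_identical(cfg$target_nonsyn_fraction, 0.5)
  expect_identical(cfg$n_homologs, 10L)  # default retained
  writeLines("bogus_key: 1", path)
  expect_error(read_sim_config(path), "unknown sim_config key")
})

test_that("the shipped demo fixture is exactly what its config regenerates", {
  dir <- demo_dataset_dir()
  expect_true(dir.exists(dir))
  regen <- withr::local_tempdir()
  simulate_dataset(demo_config(), regen)
  for (f in list.files(dir, recursive = TRUE)) {
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(regen, f)),
                     info = f)
  }
  orfs <- read_orf_fasta(file.path(dir, "orfs.fasta"))
  expect_identical(nrow(orfs), 20L)
  cand <- read_candidate_table(file.path(dir, "candidates.tsv"))
  expect_gt(nrow(cand), 80)
})
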