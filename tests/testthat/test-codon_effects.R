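test_that("a premature-stop SNP is classified as nonsense with the right codon", {
  orf <- pad1_like_orf()
  snp <- list(gene_id = "PAD1", position = 294L, ref = "T", alt = "G")
  eff <- classify_snp_effect(orf, snp)
  expect_identical(eff$codon_index, 98L)
  expect_identical(eff$codon_offset, 3L)
  expect_identical(eff$ref_codon, "TAT")
  expect_identical(eff$alt_codon, "TAG")
  expect_identical(eff$ref_aa, "Y")
  expect_identical(eff$alt_aa, "*")
  expect_identical(eff$effect_class, "nonsynonymous_nonsense")
})

test_that("third-position wobble substitutions are silent", {
  orf <- list(gene_id = "X", sequence = "GCTGGTTAA")
  eff <- classify_snp_effect(orf, list(gene_id = "X", position = 3L,
                                       ref = "T", alt = "C"))
  expect_identical(eff$ref_codon, "GCT")
  expect_identical(eff$alt_codon, "GCC")
  expect_identical(eff$effect_class, "silent")
  expect_identical(eff$ref_aa, eff$alt_aa)
})

test_that("classifier agrees with an independent oracle on all 576 substitutions", {
  subs <- all_codon_substitutions()
  expect_identical(nrow(subs), 576L)
  oracle_class <- character(nrow(subs))
  got_class <- character(nrow(subs))
  for (i in seq_len(nrow(subs))) {
    codon <- subs$codon[i]
    orf <- list(gene_id = "Z", sequence = paste0("ATG", codon, "TAA"))
    eff <- classify_snp_effect(orf, list(gene_id = "Z",
                                         position = 3L + subs$offset[i],
                                         ref = subs$ref[i], alt = subs$alt[i]))
    got_class[i] <- eff$effect_class
    alt_codon <- codon
    substr(alt_codon, subs$offset[i], subs$offset[i]) <- subs$alt[i]
    ref_aa <- oracle_translate(codon)
    alt_aa <- oracle_translate(alt_codon)
    oracle_class[i] <- if (ref_aa == alt_aa) "silent"
      else if (alt_aa == "*") "nonsynonymous_nonsense"
      else if (ref_aa == "*") "stop_loss"
      else "nonsynonymous_missense"
    # substituting the alt base into the ref codon reproduces alt_codon
    expect_identical(eff$alt_codon, alt_codon)
  }
  expect_identical(got_class, oracle_class)
  # silent fraction asserted against the oracle count, not a constant
  expect_identical(sum(got_class == "silent"), sum(oracle_class == "silent"))
})

test_that("batch classification preserves order and is permutation-equivariant", {
  cfg <- sim_config(seed = 5, n_genes = 8, snps_per_gene = 6)
  sim <- simulate_dataset(cfg)
  snps <- sim$truth[, c("gene_id", "position", "ref", "alt")]
  eff <- classify_all(sim$orfs, snps)
  expect_identical(nrow(eff), nrow(snps))
  expect_identical(eff$position, snps$position)

  perm <- sample(nrow(snps))
  eff_perm <- classify_all(sim$orfs, snps[perm, ])
  expect_identical(eff_perm$effect_class, eff$effect_class[perm])
  expect_identical(eff_perm$alt_codon, eff$alt_codon[perm])

  expect_identical(nrow(classify_all(sim$orfs, snps[0, ])), 0L)
})

test_that("record-level errors are collected, or abort in strict mode", {
  orfs <- data.frame(gene_id = "A", sequence = "ATGGCTTAA", description = "",
                     stringsAsFactors = FALSE)
  snps <- data.frame(gene_id = "A", position = c(6L, 5L), ref = c("T", "T"),
                     alt = c("C", "G"), stringsAsFactors = FALSE)
  eff <- classify_all(orfs, snps)  # position 5 is C, ref mismatch
  expect_identical(eff$effect_class[1], "silent")
  expect_true(is.na(eff$effect_class[2]))
  expect_match(eff$error[2], "mismatch")
  expect_error(classify_all(orfs, snps, strict = TRUE), "mismatch")
  expect_error(classify_all(orfs, data.frame(gene_id = "B", position = 1L,
                                             ref = "A", alt = "G")),
               "unknown gene_id")
})

test_that("frame and indeterminate-codon errors are raised", {
  expect_error(classify_snp_effect(list(gene_id = "A", sequence = "ATGG"),
                                   list(gene_id = "A", position = 1L,
                                        ref = "A", alt = "G")),
               "multiple of 3")
  expect_error(classify_snp_effect(list(gene_id = "A", sequence = "ATGGNTTAA"),
                                   list(gene_id = "A", position = 4L,
                                        ref = "G", alt = "A")),
               "indeterminate")
})

test_that("genomic-to-ORF mapping matches an independent inverse", {
  expect_identical(map_genomic_to_orf(100L, 100L, 200L, "+", "A", "G"),
                   list(orf_position = 1L, ref = "A", alt = "G"))
  expect_identical(map_genomic_to_orf(100L, 100L, 102L, "-", "A", "G"),
                   list(orf_position = 3L, ref = "T", alt = "C"))
  expect_error(map_genomic_to_orf(99L, 100L, 102L, "+", "A", "G"), "outside")

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  inverse_genomic <- function(orf_pos, start, end, strand) {
    if (strand == "+") start + orf_pos - 1L else end - orf_pos + 1L
  }
  set.seed(31)
  for (i in 1:200) {
    start <- sample(1000L, 1L)
    end <- start + sample(30:300, 1L)
    pos <- sample(start:end, 1L)
    strand <- sample(c("+", "-"), 1L)
    ref <- sample(names(comp), 1L)
    alt <- sample(setdiff(names(comp), ref), 1L)
    m <- map_genomic_to_orf(pos, start, end, strand, ref, alt)
    expect_identical(inverse_genomic(m$orf_position, start, end, strand), pos)
    if (strand == "-") {
      expect_identical(unname(comp[m$ref]), ref)
      expect_identical(unname(comp[m$alt]), alt)
    }
  }
})
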