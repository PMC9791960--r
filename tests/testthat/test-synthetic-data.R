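test_that("genome generation is deterministic and structurally sound", {
  cfg <- family_sim_config(seed = 7, n_groups = 6,
                           chromosomes_per_subgenome = 2,
                           n_background_genes = 4)
  g1 <- generate_family_genome(cfg)
  g2 <- generate_family_genome(cfg)
  expect_identical(g1, g2)

  # truth ids resolve to emitted records
  expect_true(all(g1$truth$family_gene_ids %in% g1$proteins$id))
  expect_true(all(g1$truth$family_gene_ids %in% g1$features$gene_id))
  expect_setequal(g1$proteins$id, g1$features$gene_id)
  expect_setequal(g1$proteins$id, g1$cds$id)

  # every family gene belongs to exactly one group
  expect_setequal(names(g1$truth$group_assignments), g1$truth$family_gene_ids)

  # coordinates strictly increasing and non-overlapping per chromosome
  for (ch in unique(g1$features$chrom)) {
    f <- g1$features[g1$features$chrom == ch, ]
    expect_true(all(diff(f$start) > 0))
    expect_true(all(f$start[-1] > f$end[-nrow(f)]))
  }

  # homoeologs of one group share the chromosome number across subgenomes
  for (grp in unique(g1$truth$group_assignments)) {
    members <- names(g1$truth$group_assignments)[
      g1$truth$group_assignments == grp]
    nums <- g1$features$chrom_number[match(members, g1$features$gene_id)]
    expect_equal(length(unique(nums)), 1)
  }

  # CDS translate back to the emitted proteins (with trailing stop)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(g1$cds$sequence)))
  expect_equal(sub("\\*$", "", aa), g1$proteins$sequence)
})

test_that("an all-triad mixture yields 3 genes per group by construction", {
  cfg <- family_sim_config(seed = 2, n_groups = 10,
                           ratio_mixture = c("1:1:1" = 1.0),
                           chromosomes_per_subgenome = 3,
                           n_background_genes = 2)
  g <- generate_family_genome(cfg)
  expect_equal(length(g$truth$family_gene_ids), 30)
  expect_true(all(table(g$truth$group_assignments) == 3))
  expect_true(all(g$truth$group_ratio_category == "1:1:1"))
})

test_that("planted ratio mixture is recovered within binomial error", {
  mixture <- c("1:1:1" = 0.85, "n:1:1" = 0.02, "1:1:0" = 0.07,
               "other" = 0.04, "orphan" = 0.02)
  cfg <- family_sim_config(seed = 5, n_groups = 100,
                           ratio_mixture = mixture,
                           chromosomes_per_subgenome = 7,
                           n_background_genes = 0)
  g <- generate_family_genome(cfg)
  obs <- table(factor(g$truth$group_ratio_category, levels = names(mixture)))
  for (cat in names(mixture)) {
    p <- mixture[[cat]]
    se <- sqrt(p * (1 - p) / 100)
    expect_lt(abs(obs[[cat]] / 100 - p), max(4 * se, 0.02))
  }
  # planted counts are consistent with the category labels
  for (grp in names(g$truth$group_ratio_category)) {
    cnt <- g$truth$group_counts[[grp]]
    cat <- g$truth$group_ratio_category[[grp]]
    expected <- switch(cat,
      "1:1:1" = sum(cnt == 1) == 3,
      "n:1:1" = sum(cnt > 1) == 1 && sum(cnt == 1) == 2,
      "1:1:0" = sum(cnt == 0) == 1 && sum(cnt == 1) == 2,
      "orphan" = sum(cnt) == 1,
      "other" = TRUE)
    expect_true(expected)
  }
})

test_that("ratio mixtures must sum to one", {
  expect_error(family_sim_config(ratio_mixture = c("1:1:1" = 0.5)),
               "sum to 1")
})

test_that("codon pair evolution honors its contracts", {
  # zero branch length: identical sequences
  p0 <- evolve_codon_pair(1, 50, 0, 1)
  expect_identical(p0$seq_a, p0$seq_b)
  # determinism
  expect_identical(evolve_codon_pair(9, 60, 0.3, 0.5),
                   evolve_codon_pair(9, 60, 0.3, 0.5))
  # no stop codons ever
  p <- evolve_codon_pair(3, 80, 0.8, 2)
  code <- Biostrings::GENETIC_CODE
  for (s in c(p$seq_a, p$seq_b)) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(code[cods] == "*"))
  }
  expect_error(evolve_codon_pair(1, 50, -1, 1), "branch_length")
  expect_error(evolve_codon_pair(1, 50, 1, -0.5), "omega")
  expect_error(evolve_codon_pair(1, 10, 1, 1), "n_codons")
})

test_that("purifying simulation yields omega below one almost surely", {
  est <- vapply(1:40, function(i) {
    p <- evolve_codon_pair(100 + i, 400, 0.4, 0.2)
    ka_ks(p$seq_a, p$seq_b)$omega
  }, numeric(1))
  expect_gte(mean(est < 1, na.rm = TRUE), 0.95)
})

test_that("expression generator plants DE and zeros as configured", {
  ex <- generate_expression_matrix(4, n_genes = 100,
                                   conditions = c("ctl", "trt"),
                                   replicates = 3, de_fraction = 0.2,
                                   lfc_magnitude = 3)
  expect_equal(dim(ex$tpm), c(100, 6))
  expect_equal(length(ex$truth$de_gene_ids$trt), 20)
  expect_true(all(ex$tpm >= 0))
  # determinism
  ex2 <- generate_expression_matrix(4, n_genes = 100,
                                    conditions = c("ctl", "trt"),
                                    replicates = 3, de_fraction = 0.2,
                                    lfc_magnitude = 3)
  expect_identical(ex, ex2)
  # full zero-inflation of one sample: all bins "none" there
  exz <- generate_expression_matrix(4, n_genes = 50,
                                    conditions = c("ctl", "trt"),
                                    replicates = 2,
                                    zero_samples = "trt_r1")
  cb <- census_bins(exz$tpm)
  expect_equal(cb["none", "trt_r1"], 50L)
  expect_error(generate_expression_matrix(1, de_fraction = 1.5),
               "de_fraction")
  expect_error(generate_expression_matrix(1, replicates = 1), "replicates")
})

test_that("qPCR generator inverts exactly without noise", {
  qp <- generate_qpcr_table(6, genes = "gx", treatments = c("CK", "PEG"),
                            timepoints = "6h",
                            planted_fold_changes = list(gx = list(PEG = 4)),
                            ct_noise_sd = 0)
  res <- ddct_fold_change(qp$ct, "gx", "PEG", "6h",
                          reference_gene = "beta_actin", control = "CK")
  expect_equal(res$fold_change, 4.0)
  expect_equal(res$delta_delta_ct, -2)
  expect_error(generate_qpcr_table(1, genes = "g", treatments = "CK",
                                   timepoints = "0h", reference_gene = ""),
               "reference")
})

test_that("noisy qPCR recovers planted fold on average", {
  folds <- vapply(1:60, function(i) {
    qp <- generate_qpcr_table(i, genes = "gx",
                              treatments = c("CK", "PEG"),
                              timepoints = "6h",
                              planted_fold_changes = list(gx = list(PEG = 4)),
                              ct_noise_sd = 0.2)
    ddct_fold_change(qp$ct, "gx", "PEG", "6h", control = "CK")$fold_change
  }, numeric(1))
  expect_gt(mean(folds), 3)
  expect_lt(mean(folds), 5)
})

test_that("null qPCR ANOVA keeps its nominal type-I rate", {
  pvals <- vapply(1:200, function(i) {
    qp <- generate_qpcr_table(1000 + i, genes = "gx",
                              treatments = c("CK", "PEG"),
                              timepoints = "0h",
                              ct_noise_sd = 0.3)
    ddct_fold_change(qp$ct, "gx", "PEG", "0h", control = "CK")$anova_p
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 200))
})
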