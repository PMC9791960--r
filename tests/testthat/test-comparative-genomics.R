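mk_features <- function(chrom, n, prefix) {
  data.frame(gene_id = sprintf("%s%02d", prefix, seq_len(n)),
             chrom = chrom, start = seq_len(n) * 1000L,
             end = seq_len(n) * 1000L + 500L, strand = "+",
             chrom_number = as.integer(sub("[A-Z]", "", chrom)),
             subgenome = sub("^\\d+", "", chrom),
             stringsAsFactors = FALSE)
}

test_that("anchors carry ranks and drop self/duplicate pairs", {
  fa <- rbind(mk_features("1A", 6, "a"), mk_features("1B", 6, "b"))
  hom <- data.frame(gene_a = c("a01", "a02", "a01", "b03", "a04"),
                    gene_b = c("b01", "b02", "a01", "a03", "b04"),
                    stringsAsFactors = FALSE)
  an <- build_anchors(hom, fa)
  expect_equal(nrow(an), 4)           # self pair dropped, b03~a03 canonicalized
  expect_true(all(an$gene_a < an$gene_b))
  expect_equal(an$rank_a[an$gene_a == "a04"], 3)
  expect_equal(build_anchors(hom[0, ], fa)$gene_a, character(0))
})

test_that("collinear chains obey thresholds and orientation", {
  fa <- rbind(mk_features("1A", 10, "a"), mk_features("1B", 10, "b"))
  # 6 consecutive collinear anchors
  hom <- data.frame(gene_a = sprintf("a%02d", 1:6),
                    gene_b = sprintf("b%02d", 1:6), stringsAsFactors = FALSE)
  blocks <- chain_collinear_blocks(build_anchors(hom, fa), min_anchors = 5)
  expect_equal(length(blocks), 1)
  expect_equal(blocks[[1]]$score, 6)
  expect_equal(blocks[[1]]$orientation, "same")
  # below threshold: nothing
  blocks4 <- chain_collinear_blocks(build_anchors(hom[1:4, ], fa),
                                    min_anchors = 5)
  expect_equal(length(blocks4), 0)
  # reversed order: one inverted block
  hom_inv <- data.frame(gene_a = sprintf("a%02d", 1:6),
                        gene_b = sprintf("b%02d", 6:1),
                        stringsAsFactors = FALSE)
  blocks_inv <- chain_collinear_blocks(build_anchors(hom_inv, fa),
                                       min_anchors = 5)
  expect_equal(length(blocks_inv), 1)
  expect_equal(blocks_inv[[1]]$orientation, "inverted")
  # max_gap splits distant anchors into separate (sub-threshold) chains
  fa2 <- rbind(mk_features("1A", 80, "a"), mk_features("1B", 80, "b"))
  hom_gap <- data.frame(gene_a = sprintf("a%02d", c(1:3, 60:62)),
                        gene_b = sprintf("b%02d", c(1:3, 60:62)),
                        stringsAsFactors = FALSE)
  expect_equal(length(chain_collinear_blocks(build_anchors(hom_gap, fa2),
                                             min_anchors = 5, max_gap = 25)),
               0)
  expect_equal(chain_collinear_blocks(build_anchors(hom_gap, fa2),
                                      min_anchors = 6, max_gap = 80)[[1]]$score,
               6)
})

test_that("chaining matches brute force on small instances", {
  # brute force: best monotone subset (either orientation) among <= 12 anchors
  brute_best <- function(an, max_gap) {
    n <- nrow(an)
    best <- 0
    for (mask in seq_len(2^n) - 1) {
      idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      if (length(idx) <= best) next
      for (orient in c(1, -1)) {
        o <- idx[order(an$rank_a[idx])]
        ra <- an$rank_a[o]; rb <- an$rank_b[o] * orient
        ok <- all(diff(ra) > 0) && all(diff(ra) <= max_gap) &&
          all(diff(rb) > 0) && all(abs(diff(an$rank_b[o])) <= max_gap)
        if (ok) best <- max(best, length(idx))
      }
    }
    best
  }
  set.seed(11)
  fa <- rbind(mk_features("2A", 15, "a"), mk_features("2B", 15, "b"))
  for (trial in 1:5) {
    k <- sample(6:10, 1)
    hom <- data.frame(gene_a = sprintf("a%02d", sample(1:15, k)),
                      gene_b = sprintf("b%02d", sample(1:15, k)),
                      stringsAsFactors = FALSE)
    an <- build_anchors(hom, fa)
    blocks <- chain_collinear_blocks(an, min_anchors = 1, max_gap = 10)
    got <- max(c(0, vapply(blocks, `[[`, numeric(1), "score")))
    expect_equal(got, brute_best(an, 10), info = paste("trial", trial))
  }
})

test_that("duplication typing ranks tandem over segmental over dispersed", {
  fa <- rbind(mk_features("3A", 12, "a"), mk_features("3B", 12, "b"))
  hom <- data.frame(gene_a = sprintf("a%02d", 1:6),
                    gene_b = sprintf("b%02d", 1:6), stringsAsFactors = FALSE)
  blocks <- chain_collinear_blocks(build_anchors(hom, fa), min_anchors = 5)
  # adjacent homologs on one chromosome: tandem
  expect_equal(classify_duplication(c("a01", "a02"), blocks, fa), "tandem")
  # a planted anchor inside the detected block: segmental
  expect_equal(classify_duplication(c("a03", "b03"), blocks, fa), "segmental")
  # isolated cross-chromosome pair: dispersed
  expect_equal(classify_duplication(c("a12", "b09"), blocks, fa), "dispersed")
  # same chromosome but outside the window and not in a block: dispersed
  expect_equal(classify_duplication(c("a01", "a12"), blocks, fa,
                                    tandem_window = 5), "dispersed")
})

test_that("ratio classification follows the triad taxonomy", {
  expect_equal(classify_ratio(c(1, 1, 1, 0)), "1:1:1")
  expect_equal(classify_ratio(c(2, 1, 1, 0)), "n:1:1-type")
  expect_equal(classify_ratio(c(1, 1, 0, 0)), "loss-of-one")
  expect_equal(classify_ratio(c(0, 1, 2, 0)), "other")
  expect_equal(classify_ratio(c(1, 0, 0, 0)), "orphan")
  expect_equal(classify_ratio(c(1, 1, 1)), "1:1:1")     # nU defaults to 0
  expect_equal(classify_ratio(c(2, 0, 0, 0)), "uncategorized")
  expect_equal(classify_ratio(c(1, 0, 2, 2)), "other")  # unplaced members
  expect_equal(classify_ratio(c(0, 0, 1, 0)), "orphan")
  expect_error(classify_ratio(c(-1, 1, 1, 0)), "non-negative")
})

test_that("homoeolog grouping recovers the planted partition", {
  cfg <- family_sim_config(seed = 31, n_groups = 12,
                           chromosomes_per_subgenome = 3,
                           n_background_genes = 4)
  genome <- generate_family_genome(cfg)
  truth <- genome$truth
  grp0 <- truth$group_assignments
  queries <- genome$proteins[
    genome$proteins$id %in% names(grp0)[grp0 %in% c("G001", "G002")], ]
  catalog <- identify_family(genome$proteins, queries, genome$features)
  hits <- family_similarity_hits(catalog, genome$proteins)
  groups <- group_homoeologs(catalog, hits)
  # every catalog gene in exactly one group
  expect_setequal(groups$gene_id, catalog$gene_id)
  expect_equal(anyDuplicated(groups$gene_id), 0)
  # recovered partition == planted partition
  tab <- table(grp0[groups$gene_id], groups$group_id)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
  # census equals the planted mixture exactly
  census <- summarize_triads(groups)
  planted <- table(factor(truth$group_ratio_category,
                          levels = c("1:1:1", "n:1:1", "1:1:0", "other",
                                     "orphan")))
  expect_equal(census$n_groups[census$category == "1:1:1"],
               unname(planted[["1:1:1"]]))
  expect_equal(census$n_groups[census$category == "n:1:1-type"],
               unname(planted[["n:1:1"]]))
  expect_equal(census$n_groups[census$category == "loss-of-one"],
               unname(planted[["1:1:0"]]))
  expect_equal(census$n_groups[census$category == "orphan"],
               unname(planted[["orphan"]]))
  expect_equal(sum(census$n_genes), nrow(catalog))
})

test_that("genes on different chromosome numbers are never grouped", {
  catalog <- data.frame(gene_id = c("x3A", "x5B"),
                        chrom_number = c(3L, 5L),
                        subgenome = c("A", "B"), stringsAsFactors = FALSE)
  hits <- data.frame(gene_a = "x3A", gene_b = "x5B", score = 1000,
                     stringsAsFactors = FALSE)
  groups <- group_homoeologs(catalog, hits)
  expect_equal(length(unique(groups$group_id)), 2)
  # singleton gene becomes an orphan group
  census <- summarize_triads(groups)
  expect_equal(census$n_groups[census$category == "orphan"], 2L)
})

test_that("the packaged table reproduces the printed homoeolog census", {
  census <- domain_table_census()
  get <- function(cat, col) census[census$category == cat, col]
  expect_equal(get("1:1:1", "n_groups"), 69L)
  expect_equal(get("1:1:1", "n_genes"), 207L)
  expect_equal(get("1:1:1", "pct_genes"), 84.8)
  expect_equal(get("n:1:1-type", "n_genes"), 4L)
  expect_equal(get("n:1:1-type", "pct_genes"), 1.6)
  expect_equal(get("loss-of-one", "n_groups"), 8L)
  expect_equal(get("loss-of-one", "n_genes"), 16L)
  expect_equal(get("loss-of-one", "pct_genes"), 6.6)
  expect_equal(get("other", "n_groups"), 3L)
  expect_equal(get("other", "n_genes"), 11L)
  expect_equal(get("other", "pct_genes"), 4.5)
  expect_equal(get("orphan", "n_groups"), 4L)
  expect_equal(get("uncategorized", "n_genes"), 2L)
  expect_equal(sum(census$n_genes), 244L)
  expect_equal(sum(census$pct_genes), 100, tolerance = 0.2)
})

test_that("domain-type census reproduces the printed totals", {
  counts <- domain_type_census()
  expect_equal(attr(counts, "total"), 244L)
  expect_equal(counts[["PHD"]], 43L)
  expect_equal(counts[["Jas-PHD"]], 28L)
  expect_equal(counts[["Alifn-PHD"]], 25L)
  expect_equal(counts[["PHD-Oberon_cc"]], 11L)
  expect_equal(counts[["PHD-RING"]], 11L)
})
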