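blosum62 <- local({
  e <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

test_that("local alignment scores match their closed forms", {
  set.seed(1)
  s <- paste(sample(AA_LETTERS <- c("A","R","N","D","C","Q","E","G","H","I",
                                    "L","K","M","F","P","S","T","W","Y","V"),
                    20, replace = TRUE), collapse = "")
  diag_sum <- sum(blosum62[cbind(strsplit(s, "")[[1]],
                                 strsplit(s, "")[[1]])])
  expect_equal(smith_waterman(s, s), diag_sum)

  # all-negative substitution pairs: the empty local alignment wins
  expect_equal(smith_waterman("KKKK", "DDDD"), 0)
  expect_error(smith_waterman("", "AAA"), "non-empty")
  expect_error(smith_waterman("AAO", "AAA"), "unknown residue")
})

test_that("local alignment equals an independent Gotoh DP oracle", {
  aas <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")
  for (i in 1:25) {
    set.seed(200 + i)
    q <- paste(sample(aas, 30, replace = TRUE), collapse = "")
    t <- paste(sample(aas, 30, replace = TRUE), collapse = "")
    expect_equal(smith_waterman(q, t),
                 sw_score_oracle(q, t, blosum62),
                 info = paste("pair", i))
  }
})

test_that("E-values follow the Karlin-Altschul form", {
  # hand-calculator cross-check: K m n exp(-lambda S)
  expect_equal(estimate_evalue(100, 300, 300),
               0.041 * 300 * 300 * exp(-0.267 * 100), tolerance = 1e-12)
  # linear in database size; decreasing in score
  expect_equal(estimate_evalue(50, 300, 600),
               2 * estimate_evalue(50, 300, 300))
  expect_lt(estimate_evalue(120, 300, 300), estimate_evalue(80, 300, 300))
  expect_lt(estimate_evalue(1e6, 300, 300), 1e-300)
  expect_error(estimate_evalue(10, 0, 300), "positive")
})

test_that("motif scanner finds planted domains and nothing else", {
  # poly-Ala also trips the nucleotide-alphabet heuristic (A is ambiguous)
  expect_equal(nrow(suppressWarnings(scan_phd_motif(strrep("A", 200)))), 0)
  expect_equal(nrow(scan_phd_motif(strrep("L", 200))), 0)
  expect_warning(res <- scan_phd_motif("ACGTACGTACGT"), "nucleotide")
  expect_equal(nrow(res), 0)

  # a planted canonical motif at a known offset
  set.seed(42)
  motif <- polyfam:::sample_motif(default_spacer_ranges())
  flank <- function(n) paste(sample(setdiff(polyfam:::AA20, c("C", "H")),
                                    n, replace = TRUE), collapse = "")
  prot <- paste0(flank(40), motif$seq, flank(60))
  hits <- scan_phd_motif(prot)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 41)
  expect_equal(hits$end, 40 + nchar(motif$seq))
  lig <- hits$ligands[[1]]
  expect_equal(length(lig), 8)
  expect_true(all(diff(lig) > 0))
  chars <- strsplit(prot, "")[[1]]
  expect_equal(chars[lig], c("C","C","C","C","H","C","C","C"))
  expect_equal(lig, 40 + unname(motif$ligand_offsets))

  # two planted motifs far apart: two non-overlapping hits
  motif2 <- polyfam:::sample_motif(default_spacer_ranges())
  prot2 <- paste0(flank(30), motif$seq, flank(100), motif2$seq, flank(20))
  hits2 <- scan_phd_motif(prot2)
  expect_equal(nrow(hits2), 2)
  expect_lt(hits2$end[1], hits2$start[2])
})

test_that("naming follows chromosomal order with unplaced genes last", {
  feats <- data.frame(
    gene_id = c("gz", "gy", "gx", "gw", "gu"),
    chrom = c("1A", "1A", "1B", "2A", "U"),
    start = c(100L, 500L, 50L, 10L, 7L),
    end = c(200L, 600L, 80L, 20L, 9L),
    strand = "+",
    chrom_number = c(1L, 1L, 1L, 2L, NA),
    subgenome = c("A", "A", "B", "A", "U"),
    stringsAsFactors = FALSE)
  named <- assign_names(feats, prefix = "FAM")
  expect_equal(named$gene_id, c("gz", "gy", "gx", "gw", "gu"))
  expect_equal(named$name, paste0("FAM", 1:5))
  # a 1D gene must precede a 2A gene
  feats2 <- data.frame(gene_id = c("a", "b"), chrom = c("2A", "1D"),
                       start = c(1L, 999L), end = c(5L, 1000L), strand = "+",
                       chrom_number = c(2L, 1L), subgenome = c("A", "D"),
                       stringsAsFactors = FALSE)
  named2 <- assign_names(feats2, "FAM")
  expect_equal(named2$gene_id, c("b", "a"))
  # ties in start broken by gene id
  feats3 <- data.frame(gene_id = c("g2", "g1"), chrom = "3A",
                       start = c(10L, 10L), end = c(20L, 20L), strand = "+",
                       chrom_number = 3L, subgenome = "A",
                       stringsAsFactors = FALSE)
  expect_equal(assign_names(feats3, "F")$gene_id, c("g1", "g2"))
})

test_that("identification recovers exactly the planted family", {
  cfg <- family_sim_config(seed = 21, n_groups = 8,
                           chromosomes_per_subgenome = 2,
                           n_background_genes = 6)
  genome <- generate_family_genome(cfg)
  truth <- genome$truth
  grp <- truth$group_assignments
  queries <- genome$proteins[
    genome$proteins$id %in% names(grp)[grp %in% c("G001", "G002")], ]
  catalog <- identify_family(genome$proteins, queries, genome$features,
                             prefix = "FAM")
  expect_setequal(catalog$gene_id, truth$family_gene_ids)   # sens = spec = 1
  expect_true(all(catalog$n_domains >= 1))
  expect_equal(catalog$name, paste0("FAM", seq_len(nrow(catalog))))

  # order independence: permuting the proteome yields the same catalog
  set.seed(1)
  shuffled <- genome$proteins[sample(nrow(genome$proteins)), ]
  catalog2 <- identify_family(shuffled, queries, genome$features,
                              prefix = "FAM")
  expect_equal(catalog2, catalog)

  # degenerate gates
  expect_equal(nrow(identify_family(genome$proteins,
                                    queries[0, ], genome$features)), 0)
  expect_equal(nrow(identify_family(genome$proteins, queries,
                                    genome$features,
                                    evalue_threshold = 0)), 0)
})

test_that("accepted genes without coordinates surface as unplaced", {
  cfg <- family_sim_config(seed = 22, n_groups = 3,
                           chromosomes_per_subgenome = 1,
                           n_background_genes = 2)
  genome <- generate_family_genome(cfg)
  grp <- genome$truth$group_assignments
  queries <- genome$proteins[genome$proteins$id %in% names(grp), ][1:2, ]
  drop_id <- genome$truth$family_gene_ids[1]
  gff <- genome$features[genome$features$gene_id != drop_id, ]
  catalog <- identify_family(genome$proteins, queries, gff, prefix = "FAM")
  expect_false(drop_id %in% catalog$gene_id)
  expect_true(drop_id %in% attr(catalog, "unplaced"))
})

test_that("the first isoform represents its gene", {
  prot <- data.frame(id = c("g1.2", "g1.1", "g2.1"), description = "",
                     sequence = c("MA", "MB", "MC"), stringsAsFactors = FALSE)
  map <- c("g1.2" = "g1", "g1.1" = "g1", "g2.1" = "g2")
  rep <- select_representative_isoforms(prot, map)
  expect_equal(rep$id, c("g1", "g2"))
  expect_equal(rep$sequence, c("MB", "MC"))  # g1.1 is lexicographically first
})
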