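# Comparative genomics: anchor pairs, collinear-block chaining, duplication
# typing, homoeolog grouping and the A:B:D triad census.

#' Gene ranks along each chromosome
#'
#' 0-based index of every gene along its chromosome (all genes, not only
#' family members), by start coordinate.
#'
#' @param features Gene table (as from [read_gff3()]).
#' @return `features` with a `rank` column appended.
#' @export
gene_ranks <- function(features) {
  features$rank <- NA_integer_
  for (ch in unique(features$chrom)) {
    idx <- which(features$chrom == ch)
    features$rank[idx[order(features$start[idx], features$gene_id[idx])]] <-
      seq_along(idx) - 1L
  }
  features
}

#' Build anchor pairs from homology calls
#'
#' One anchor per homologous gene pair, annotated with each gene's
#' chromosome and rank. Self-pairs are dropped; pairs are canonicalized
#' (gene_a < gene_b) and de-duplicated.
#'
#' @param homologs Data frame with `gene_a`, `gene_b` columns.
#' @param features_a,features_b Gene tables for the two genomes
#'   (`features_b` defaults to `features_a` for a self-comparison).
#' @return Data frame: `gene_a`, `gene_b`, `chrom_a`, `chrom_b`, `rank_a`,
#'   `rank_b`.
#' @export
build_anchors <- function(homologs, features_a, features_b = features_a) {
  if (!nrow(homologs))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      chrom_a = character(0), chrom_b = character(0),
                      rank_a = integer(0), rank_b = integer(0)))
  ra <- gene_ranks(features_a)
  rb <- gene_ranks(features_b)
  self_cmp <- identical(features_a, features_b)
  h <- homologs[homologs$gene_a != homologs$gene_b, , drop = FALSE]
  if (self_cmp) {
    swap <- h$gene_a > h$gene_b
    tmp <- h$gene_a[swap]; h$gene_a[swap] <- h$gene_b[swap]
    h$gene_b[swap] <- tmp
  }
  h <- h[!duplicated(h[, c("gene_a", "gene_b")]), , drop = FALSE]
  ia <- match(h$gene_a, ra$gene_id)
  ib <- match(h$gene_b, rb$gene_id)
  if (anyNA(ia) || anyNA(ib))
    stop("homolog gene missing from features: ",
         c(h$gene_a[is.na(ia)], h$gene_b[is.na(ib)])[1])
  out <- data.frame(gene_a = h$gene_a, gene_b = h$gene_b,
                    chrom_a = ra$chrom[ia], chrom_b = rb$chrom[ib],
                    rank_a = ra$rank[ia], rank_b = rb$rank[ib],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Chain anchors into collinear blocks
#'
#' Per chromosome pair and orientation, maximal collinear chains are found by
#' longest-increasing-subsequence dynamic programming over anchor ranks (both
#' ranks strictly monotone; rank gaps at most `max_gap`), extracted greedily
#' best-first with used anchors removed. Chains shorter than `min_anchors`
#' are discarded.
#'
#' @param anchors Anchor table from [build_anchors()].
#' @param min_anchors Minimum anchors per block (default 5, a common
#'   collinearity-scan default).
#' @param max_gap Maximum rank gap between consecutive anchors (default 25).
#' @return List of blocks; each is a list with `anchors` (data frame),
#'   `orientation` (`"same"`/`"inverted"`), `chrom_a`, `chrom_b`, `score`
#'   (anchor count).
#' @export
chain_collinear_blocks <- function(anchors, min_anchors = 5, max_gap = 25) {
  blocks <- list()
  if (!nrow(anchors)) return(blocks)
  key <- paste(anchors$chrom_a, anchors$chrom_b, sep = "~")
  for (cp in unique(key)) {
    sub <- anchors[key == cp, , drop = FALSE]
    repeat {
      if (!nrow(sub)) break
      ch_same <- best_chain(sub, "same", max_gap)
      ch_inv <- best_chain(sub, "inverted", max_gap)
      orient <- if (length(ch_same) >= length(ch_inv)) "same" else "inverted"
      chain <- if (orient == "same") ch_same else ch_inv
      if (length(chain) < min_anchors) break
      blk <- sub[chain, , drop = FALSE]
      blocks[[length(blocks) + 1]] <-
        list(anchors = blk, orientation = orient,
             chrom_a = blk$chrom_a[1], chrom_b = blk$chrom_b[1],
             score = nrow(blk))
      sub <- sub[-chain, , drop = FALSE]
    }
  }
  blocks
}

# Best chain (row indices into `sub`) with both ranks strictly monotone
# (rank_b increasing for "same", decreasing for "inverted") and gaps <=
# max_gap on both axes; classic O(n^2) DP.
best_chain <- function(sub, orient, max_gap) {
  n <- nrow(sub)
  if (!n) return(integer(0))
  ord <- order(sub$rank_a, if (orient == "same") sub$rank_b else -sub$rank_b)
  a <- sub$rank_a[ord]
  b <- sub$rank_b[ord]
  best <- rep(1L, n)
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      ok_a <- a[j] < a[i] && a[i] - a[j] <= max_gap
      ok_b <- if (orient == "same") b[j] < b[i] && b[i] - b[j] <= max_gap
              else b[j] > b[i] && b[j] - b[i] <= max_gap
      if (ok_a && ok_b && best[j] + 1L > best[i]) {
        best[i] <- best[j] + 1L
        prev[i] <- j
      }
    }
  }
  end <- which.max(best)
  chain <- integer(0)
  while (end != 0) { chain <- c(end, chain); end <- prev[end] }
  ord[chain]
}

#' Classify a duplicate gene pair
#'
#' `tandem` if both genes sit on the same chromosome within `tandem_window`
#' gene ranks; otherwise `segmental` if the pair is an anchor of any detected
#' collinear block; otherwise `dispersed`. Tandem takes precedence.
#'
#' @param pair Character vector of two gene ids.
#' @param blocks Blocks from [chain_collinear_blocks()].
#' @param features Gene table covering both genes.
#' @param tandem_window Maximum rank separation for tandem duplicates
#'   (default 5).
#' @return One of `"tandem"`, `"segmental"`, `"dispersed"`.
#' @export
classify_duplication <- function(pair, blocks, features, tandem_window = 5) {
  rf <- gene_ranks(features)
  i <- match(pair[1], rf$gene_id); j <- match(pair[2], rf$gene_id)
  if (is.na(i) || is.na(j)) stop("pair gene missing from features")
  if (rf$chrom[i] == rf$chrom[j] &&
      abs(rf$rank[i] - rf$rank[j]) <= tandem_window) return("tandem")
  for (blk in blocks) {
    hit <- (blk$anchors$gene_a == pair[1] & blk$anchors$gene_b == pair[2]) |
           (blk$anchors$gene_a == pair[2] & blk$anchors$gene_b == pair[1])
    if (any(hit)) return("segmental")
  }
  "dispersed"
}

#' Group family genes into homoeologous groups
#'
#' Single-linkage connected components over reciprocal-best cross-subgenome
#' hits restricted to identical chromosome numbers. Hits within `tie_tol`
#' (relative score) of a gene's best hit in a subgenome count as co-best, so
#' duplicated homoeologs join their group. Every catalog gene lands in
#' exactly one group (possibly a singleton).
#'
#' @param catalog Gene catalog (needs `gene_id`, `chrom_number`, `subgenome`).
#' @param hits Data frame `gene_a`, `gene_b`, `score` of similarity hits
#'   among family genes (undirected; only cross-subgenome pairs are used).
#'   An optional `frac` column (score over the smaller self-alignment score)
#'   gates candidate homoeolog pairs at `min_self_frac` — homoeologs are
#'   near-identical, cross-group paralogs are not.
#' @param tie_tol Relative tolerance for co-best hits (default 0.05).
#' @param min_self_frac Minimum `frac` for a hit to count as a candidate
#'   homoeolog pair (default 0.75; ignored when `hits` has no `frac`).
#' @return Data frame: `group_id`, `gene_id`, `chrom_number`, `subgenome`.
#' @export
group_homoeologs <- function(catalog, hits, tie_tol = 0.05,
                             min_self_frac = 0.75) {
  ids <- catalog$gene_id
  sg <- stats::setNames(catalog$subgenome, ids)
  cn <- stats::setNames(catalog$chrom_number, ids)
  edges <- list()
  if (!is.null(hits$frac))
    hits <- hits[hits$frac >= min_self_frac, , drop = FALSE]
  if (nrow(hits)) {
    h <- rbind(hits[, c("gene_a", "gene_b", "score")],
               stats::setNames(hits[, c("gene_b", "gene_a", "score")],
                               c("gene_a", "gene_b", "score")))
    h <- h[h$gene_a %in% ids & h$gene_b %in% ids, , drop = FALSE]
    h <- h[sg[h$gene_a] != sg[h$gene_b] &
             !is.na(cn[h$gene_a]) & !is.na(cn[h$gene_b]) &
             cn[h$gene_a] == cn[h$gene_b], , drop = FALSE]
    if (nrow(h)) {
      # per (gene, other subgenome): the set of co-best partners
      grp <- paste(h$gene_a, sg[h$gene_b], sep = "~")
      best <- tapply(h$score, grp, max)
      h$cobest <- h$score >= (1 - tie_tol) * best[grp]
      hb <- h[h$cobest, , drop = FALSE]
      fwd <- paste(hb$gene_a, hb$gene_b)
      rev <- paste(hb$gene_b, hb$gene_a)
      recip <- fwd %in% rev
      edges <- hb[recip, c("gene_a", "gene_b"), drop = FALSE]
    }
  }
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (length(edges) && nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- find(match(edges$gene_a[k], ids))
      b <- find(match(edges$gene_b[k], ids))
      if (a != b) parent[b] <- a
    }
  }
  comp <- vapply(seq_along(ids), find, numeric(1))
  comp_ids <- split(ids, comp)
  # stable group ids ordered by first member
  comp_ids <- comp_ids[order(vapply(comp_ids, function(g) sort(g)[1],
                                    character(1)))]
  out <- do.call(rbind, lapply(seq_along(comp_ids), function(i) {
    data.frame(group_id = sprintf("HG%03d", i), gene_id = comp_ids[[i]],
               stringsAsFactors = FALSE)
  }))
  out$chrom_number <- cn[out$gene_id]
  out$subgenome <- sg[out$gene_id]
  rownames(out) <- NULL
  out
}

#' Classify a homoeologous group's A:B:D ratio
#'
#' Categories follow the standard allohexaploid triad taxonomy:
#' complete triads (`1:1:1`), homoeolog-specific duplication (`n:1:1-type`,
#' one subgenome with n > 1 copies, the others single), loss of one
#' homoeolog (`loss-of-one`), singletons (`orphan`), mixed ratios including
#' groups with unplaced members (`other`), and multi-gene groups confined to
#' a single subgenome, whose homoeologous ratio is not measurable
#' (`uncategorized`).
#'
#' @param counts Integer vector `(nA, nB, nD)` or `(nA, nB, nD, nU)`.
#' @return The category label.
#' @export
classify_ratio <- function(counts) {
  if (length(counts) == 3) counts <- c(counts, 0L)
  if (length(counts) != 4 || any(counts < 0))
    stop("counts must be (nA, nB, nD[, nU]) with non-negative entries")
  nU <- counts[4]
  abd <- counts[1:3]
  if (sum(counts) == 1) return("orphan")
  if (nU == 0) {
    if (all(abd == 1)) return("1:1:1")
    if (sum(abd > 1) == 1 && sum(abd == 1) == 2) return("n:1:1-type")
    if (sum(abd == 0) == 1 && sum(abd == 1) == 2) return("loss-of-one")
  }
  if (sum(abd > 0) == 1) return("uncategorized")
  "other"
}

#' Summarize homoeologous groups into the triad census
#'
#' Per category: number of groups, number of genes, and percent of the total
#' catalog (one decimal, percentages computed on `total_genes`).
#'
#' @param groups Data frame as from [group_homoeologs()], or any data frame
#'   with `group_id` and `subgenome` columns (`subgenome` in A/B/D/U).
#' @param total_genes Denominator for percentages (defaults to the number of
#'   genes in `groups`).
#' @return Data frame: `category`, `n_groups`, `n_genes`, `pct_genes`.
#' @export
summarize_triads <- function(groups, total_genes = nrow(groups)) {
  cats <- c("1:1:1", "n:1:1-type", "loss-of-one", "other", "orphan",
            "uncategorized")
  by_grp <- split(groups$subgenome, groups$group_id)
  cat_of <- vapply(by_grp, function(sgs) {
    classify_ratio(c(sum(sgs == "A"), sum(sgs == "B"), sum(sgs == "D"),
                     sum(sgs == "U")))
  }, character(1))
  sizes <- lengths(by_grp)
  out <- data.frame(
    category = cats,
    n_groups = vapply(cats, function(cc) sum(cat_of == cc), integer(1)),
    n_genes = vapply(cats, function(cc) sum(sizes[cat_of == cc]), integer(1)),
    stringsAsFactors = FALSE)
  out$pct_genes <- round(100 * out$n_genes / total_genes, 1)
  rownames(out) <- NULL
  out
}

#' Parse a subgenome-composition field into counts
#'
#' Fields like `"A(DD)UU"` from the packaged domain table: parentheses are
#' stripped and each subgenome letter counted; `U` counts into the unplaced
#' bucket.
#'
#' @param field Character vector of composition strings.
#' @return Integer matrix with columns `nA`, `nB`, `nD`, `nU`.
#' @export
parse_genomes_field <- function(field) {
  letters_only <- gsub("[()]", "", field)
  t(vapply(strsplit(letters_only, ""), function(ch) {
    c(nA = sum(ch == "A"), nB = sum(ch == "B"), nD = sum(ch == "D"),
      nU = sum(ch == "U"))
  }, integer(4)))
}

#' Triad census of the packaged domain table
#'
#' Treats each domain-table row as one homoeologous group and summarizes the
#' A:B:D composition census.
#'
#' @param table Parsed domain table (from [parse_domain_table()]).
#' @return As [summarize_triads()].
#' @export
domain_table_census <- function(table = parse_domain_table()) {
  counts <- parse_genomes_field(table$genomes_field)
  total <- sum(table$gene_number)
  mismatch <- which(rowSums(counts) != table$gene_number)
  if (length(mismatch))
    stop("row ", mismatch[1], ": genomes field letters (",
         rowSums(counts)[mismatch[1]], ") do not match gene_number")
  groups <- data.frame(
    group_id = rep(sprintf("ROW%02d", seq_len(nrow(table))),
                   times = table$gene_number),
    subgenome = unlist(lapply(seq_len(nrow(table)), function(i) {
      rep(c("A", "B", "D", "U"), times = counts[i, ])
    })),
    stringsAsFactors = FALSE)
  summarize_triads(groups, total_genes = total)
}

#' Gene counts per domain type in the packaged domain table
#'
#' @param table Parsed domain table (from [parse_domain_table()]).
#' @return Named integer vector: domain type -> gene count, plus attribute
#'   `total` with the overall gene count.
#' @export
domain_type_census <- function(table = parse_domain_table()) {
  counts <- tapply(table$gene_number, table$domain_type, sum)
  out <- stats::setNames(as.integer(counts), names(counts))
  attr(out, "total") <- sum(table$gene_number)
  out
}
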