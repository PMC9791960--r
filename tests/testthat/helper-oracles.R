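# Independent oracles used across the suite. Each re-derives a quantity by a
# different algorithm than the package implementation.

# Affine-gap local alignment score by explicit Gotoh dynamic programming.
# Gap of length L costs gap_open + L * gap_extend; empty alignment admissible.
sw_score_oracle <- function(query, target, mat, gap_open = 11,
                            gap_extend = 1) {
  q <- strsplit(query, "")[[1]]
  t <- strsplit(target, "")[[1]]
  n <- length(q); m <- length(t)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in query (consume target)
  F_ <- matrix(-Inf, n + 1, m + 1) # gap in target (consume query)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F_[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                      F_[i - 1, j] - gap_extend)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + mat[q[i - 1], t[j - 1]],
                     E[i, j], F_[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Pathway-averaged NG86 differences by recursive path counting over the
# codon graph (a different traversal than the permutation enumeration in the
# implementation). Returns c(sd, nd); NULL if every path is blocked.
ng86_pathway_oracle <- function(codon_a, codon_b) {
  code <- Biostrings::GENETIC_CODE
  walk <- function(cur, target) {
    # returns c(total_sd, total_nd, n_paths) over all unblocked orderings
    diffs <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(diffs)) return(c(0, 0, 1))
    acc <- c(0, 0, 0)
    for (pos in diffs) {
      nxt <- strsplit(cur, "")[[1]]
      nxt[pos] <- strsplit(target, "")[[1]][pos]
      nxt <- paste(nxt, collapse = "")
      if (code[[nxt]] == "*") next
      sub <- walk(nxt, target)
      if (sub[3] == 0) next
      step_syn <- as.numeric(code[[cur]] == code[[nxt]])
      acc <- acc + c(sub[1] + sub[3] * step_syn,
                     sub[2] + sub[3] * (1 - step_syn),
                     sub[3])
    }
    acc
  }
  res <- walk(toupper(codon_a), toupper(codon_b))
  if (res[3] == 0) return(NULL)
  c(sd = res[1] / res[3], nd = res[2] / res[3])
}

# NG86 site counts by direct enumeration of the nine single-nucleotide
# changes against the genetic code (no shared machinery with the package).
ng86_sites_oracle <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  nucs <- c("A", "C", "G", "T")
  ch <- strsplit(toupper(codon), "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0; usable <- 0
    for (alt in setdiff(nucs, ch[pos])) {
      mut <- ch; mut[pos] <- alt
      mut <- paste(mut, collapse = "")
      if (code[[mut]] == "*") next
      usable <- usable + 1
      if (code[[mut]] == code[[paste(ch, collapse = "")]]) syn <- syn + 1
    }
    if (usable > 0) s <- s + syn / usable
  }
  c(s = s, n = 3 - s)
}

# All unrooted binary topologies over the given taxa, as ape trees with
# unit branch lengths (recursive edge insertion).
all_unrooted_topologies <- function(taxa) {
  stopifnot(length(taxa) >= 3)
  base <- sprintf("(%s,%s,%s);", taxa[1], taxa[2], taxa[3])
  trees <- list(ape::read.tree(text = base))
  for (k in seq_along(taxa)[-(1:3)]) {
    new_trees <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edge))) {
        t2 <- phangorn_free_bind(tr, taxa[k], e)
        new_trees[[length(new_trees) + 1]] <- t2
      }
    }
    trees <- new_trees
  }
  trees
}

# Insert a new tip into edge e of an unrooted tree (pure ape surgery).
phangorn_free_bind <- function(tree, tip, e) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  ape::bind.tree(tree, structure(list(edge = matrix(c(2L, 1L), 1, 2),
                                      tip.label = tip, edge.length = 1,
                                      Nnode = 1L), class = "phylo"),
                 where = tree$edge[e, 2], position = 0.5)
}

# Least-squares branch lengths for a fixed topology against a distance
# matrix; returns list(sse, lengths). Edges parameterized by indicator of
# tip-pair paths.
ls_fit_topology <- function(tree, d) {
  taxa <- rownames(d)
  tree <- ape::unroot(tree)
  n <- length(taxa)
  pairs <- utils::combn(taxa, 2)
  n_edges <- nrow(tree$edge)
  X <- matrix(0, ncol(pairs), n_edges)
  y <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    path_edges <- edges_on_path(tree, pairs[1, p], pairs[2, p])
    X[p, path_edges] <- 1
    y[p] <- d[pairs[1, p], pairs[2, p]]
  }
  fit <- stats::lm.fit(X, y)
  sse <- sum(fit$residuals^2)
  list(sse = sse, lengths = fit$coefficients, tree = tree)
}

edges_on_path <- function(tree, tip_a, tip_b) {
  # path between two tips via node parents
  ntip <- length(tree$tip.label)
  a <- match(tip_a, tree$tip.label)
  b <- match(tip_b, tree$tip.label)
  parent_of <- function(x) tree$edge[tree$edge[, 2] == x, 1]
  anc <- function(x) {
    out <- x
    while (length(p <- parent_of(x))) { out <- c(out, p); x <- p }
    out
  }
  pa <- anc(a); pb <- anc(b)
  common <- intersect(pa, pb)[1]
  edges <- integer(0)
  # collect edges along a-to-common and b-to-common
  for (x in list(pa[seq_len(which(pa == common))],
                 pb[seq_len(which(pb == common))])) {
    for (i in seq_len(length(x) - 1)) {
      edges <- c(edges, which(tree$edge[, 1] == x[i + 1] &
                                tree$edge[, 2] == x[i]))
    }
  }
  unique(edges)
}

# Unrooted bipartition set of a tree, as sorted strings of the smaller side.
bipartition_set <- function(tree) {
  ntip <- length(tree$tip.label)
  all_tips <- sort(tree$tip.label)
  root <- ntip + 1
  internal <- setdiff(unique(tree$edge[, 1]), root)
  out <- character(0)
  for (node in internal) {
    kids <- integer(0)
    stack <- node
    while (length(stack)) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      ch <- tree$edge[tree$edge[, 1] == x, 2]
      kids <- c(kids, ch[ch <= ntip])
      stack <- c(stack, ch[ch > ntip])
    }
    tips <- sort(tree$tip.label[kids])
    other <- setdiff(all_tips, tips)
    if (length(tips) < 2 || length(other) < 2) next
    side <- if (length(tips) < length(other)) tips
            else if (length(other) < length(tips)) other
            else if (tips[1] < other[1]) tips else other
    out <- c(out, paste(side, collapse = "|"))
  }
  sort(unique(out))
}

# A random additive (tree-metric) distance matrix: random topology with
# positive branch lengths, distances = path lengths.
random_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  taxa <- paste0("t", seq_len(n_taxa))
  tr <- ape::rtree(n_taxa, rooted = FALSE, tip.label = taxa)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 3)
  list(d = ape::cophenetic.phylo(tr)[taxa, taxa], tree = tr)
}
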