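# Distance-based phylogenetics: Poisson-corrected amino-acid distances,
# neighbor joining, bootstrap supports, clade assignment.

#' Proportion of differing sites between two aligned sequences
#'
#' Pairwise-deletion gap handling: sites where either sequence holds a gap
#' (`-` or `.`) are excluded from both numerator and denominator.
#'
#' @param a,b Aligned sequences of equal length.
#' @return p-distance in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb)) stop("aligned sequences differ in length")
  gap <- ca %in% c("-", ".") | cb %in% c("-", ".")
  usable <- !gap
  if (!any(usable)) stop("no comparable sites (all-gap overlap)")
  sum(ca[usable] != cb[usable]) / sum(usable)
}

#' Poisson correction of a p-distance
#'
#' `d = -ln(1 - p)`, the expected number of substitutions per site under a
#' Poisson model of equal rates across sites.
#'
#' @param p Proportion of differing sites, `0 <= p < 1`.
#' @return Corrected distance (substitutions per site).
#' @export
poisson_correct <- function(p) {
  if (any(p < 0 | p >= 1)) stop("p must satisfy 0 <= p < 1 (saturation at 1)")
  -log(1 - p)
}

#' Poisson-corrected distance matrix from an alignment
#'
#' @param alignment Sequence table (as from [read_fasta()]) of aligned
#'   sequences.
#' @return Symmetric numeric matrix with taxon dimnames.
#' @export
alignment_distances <- function(alignment) {
  n <- nrow(alignment)
  d <- matrix(0, n, n, dimnames = list(alignment$id, alignment$id))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d[i, j] <- d[j, i] <-
      poisson_correct(p_distance(alignment$sequence[i],
                                 alignment$sequence[j]))
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei NJ: iteratively join the pair minimizing
#' `Q(i, j) = (r - 2) d(i, j) - R_i - R_j` (with `R_i` the row sum over
#' active nodes), attach the pair at branch lengths given by the
#' rate-corrected split formula, and reduce the matrix. Negative branch
#' lengths are clamped to zero. Ties in Q are broken by the first (row-major)
#' minimal pair, so the result is deterministic.
#'
#' @param d Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(d) {
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # each active node carries its newick subtree string
  sub <- labels
  D <- unname(d)
  fmt <- function(x) sprintf("%.10g", max(0, x))
  while (nrow(D) > 3) {
    r <- nrow(D)
    rs <- rowSums(D)
    Q <- (r - 2) * D - outer(rs, rs, `+`)
    diag(Q) <- Inf
    k <- which(Q == min(Q), arr.ind = TRUE)
    k <- k[order(k[, 1], k[, 2]), , drop = FALSE][1, ]
    i <- min(k); j <- max(k)
    li <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    new_sub <- sprintf("(%s:%s,%s:%s)", sub[i], fmt(li), sub[j], fmt(lj))
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    sub <- c(sub[keep], new_sub)
    D <- D2
  }
  # final three nodes joined at the unrooted trifurcation
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[1], fmt(l1), sub[2], fmt(l2),
                 sub[3], fmt(l3))
  ape::read.tree(text = nwk)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the full-data NJ tree from Poisson-corrected distances, then
#' resamples alignment columns with replacement `n_replicates` times
#' (each replicate's draw is keyed by `seed + replicate index`, so supports
#' do not depend on taxon input order), rebuilds NJ, and labels each internal
#' edge of the full-data tree with the percentage of replicates containing
#' the same bipartition.
#'
#' @param alignment Sequence table of aligned sequences.
#' @param n_replicates Bootstrap replicate count; 0 skips supports.
#' @param seed Integer seed.
#' @return An `ape::phylo` tree; `node.label` holds integer percentage
#'   supports when `n_replicates > 0`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000, seed = 1) {
  cols <- nchar(alignment$sequence[1])
  if (cols < 1) stop("alignment must have at least one column")
  tree <- neighbor_joining(alignment_distances(alignment))
  if (n_replicates == 0) return(tree)
  mat <- do.call(rbind, strsplit(alignment$sequence, ""))
  rownames(mat) <- alignment$id
  boot_trees <- vector("list", n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    set.seed(seed + rep_i)
    idx <- sample.int(cols, cols, replace = TRUE)
    res <- data.frame(id = alignment$id,
                      sequence = apply(mat[, idx, drop = FALSE], 1, paste,
                                       collapse = ""),
                      stringsAsFactors = FALSE)
    boot_trees[[rep_i]] <- neighbor_joining(alignment_distances(res))
  }
  ref_splits <- tree_bipartitions(tree)
  counts <- integer(length(ref_splits))
  for (bt in boot_trees) {
    bs <- tree_bipartitions(bt)
    counts <- counts + (ref_splits %in% bs)
  }
  # node labels: root node unlabeled, internal nodes get % support
  supp <- as.integer(round(100 * counts / n_replicates))
  tree$node.label <- rep("", tree$Nnode)
  names(supp) <- names(ref_splits)
  for (k in seq_along(supp))
    tree$node.label[as.integer(names(supp)[k]) - length(tree$tip.label)] <-
      as.character(supp[k])
  tree
}

# Canonical string per internal (non-root) node: the lexicographically sorted
# tip set of the smaller side of its bipartition (ties: the side containing
# the alphabetically first tip overall). Names are the internal node numbers.
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1
  internal <- setdiff(unique(tree$edge[, 1]), root)
  # also exclude internal nodes directly defining trivial splits
  all_tips <- sort(tree$tip.label)
  splits <- character(0)
  for (node in internal) {
    tips <- sort(tree$tip.label[descendant_tips(tree, node)])
    other <- setdiff(all_tips, tips)
    side <- if (length(tips) < length(other)) tips
            else if (length(other) < length(tips)) other
            else if (tips[1] < other[1]) tips else other
    if (length(side) < 2 || length(side) > ntip - 2) next  # trivial
    splits[as.character(node)] <- paste(side, collapse = "|")
  }
  splits
}

descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == x, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}

#' Partition a tree's taxa into k clades
#'
#' Operationalizes a visual clade partition: the `k - 1` longest internal
#' edges are cut (ties broken by the lexicographic bipartition string) and
#' the resulting connected leaf groups are labeled `1..k` by decreasing size
#' (ties by the alphabetically first member).
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param k Number of clades (>= 1; `k = n` gives singletons).
#' @return Named integer vector: taxon -> clade label.
#' @export
assign_clades <- function(tree, k) {
  ntip <- length(tree$tip.label)
  if (k < 1) stop("k must be >= 1")
  if (k > ntip) stop("k cannot exceed the number of taxa")
  edge_key <- vapply(seq_len(nrow(tree$edge)), function(e) {
    node <- tree$edge[e, 2]
    tips <- if (node <= ntip) tree$tip.label[node]
            else sort(tree$tip.label[descendant_tips(tree, node)])
    paste(tips, collapse = "|")
  }, character(1))
  internal <- tree$edge[, 2] > ntip
  # internal edges first (longest, ties lexicographic), then pendant edges
  # for the degenerate k close to n
  ord <- c(which(internal)[order(-tree$edge.length[internal],
                                 edge_key[internal])],
           which(!internal)[order(-tree$edge.length[!internal],
                                  edge_key[!internal])])
  leaf_comp <- function(cut) {
    parent <- seq_len(ntip + tree$Nnode)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (e in setdiff(seq_len(nrow(tree$edge)), cut)) {
      a <- find(tree$edge[e, 1]); b <- find(tree$edge[e, 2])
      if (a != b) parent[b] <- a
    }
    vapply(seq_len(ntip), find, integer(1))
  }
  # cut greedily, keeping only cuts that split a leaf group
  cut <- integer(0)
  n_groups <- 1L
  for (e in ord) {
    if (n_groups >= k) break
    trial <- c(cut, e)
    ng <- length(unique(leaf_comp(trial)))
    if (ng > n_groups) { cut <- trial; n_groups <- ng }
  }
  comp <- leaf_comp(cut)
  groups <- split(tree$tip.label[seq_len(ntip)], comp)
  first_member <- vapply(groups, function(g) sort(g)[1], character(1))
  ord <- order(-lengths(groups), first_member)
  out <- integer(ntip)
  names(out) <- tree$tip.label
  for (i in seq_along(ord)) out[groups[[ord[i]]]] <- i
  out
}
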