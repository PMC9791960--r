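# Family identification: local-alignment candidate search with a
# Karlin-Altschul E-value gate, Cys4-His-Cys3 motif confirmation, and
# sequential naming in chromosomal order.

#' Optimal local alignment score (Smith-Waterman, affine gaps)
#'
#' Exact local alignment via `Biostrings::pairwiseAlignment` with BLOSUM62 by
#' default and affine gap costs: a gap of length L costs
#' `gap_open + L * gap_extend`. The empty alignment is admissible, so scores
#' are floored at zero.
#'
#' @param query,target Amino-acid strings.
#' @param matrix Substitution matrix name (a matrix shipped with Biostrings)
#'   or a numeric matrix.
#' @param gap_open,gap_extend Gap opening/extension costs (positive).
#' @return The optimal local alignment score (numeric scalar).
#' @export
smith_waterman <- function(query, target, matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1) {
  if (!nzchar(query) || !nzchar(target)) stop("sequences must be non-empty")
  mat <- if (is.character(matrix)) {
    get(data(list = matrix, package = "Biostrings", envir = environment()))
  } else matrix
  bad <- setdiff(unique(strsplit(paste0(query, target), "")[[1]]),
                 rownames(mat))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
  score <- Biostrings::pairwiseAlignment(
    pattern = query, subject = target, type = "local",
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, scoreOnly = TRUE)
  max(0, score)
}

# Vectorized query-vs-database local alignment scores (one query, many
# subjects); used by identify_family for speed.
sw_scores_many <- function(query, targets, matrix, gap_open, gap_extend) {
  scores <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(rep(query, length(targets))),
    subject = Biostrings::AAStringSet(targets), type = "local",
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, scoreOnly = TRUE)
  pmax(0, scores)
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of alignments of
#' score `>= S` between a random query of length `m` and a database of total
#' length `n`.
#'
#' @param score Raw alignment score.
#' @param m Query length (residues).
#' @param n Database length (total residues searched).
#' @param K,lambda Karlin-Altschul parameters (ungapped BLOSUM62-style
#'   defaults K = 0.041, lambda = 0.267).
#' @return The E-value.
#' @export
estimate_evalue <- function(score, m, n, K = 0.041, lambda = 0.267) {
  if (m <= 0 || n <= 0) stop("lengths must be positive")
  K * m * n * exp(-lambda * score)
}

#' Scan a protein for the Cys4-His-Cys3 zinc-finger motif
#'
#' Finds non-overlapping matches of the spaced ligand pattern
#' C-x(..)-C-x(..)-C-x(..)-C-x(..)-H-x(..)-C-x(..)-C-x(..)-C whose total span
#' lies within `span_range` residues (50-80 by default, the canonical domain
#' size). Scanning is leftmost-shortest: at each candidate start the match
#' with the smallest end wins, and scanning resumes after its end.
#'
#' @param sequence Amino-acid string (a record's `sequence`).
#' @param spacer_ranges 7x2 min/max matrix of inter-ligand spacer lengths.
#' @param span_range Allowed total span (inclusive).
#' @return A data.frame with one row per hit: `start`, `end` (1-based
#'   inclusive) and `ligands` (list column of the eight ligand positions).
#'   ACGT-only input triggers a warning and an empty result.
#' @export
scan_phd_motif <- function(sequence, spacer_ranges = default_spacer_ranges(),
                           span_range = c(50, 80)) {
  sequence <- toupper(sequence)
  if (nzchar(sequence) && grepl("^[ACGT]+$", sequence)) {
    warning("sequence looks nucleotide (ACGT-only); no motif scan performed")
    return(data.frame(start = integer(0), end = integer(0),
                      ligands = I(list())))
  }
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  ligand_res <- c("C", "C", "C", "C", "H", "C", "C", "C")

  hits <- list()
  search_from <- 1
  while (search_from <= n - span_range[1] + 1) {
    starts <- which(chars == "C")
    starts <- starts[starts >= search_from]
    found <- FALSE
    for (s in starts) {
      best_end <- motif_min_end(chars, s, spacer_ranges, ligand_res,
                                span_range)
      if (!is.na(best_end)) {
        # recover one ligand assignment for the chosen (start, end)
        lig <- recover_ligands(chars, s, best_end, spacer_ranges, ligand_res)
        hits[[length(hits) + 1]] <- list(start = s, end = best_end,
                                         ligands = lig)
        search_from <- best_end + 1
        found <- TRUE
        break
      }
    }
    if (!found) break
  }
  if (!length(hits))
    return(data.frame(start = integer(0), end = integer(0),
                      ligands = I(list())))
  data.frame(start = vapply(hits, `[[`, integer(1), "start"),
             end = vapply(hits, `[[`, integer(1), "end"),
             ligands = I(lapply(hits, `[[`, "ligands")))
}

# Smallest valid match end for a motif starting at `start`, or NA. Depth-first
# search over ligand placements with pruning on the best end found so far and
# on the maximum admissible span.
motif_min_end <- function(chars, start, spacer_ranges, ligand_res,
                          span_range) {
  n <- length(chars)
  # minimal residues from ligand k (inclusive) to ligand 8 (inclusive)
  min_tail <- rev(cumsum(rev(c(spacer_ranges[, "min"] + 1, 1))))
  env <- new.env(parent = emptyenv())
  env$best <- NA_integer_
  hard_max <- start + span_range[2] - 1
  hard_min <- start + span_range[1] - 1
  place <- function(k, pos) {
    if (k == 8) {
      if (pos >= hard_min && (is.na(env$best) || pos < env$best))
        env$best <- pos
      return(invisible(NULL))
    }
    lo <- pos + spacer_ranges[k, "min"] + 1
    hi <- min(pos + spacer_ranges[k, "max"] + 1, n)
    if (lo > hi) return(invisible(NULL))
    for (p in lo:hi) {
      if (chars[p] != ligand_res[k + 1]) next
      end_lb <- p + min_tail[k + 1] - 1   # earliest possible end from here
      if (end_lb > hard_max) next
      if (!is.na(env$best) && end_lb >= env$best) next
      place(k + 1, p)
    }
    invisible(NULL)
  }
  place(1, start)
  env$best
}

# Backtrack one valid ligand assignment between fixed start and end.
recover_ligands <- function(chars, start, end, spacer_ranges, ligand_res) {
  path <- integer(8)
  path[1] <- start
  solve <- function(k, pos) {
    if (k == 8) return(pos == end)
    lo <- pos + spacer_ranges[k, "min"] + 1
    hi <- min(pos + spacer_ranges[k, "max"] + 1, end)
    if (lo > hi) return(FALSE)
    for (p in lo:hi) {
      if (chars[p] != ligand_res[k + 1]) next
      path[k + 1] <<- p
      if (solve(k + 1, p)) return(TRUE)
    }
    FALSE
  }
  if (!solve(1, start)) stop("internal error: ligand backtrack failed")
  path
}

#' Assign sequential family names in chromosomal order
#'
#' Sort key: chromosome number, then subgenome letter (A < B < D), then start
#' position, ties broken by gene id. Unplaced genes (chromosome `U`) come
#' last, ordered by id. Names are `prefix` followed by 1..N.
#'
#' @param features Gene table (as from [read_gff3()]) of the accepted genes.
#' @param prefix Name prefix (e.g. `"TaPHD"`).
#' @return `features` reordered, with a `name` column prepended.
#' @export
assign_names <- function(features, prefix = "FAM") {
  placed <- features$chrom != "U" & !is.na(features$chrom_number)
  f1 <- features[placed, , drop = FALSE]
  f1 <- f1[order(f1$chrom_number, f1$subgenome, f1$start, f1$gene_id), ,
           drop = FALSE]
  f2 <- features[!placed, , drop = FALSE]
  f2 <- f2[order(f2$gene_id), , drop = FALSE]
  out <- rbind(f1, f2)
  out <- cbind(name = paste0(prefix, seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Identify family members in a proteome
#'
#' Two-stage rule mirroring a BLASTP-plus-domain-confirmation screen: a
#' protein is accepted iff (1) its best local-alignment E-value against any
#' query falls below `evalue_threshold`, and (2) the motif scan confirms at
#' least one Cys4-His-Cys3 domain. Accepted genes are named sequentially in
#' chromosomal order. Proteins that pass both stages but have no coordinates
#' are reported in the `unplaced` attribute rather than silently dropped.
#'
#' @param proteome Sequence table (as from [read_fasta()]).
#' @param queries Sequence table of query proteins (known family members).
#' @param gff Gene table (as from [read_gff3()]).
#' @param evalue_threshold E-value gate (default 1e-5).
#' @param prefix Name prefix for [assign_names()].
#' @param spacer_ranges Motif spacer configuration.
#' @param matrix,gap_open,gap_extend Alignment scoring parameters.
#' @return A `gene_catalog` data.frame: `name`, `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `chrom_number`, `subgenome`, `n_domains`,
#'   `domain_spans`, `best_evalue`, plus a `domains` list column of motif
#'   hits. Attribute `unplaced` lists accepted ids without coordinates.
#' @export
identify_family <- function(proteome, queries, gff, evalue_threshold = 1e-5,
                            prefix = "FAM",
                            spacer_ranges = default_spacer_ranges(),
                            matrix = "BLOSUM62", gap_open = 11,
                            gap_extend = 1) {
  # stable results regardless of input row order
  proteome <- proteome[order(proteome$id), , drop = FALSE]
  if (nrow(proteome) == 0 || nrow(queries) == 0) {
    out <- empty_catalog()
    attr(out, "unplaced") <- character(0)
    return(out)
  }
  mat <- if (is.character(matrix)) {
    get(data(list = matrix, package = "Biostrings", envir = environment()))
  } else matrix
  db_len <- sum(nchar(proteome$sequence))
  best_e <- rep(Inf, nrow(proteome))
  for (q in seq_len(nrow(queries))) {
    sc <- sw_scores_many(queries$sequence[q], proteome$sequence, mat,
                         gap_open, gap_extend)
    e <- estimate_evalue(sc, m = nchar(queries$sequence[q]), n = db_len)
    best_e <- pmin(best_e, e)
  }
  candidate <- best_e < evalue_threshold
  domains <- lapply(seq_len(nrow(proteome)), function(i) {
    if (!candidate[i]) return(NULL)
    scan_phd_motif(proteome$sequence[i], spacer_ranges)
  })
  confirmed <- candidate & vapply(domains, function(d)
    !is.null(d) && nrow(d) > 0, logical(1))
  acc_ids <- proteome$id[confirmed]
  feat <- gff[match(acc_ids, gff$gene_id), , drop = FALSE]
  unplaced <- acc_ids[is.na(feat$gene_id)]
  placed_ids <- acc_ids[!is.na(feat$gene_id)]
  feat <- feat[!is.na(feat$gene_id), , drop = FALSE]
  if (nrow(feat) == 0) {
    out <- empty_catalog()
    attr(out, "unplaced") <- unplaced
    return(out)
  }
  named <- assign_names(feat, prefix)
  idx <- match(named$gene_id, proteome$id)
  dom <- domains[idx]
  named$n_domains <- vapply(dom, nrow, integer(1))
  named$domain_spans <- vapply(dom, function(d)
    paste(sprintf("%d-%d", d$start, d$end), collapse = ","), character(1))
  named$best_evalue <- best_e[idx]
  named$domains <- I(dom)
  class(named) <- c("gene_catalog", class(named))
  attr(named, "unplaced") <- unplaced
  named
}

empty_catalog <- function() {
  out <- data.frame(name = character(0), gene_id = character(0),
                    chrom = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    chrom_number = integer(0), subgenome = character(0),
                    n_domains = integer(0), domain_spans = character(0),
                    best_evalue = numeric(0), stringsAsFactors = FALSE)
  out$domains <- I(list())
  class(out) <- c("gene_catalog", class(out))
  out
}

#' Keep one representative isoform per gene
#'
#' When several proteins share a gene parent, the lexicographically first
#' transcript id is retained (a reproducible stand-in for "first splice
#' variant").
#'
#' @param proteome Sequence table.
#' @param transcript_to_gene Named character vector mapping transcript ids to
#'   gene ids; ids absent from the map are treated as their own gene.
#' @return The filtered sequence table with ids replaced by gene ids.
#' @export
select_representative_isoforms <- function(proteome, transcript_to_gene) {
  gene <- transcript_to_gene[proteome$id]
  gene[is.na(gene)] <- proteome$id[is.na(gene)]
  ord <- order(gene, proteome$id)
  proteome <- proteome[ord, , drop = FALSE]
  gene <- gene[ord]
  keep <- !duplicated(gene)
  out <- proteome[keep, , drop = FALSE]
  out$id <- unname(gene[keep])
  rownames(out) <- NULL
  out
}
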