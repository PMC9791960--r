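# Synthetic-data generators: a three-subgenome genome with a planted
# Cys4-His-Cys3 family, codon pairs diverged under a known dN/dS, TPM
# matrices with planted differential expression, and qPCR Ct tables with
# planted fold changes. Every generator is deterministic for a fixed seed
# and returns its ground truth alongside the data.

# Default spacer ranges of the planted (and scanned) zinc-ligand motif:
# C-x(1,3)-C-x(8,21)-C-x(2,4)-C-x(4,6)-H-x(1,2)-C-x(10,46)-C-x(2,3)-C.
#' @export
default_spacer_ranges <- function() {
  matrix(c(1, 3, 8, 21, 2, 4, 4, 6, 1, 2, 10, 46, 2, 3),
         ncol = 2, byrow = TRUE,
         dimnames = list(paste0("gap", 1:7), c("min", "max")))
}

#' Configuration for the synthetic family genome
#'
#' The default ratio mixture mirrors the homoeolog-retention profile reported
#' for the wheat PHD-finger family (85% complete triads, rare subgenome
#' duplications, moderate single-homoeolog loss, few orphans).
#'
#' @param seed Integer seed; all genome randomness flows from it.
#' @param n_groups Number of homoeologous groups to plant.
#' @param ratio_mixture Named proportions over the categories
#'   `1:1:1`, `n:1:1`, `1:1:0`, `other`, `orphan`; must sum to 1.
#' @param subgenomes Ordered subgenome labels.
#' @param chromosomes_per_subgenome Chromosome count per subgenome.
#' @param n_background_genes Non-family genes per chromosome.
#' @param motif_spacer_ranges 7x2 matrix of min/max spacer lengths between the
#'   eight zinc ligands.
#' @param protein_length_range Min/max protein length in residues.
#' @param mutation_rate Per-residue substitution rate between members of one
#'   homoeologous group (sequence divergence among homoeologs).
#' @param group_divergence Per-residue substitution rate between each group's
#'   template and the family ancestor (divergence among paralogous groups).
#' @return A validated config list of class `family_sim_config`.
#' @export
family_sim_config <- function(seed = 1,
                              n_groups = 20,
                              ratio_mixture = c("1:1:1" = 0.85, "n:1:1" = 0.02,
                                                "1:1:0" = 0.07, "other" = 0.04,
                                                "orphan" = 0.02),
                              subgenomes = c("A", "B", "D"),
                              chromosomes_per_subgenome = 7,
                              n_background_genes = 8,
                              motif_spacer_ranges = default_spacer_ranges(),
                              protein_length_range = c(220, 420),
                              mutation_rate = 0.01,
                              group_divergence = 0.2) {
  if (abs(sum(ratio_mixture) - 1) > 1e-9)
    stop("ratio_mixture proportions must sum to 1")
  if (n_groups < 0 || chromosomes_per_subgenome < 1 || n_background_genes < 0)
    stop("counts must be non-negative (and at least one chromosome)")
  if (any(motif_spacer_ranges[, "min"] > motif_spacer_ranges[, "max"]))
    stop("motif spacer ranges must satisfy min <= max")
  if (protein_length_range[1] > protein_length_range[2])
    stop("protein_length_range must satisfy min <= max")
  structure(list(seed = seed, n_groups = n_groups,
                 ratio_mixture = ratio_mixture, subgenomes = subgenomes,
                 chromosomes_per_subgenome = chromosomes_per_subgenome,
                 n_background_genes = n_background_genes,
                 motif_spacer_ranges = motif_spacer_ranges,
                 protein_length_range = protein_length_range,
                 mutation_rate = mutation_rate,
                 group_divergence = group_divergence),
            class = "family_sim_config")
}

# Residue alphabets: spacers and flanks avoid C and H so the only
# Cys4-His-Cys3 match in a family protein is the planted one, and background
# proteins (drawn from the same alphabet) are motif-free by construction.
.AA_NONCH <- setdiff(AA20, c("C", "H"))

sample_motif <- function(spacer_ranges, span_range = c(50, 80)) {
  repeat {
    gaps <- unname(mapply(function(a, b) sample(seq(a, b), 1),
                          spacer_ranges[, "min"], spacer_ranges[, "max"]))
    span <- 8 + sum(gaps)
    if (span >= span_range[1] && span <= span_range[2]) break
  }
  ligands <- c("C", "C", "C", "C", "H", "C", "C", "C")
  parts <- character(0)
  lig_pos <- 1L
  for (i in 1:7) {
    parts <- c(parts, ligands[i],
               paste(sample(.AA_NONCH, gaps[i], replace = TRUE), collapse = ""))
    lig_pos <- c(lig_pos, lig_pos[length(lig_pos)] + 1L + gaps[i])
  }
  list(seq = paste0(paste(parts, collapse = ""), ligands[8]),
       ligand_offsets = lig_pos)
}

random_protein <- function(len) {
  paste(sample(.AA_NONCH, len, replace = TRUE), collapse = "")
}

# Mutate a protein at `rate` per residue, avoiding the ligand positions of the
# planted motif (given as a 1-based span) and never introducing C or H.
mutate_protein <- function(seq, rate, protect = integer(0)) {
  chars <- strsplit(seq, "")[[1]]
  k <- stats::rbinom(1, length(chars), rate)
  if (k == 0) return(seq)
  cand <- setdiff(seq_along(chars), protect)
  pos <- sample(cand, min(k, length(cand)))
  chars[pos] <- sample(.AA_NONCH, length(pos), replace = TRUE)
  paste(chars, collapse = "")
}

# Reverse-translate a protein to a CDS with uniformly sampled synonymous
# codons, appending a stop codon.
reverse_translate <- function(protein) {
  tab <- codon_tables()
  by_aa <- split(CODONS, tab$aa)
  chars <- strsplit(protein, "")[[1]]
  codons <- vapply(chars, function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1))
  paste0(paste(codons, collapse = ""), sample(by_aa[["*"]], 1))
}

# Derive a member CDS from its group's template CDS: codons of unchanged
# residues are inherited (with a small synonymous swap rate, giving the
# within-group Ks signal), codons of mutated residues are resampled for the
# new residue (the Ka signal). The template's stop codon is kept.
derive_member_cds <- function(template_cds, template_protein, member_protein,
                              syn_rate = 0.03) {
  tab <- codon_tables()
  by_aa <- split(CODONS, tab$aa)
  cods <- split_codons(template_cds)
  tp <- strsplit(template_protein, "")[[1]]
  mp <- strsplit(member_protein, "")[[1]]
  stopifnot(length(cods) == length(tp) + 1)
  for (i in seq_along(mp)) {
    if (mp[i] != tp[i]) {
      opts <- by_aa[[mp[i]]]
      cods[i] <- opts[sample.int(length(opts), 1)]
    } else if (stats::runif(1) < syn_rate) {
      opts <- by_aa[[tp[i]]]
      cods[i] <- opts[sample.int(length(opts), 1)]
    }
  }
  paste(cods, collapse = "")
}

#' Generate a synthetic three-subgenome genome with a planted gene family
#'
#' Plants `n_groups` homoeologous groups whose A:B:D composition follows the
#' configured ratio mixture. All members of a group sit on the same chromosome
#' number of different subgenomes, in a group order that is conserved across
#' subgenomes (so homoeologous chromosomes are collinear). Extra copies of a
#' duplicated homoeolog are placed adjacently (tandem). Family proteins carry
#' one planted Cys4-His-Cys3 motif; background proteins are motif-free.
#'
#' @param config A [family_sim_config()].
#' @return A list with `proteins` and `cds` (sequence tables as from
#'   [read_fasta()]), `features` (gene table as from [read_gff3()]), and
#'   `truth` (family ids, group assignments, per-group ratio category and
#'   planted counts, background ids).
#' @export
generate_family_genome <- function(config) {
  stopifnot(inherits(config, "family_sim_config"))
  set.seed(config$seed)
  sg <- config$subgenomes
  n_sg <- length(sg)
  categories <- names(config$ratio_mixture)
  # deterministic multinomial draw of per-group categories
  cat_of_group <- if (config$n_groups > 0)
    sample(categories, config$n_groups, replace = TRUE,
           prob = config$ratio_mixture) else character(0)

  # per-group member counts across subgenomes
  counts_for <- function(category) {
    n <- rep(1L, n_sg)
    if (category == "1:1:1") return(n)
    if (category == "n:1:1") { n[sample.int(n_sg, 1)] <- 2L; return(n) }
    if (category == "1:1:0") { n[sample.int(n_sg, 1)] <- 0L; return(n) }
    if (category == "orphan") { n <- rep(0L, n_sg); n[sample.int(n_sg, 1)] <- 1L; return(n) }
    # "other": one subgenome lost, another duplicated (e.g. 0:1:2)
    lost <- sample.int(n_sg, 1)
    dup <- sample(setdiff(seq_len(n_sg), lost), 1)
    n[lost] <- 0L; n[dup] <- 2L
    n
  }

  group_ids <- sprintf("G%03d", seq_len(config$n_groups))
  group_chrom <- if (config$n_groups > 0)
    sample.int(config$chromosomes_per_subgenome, config$n_groups,
               replace = TRUE) else integer(0)
  group_counts <- lapply(cat_of_group, counts_for)

  # one family ancestor with a planted motif; group templates diverge from it
  # (so every family member stays detectably homologous to any query), and
  # members diverge a little more within their group
  fam_len <- round(mean(config$protein_length_range))
  motif <- sample_motif(config$motif_spacer_ranges)
  flank_len <- max(fam_len - nchar(motif$seq), 40)
  offset <- sample.int(flank_len - 20, 1) + 10   # motif not at the very ends
  ancestor <- paste0(random_protein(offset), motif$seq,
                     random_protein(flank_len - offset))
  motif_start <- offset + 1L
  motif_end <- offset + nchar(motif$seq)
  ligand_pos <- offset + motif$ligand_offsets   # protected zinc ligands
  templates <- vector("list", config$n_groups)
  for (g in seq_len(config$n_groups)) {
    templates[[g]] <- list(
      seq = mutate_protein(ancestor, config$group_divergence, ligand_pos),
      motif_start = motif_start, motif_end = motif_end)
  }

  prot <- character(0); cds <- character(0); ids <- character(0)
  chrom_of <- character(0); grp_of <- character(0); slot_of <- integer(0)
  copy_of <- integer(0)
  for (g in seq_len(config$n_groups)) {
    tpl <- templates[[g]]
    tpl_cds <- reverse_translate(tpl$seq)
    protect <- ligand_pos
    for (s in seq_len(n_sg)) {
      for (copy in seq_len(group_counts[[g]][s])) {
        gid <- sprintf("SYN%s%02dG%03d%s", sg[s], group_chrom[g], g,
                       if (copy > 1) letters[copy] else "")
        p <- mutate_protein(tpl$seq, config$mutation_rate, protect)
        ids <- c(ids, gid); prot <- c(prot, p)
        cds <- c(cds, derive_member_cds(tpl_cds, tpl$seq, p))
        chrom_of <- c(chrom_of, paste0(group_chrom[g], sg[s]))
        grp_of <- c(grp_of, group_ids[g])
        slot_of <- c(slot_of, g)
        copy_of <- c(copy_of, copy)
      }
    }
  }
  family_ids <- ids

  # background genes per chromosome (motif-free)
  bg_ids <- character(0)
  for (s in seq_len(n_sg)) {
    for (ch in seq_len(config$chromosomes_per_subgenome)) {
      for (b in seq_len(config$n_background_genes)) {
        gid <- sprintf("SYN%s%02dB%03d", sg[s], ch, b)
        p <- random_protein(sample(seq(config$protein_length_range[1],
                                       config$protein_length_range[2]), 1))
        ids <- c(ids, gid); prot <- c(prot, p)
        cds <- c(cds, reverse_translate(p))
        chrom_of <- c(chrom_of, paste0(ch, sg[s]))
        grp_of <- c(grp_of, NA_character_)
        slot_of <- c(slot_of, NA_integer_)
        copy_of <- c(copy_of, NA_integer_)
        bg_ids <- c(bg_ids, gid)
      }
    }
  }

  # lay out coordinates: family genes ordered by group slot (conserved across
  # subgenomes, extra copies adjacent), background interleaved after each slot
  feats <- data.frame(gene_id = ids, chrom = chrom_of, stringsAsFactors = FALSE)
  feats$slot <- slot_of
  feats$copy <- copy_of
  start <- integer(length(ids)); end <- integer(length(ids))
  for (ch in unique(chrom_of)) {
    idx <- which(chrom_of == ch)
    fam <- idx[!is.na(slot_of[idx])]
    fam <- fam[order(slot_of[fam], copy_of[fam])]
    bg <- idx[is.na(slot_of[idx])]
    ordered <- integer(0)
    n_slots <- length(fam) + 1
    bg_split <- if (length(bg))
      split(bg, ceiling(seq_along(bg) * n_slots / length(bg))) else list()
    for (i in seq_len(n_slots)) {
      if (i <= length(fam)) ordered <- c(ordered, fam[i])
      if (i <= length(bg_split)) ordered <- c(ordered, bg_split[[i]])
    }
    pos <- 1000L
    for (j in ordered) {
      glen <- nchar(cds[j]) + 200L
      start[j] <- pos
      end[j] <- pos + glen - 1L
      pos <- pos + glen + sample(500:2000, 1)
    }
  }
  pc <- parse_chromosome(chrom_of)
  features <- data.frame(gene_id = ids, chrom = chrom_of, start = start,
                         end = end, strand = sample(c("+", "-"), length(ids),
                                                    replace = TRUE),
                         chrom_number = pc$number, subgenome = pc$subgenome,
                         stringsAsFactors = FALSE)
  features <- features[order(features$chrom, features$start), , drop = FALSE]
  rownames(features) <- NULL

  truth <- list(
    family_gene_ids = family_ids,
    background_gene_ids = bg_ids,
    group_assignments = stats::setNames(grp_of[seq_along(family_ids)],
                                        family_ids),
    group_ratio_category = stats::setNames(cat_of_group, group_ids),
    group_counts = stats::setNames(group_counts, group_ids)
  )
  # planted motif span per family gene (same span as its group template)
  truth$motif_spans <- stats::setNames(
    lapply(seq_along(family_ids), function(i) {
      g <- match(truth$group_assignments[[i]], group_ids)
      c(start = templates[[g]]$motif_start, end = templates[[g]]$motif_end)
    }), family_ids)

  list(proteins = data.frame(id = ids, description = "", sequence = prot,
                             stringsAsFactors = FALSE),
       cds = data.frame(id = ids, description = "", sequence = cds,
                        stringsAsFactors = FALSE),
       features = features,
       truth = truth)
}

#' Evolve a codon-sequence pair under a known dN/dS
#'
#' An ancestral gap- and stop-free codon sequence is drawn uniformly over the
#' 61 sense codons and evolved independently down two branches of length
#' `branch_length / 2` each. Mutations arise uniformly per nucleotide site
#' (branch length is measured in expected mutation attempts per site);
#' synonymous changes are accepted with relative probability
#' `min(1, 1/omega)` and nonsynonymous with `min(1, omega)`, so the
#' nonsynonymous:synonymous acceptance odds are `omega`. Changes creating a
#' stop codon are rejected.
#'
#' @param seed Integer seed.
#' @param n_codons Number of codons (>= 30).
#' @param branch_length Total expected mutation attempts per nucleotide site
#'   separating the two sequences (>= 0).
#' @param omega Target dN/dS (>= 0).
#' @return List with `seq_a`, `seq_b` (nucleotide strings) and `truth`
#'   (planted omega and branch length).
#' @export
evolve_codon_pair <- function(seed, n_codons, branch_length, omega) {
  if (omega < 0) stop("omega must be >= 0")
  if (branch_length < 0) stop("branch_length must be >= 0")
  if (n_codons < 30) stop("n_codons must be >= 30")
  set.seed(seed)
  tab <- codon_tables()
  sense <- which(!tab$is_stop)
  anc <- sample(sense, n_codons, replace = TRUE)
  p_syn <- min(1, if (omega > 0) 1 / omega else 1)
  p_non <- min(1, omega)
  evolve <- function(codons, t) {
    n_events <- stats::rpois(1, t * 3 * length(codons))
    if (n_events == 0) return(codons)
    pos <- sample.int(length(codons), n_events, replace = TRUE)
    slot <- sample.int(9, n_events, replace = TRUE)
    u <- stats::runif(n_events)
    for (k in seq_len(n_events)) {
      i <- codons[pos[k]]
      j <- tab$nbr[i, slot[k]]
      if (tab$nbr_stop[i, slot[k]]) next
      acc <- if (tab$nbr_syn[i, slot[k]]) p_syn else p_non
      if (u[k] < acc) codons[pos[k]] <- j
    }
    codons
  }
  a <- evolve(anc, branch_length / 2)
  b <- evolve(anc, branch_length / 2)
  list(seq_a = paste(CODONS[a], collapse = ""),
       seq_b = paste(CODONS[b], collapse = ""),
       truth = list(omega = omega, branch_length = branch_length))
}

#' Generate a TPM expression matrix with planted differential expression
#'
#' Baseline per-gene expression is lognormal (meanlog 3, sdlog 1.5) on the TPM
#' scale, spanning the none/low/medium/high binning thresholds. In each
#' non-control condition a fraction `de_fraction` of genes is shifted by
#' `±lfc_magnitude` on the log2 scale; replicate noise is lognormal with
#' sdlog `dispersion`.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes.
#' @param conditions Character vector of condition names; the first is the
#'   control.
#' @param replicates Replicates per condition (>= 2).
#' @param de_fraction Fraction of genes differentially expressed per treated
#'   condition, in `[0, 1]`.
#' @param lfc_magnitude Absolute planted log2 fold change.
#' @param dispersion Replicate noise (sdlog of the lognormal).
#' @param zero_samples Sample names forced to all-zero TPM (optional).
#' @return List with `tpm` (genes x samples matrix), `samples` (metadata with
#'   `sample`, `condition`, `replicate`) and `truth` (per-condition DE gene
#'   ids and planted log2 fold changes).
#' @export
generate_expression_matrix <- function(seed, n_genes = 200,
                                       conditions = c("control", "treated"),
                                       replicates = 3, de_fraction = 0.1,
                                       lfc_magnitude = 2, dispersion = 0.2,
                                       zero_samples = character(0)) {
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must be in [0, 1]")
  if (replicates < 2) stop("at least 2 replicates per condition are required")
  set.seed(seed)
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  samples <- data.frame(
    sample = paste(rep(conditions, each = replicates),
                   rep(seq_len(replicates), length(conditions)), sep = "_r"),
    condition = rep(conditions, each = replicates),
    replicate = rep(seq_len(replicates), length(conditions)),
    stringsAsFactors = FALSE)
  baseline <- stats::rlnorm(n_genes, meanlog = 3, sdlog = 1.5)
  lfc <- matrix(0, n_genes, length(conditions),
                dimnames = list(genes, conditions))
  de <- stats::setNames(vector("list", length(conditions)), conditions)
  for (cond in conditions[-1]) {
    n_de <- round(de_fraction * n_genes)
    pick <- if (n_de > 0) sample(genes, n_de) else character(0)
    de[[cond]] <- pick
    lfc[pick, cond] <- sample(c(-1, 1), length(pick), replace = TRUE) *
      lfc_magnitude
  }
  de[[conditions[1]]] <- character(0)
  tpm <- matrix(0, n_genes, nrow(samples),
                dimnames = list(genes, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- baseline * 2^lfc[, samples$condition[j]]
    tpm[, j] <- mu * stats::rlnorm(n_genes, 0, dispersion)
  }
  tpm[, colnames(tpm) %in% zero_samples] <- 0
  list(tpm = tpm, samples = samples,
       truth = list(de_gene_ids = de, planted_log2fc = lfc,
                    baseline = stats::setNames(baseline, genes)))
}

#' Generate a qPCR Ct table with planted fold changes
#'
#' Emits a long Ct table with triplicate technical structure and a reference
#' gene present in every (treatment, timepoint, replicate) cell. Target Ct
#' values equal a per-gene baseline minus log2 of the planted expression fold
#' (relative to the control treatment), plus Gaussian noise.
#'
#' @param seed Integer seed.
#' @param genes Target gene names.
#' @param treatments Treatment names; the first is the control.
#' @param timepoints Timepoint labels.
#' @param planted_fold_changes Named list `gene -> treatment -> numeric vector
#'   over timepoints` of expression folds relative to control (default 1).
#' @param ct_noise_sd Gaussian noise SD on Ct values.
#' @param reference_gene Reference gene name (always included).
#' @param replicates Replicates per cell (default 3).
#' @return List with `ct` (long data frame: gene, treatment, timepoint,
#'   replicate, ct) and `truth` (the planted fold array).
#' @export
generate_qpcr_table <- function(seed, genes, treatments, timepoints,
                                planted_fold_changes = list(),
                                ct_noise_sd = 0.2,
                                reference_gene = "beta_actin",
                                replicates = 3) {
  if (!nzchar(reference_gene)) stop("a reference gene is required")
  set.seed(seed)
  fold <- array(1, dim = c(length(genes), length(treatments),
                           length(timepoints)),
                dimnames = list(genes, treatments, timepoints))
  for (g in names(planted_fold_changes))
    for (tr in names(planted_fold_changes[[g]]))
      fold[g, tr, ] <- planted_fold_changes[[g]][[tr]]
  baseline <- stats::setNames(stats::runif(length(genes), 22, 28), genes)
  ref_ct <- 18
  rows <- expand.grid(gene = c(reference_gene, genes), treatment = treatments,
                      timepoint = timepoints, replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  ct <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    g <- rows$gene[i]
    ct[i] <- if (g == reference_gene) ref_ct else
      baseline[[g]] - log2(fold[g, rows$treatment[i], rows$timepoint[i]])
  }
  rows$ct <- ct + stats::rnorm(nrow(rows), 0, ct_noise_sd)
  list(ct = rows, truth = list(planted_fold = fold,
                               reference_gene = reference_gene,
                               control = treatments[1]))
}
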