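# Expression analysis: log2 TPM transforms, expression binning and census,
# DEG calling (Welch t-test + Benjamini-Hochberg under a fold-change rule),
# DEG-set intersections, heatmap clustering order, and 2^(-ddCt) qPCR
# analysis with one-way ANOVA.

#' log2-transform a TPM matrix
#'
#' @param tpm Non-negative numeric matrix (genes x samples).
#' @param pseudocount Added before the log (default 1).
#' @return `log2(tpm + pseudocount)`.
#' @export
log2_tpm <- function(tpm, pseudocount = 1) {
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  log2(tpm + pseudocount)
}

#' Bin a TPM value into an expression level
#'
#' Boundary semantics as conventionally printed: high for TPM > 10, medium
#' for 1 < TPM <= 10, low for 0 < TPM <= 1, none for TPM = 0.
#'
#' @param tpm Non-negative numeric vector.
#' @return Character vector over `"high"`, `"medium"`, `"low"`, `"none"`.
#' @export
bin_expression <- function(tpm) {
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  ifelse(tpm > 10, "high",
         ifelse(tpm > 1, "medium",
                ifelse(tpm > 0, "low", "none")))
}

#' Per-sample census of expression bins
#'
#' @param tpm Non-negative matrix (genes x samples).
#' @return Integer matrix, bins x samples; columns sum to the gene count.
#' @export
census_bins <- function(tpm) {
  bins <- c("high", "medium", "low", "none")
  out <- vapply(seq_len(ncol(tpm)), function(j) {
    b <- bin_expression(tpm[, j])
    vapply(bins, function(x) sum(b == x), integer(1))
  }, integer(4))
  dimnames(out) <- list(bins, colnames(tpm))
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (via `stats::p.adjust`).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, monotone in `p` and at most 1.
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes between two sample groups
#'
#' Per gene: log2 fold change = difference of group means of
#' `log2(TPM + pseudocount)`; p-value from a two-sided Welch t-test on the
#' same scale; FDR by Benjamini-Hochberg across genes. A gene is a DEG iff
#' `|log2fc| > fc_threshold` and `fdr < fdr_threshold`.
#'
#' @param tpm Matrix (genes x samples).
#' @param control_samples,treated_samples Column names of the two groups
#'   (>= 2 each).
#' @param fc_threshold log2 fold-change threshold (default 1, i.e. two-fold).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @param pseudocount Pseudocount for the log transform.
#' @return Data frame: `gene`, `log2fc`, `p_value`, `fdr`, `is_deg`.
#' @export
call_degs <- function(tpm, control_samples, treated_samples,
                      fc_threshold = 1, fdr_threshold = 0.05,
                      pseudocount = 1) {
  if (length(control_samples) < 2 || length(treated_samples) < 2)
    stop("at least 2 replicates per group are required")
  missing <- setdiff(c(control_samples, treated_samples), colnames(tpm))
  if (length(missing)) stop("samples not in matrix: ",
                            paste(missing, collapse = ", "))
  lg <- log2_tpm(tpm, pseudocount)
  x <- lg[, treated_samples, drop = FALSE]
  y <- lg[, control_samples, drop = FALSE]
  log2fc <- rowMeans(x) - rowMeans(y)
  p <- vapply(seq_len(nrow(lg)), function(i) {
    xi <- x[i, ]; yi <- y[i, ]
    if (stats::sd(xi) == 0 && stats::sd(yi) == 0)
      return(if (mean(xi) == mean(yi)) 1 else 0)
    stats::t.test(xi, yi)$p.value
  }, numeric(1))
  fdr <- benjamini_hochberg(p)
  data.frame(gene = rownames(tpm), log2fc = log2fc, p_value = p, fdr = fdr,
             is_deg = abs(log2fc) > fc_threshold & fdr < fdr_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Exclusive region counts for up to six named sets
#'
#' Venn-style decomposition: every non-empty combination of set memberships
#' becomes a region; counts are exclusive and sum to the union size.
#'
#' @param sets Named list of character vectors (at most 6 sets).
#' @return Data frame: `region` (set names joined by `&`), `count`.
#' @export
intersect_deg_sets <- function(sets) {
  k <- length(sets)
  if (k < 1 || k > 6) stop("between 1 and 6 sets are supported")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "&"))
  combos <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(names(sets), m, paste, collapse = "&", simplify = TRUE)
  }))
  data.frame(region = combos,
             count = vapply(combos, function(cc) sum(pattern == cc),
                            integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gene ordering for an expression heatmap
#'
#' Average-linkage hierarchical clustering on `1 - Pearson correlation` of
#' the `log2(TPM + pseudocount)` rows. Genes are pre-sorted by id so the
#' leaf order is a deterministic function of the data. Zero-variance rows
#' get zero correlation with everything.
#'
#' @param tpm Matrix (>= 2 genes).
#' @param pseudocount Pseudocount for the log transform.
#' @return Character vector of gene ids in display order.
#' @export
cluster_order <- function(tpm, pseudocount = 1) {
  if (nrow(tpm) < 2) stop("clustering needs at least 2 genes")
  tpm <- tpm[order(rownames(tpm)), , drop = FALSE]
  lg <- log2_tpm(tpm, pseudocount)
  cc <- suppressWarnings(stats::cor(t(lg)))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  rownames(tpm)[hc$order]
}

#' Relative expression by the 2^(-ddCt) method
#'
#' Per replicate, `dCt = Ct_target - Ct_reference`; `ddCt` is the mean dCt
#' of the treated cell minus the mean dCt of the control treatment at the
#' same timepoint; relative expression is `2^(-ddCt)`. Significance is a
#' one-way ANOVA on the replicate dCt values of the control vs treated
#' groups (stars: `*` p < 0.05, `**` p < 0.01).
#'
#' @param ct Long Ct table: `gene`, `treatment`, `timepoint`, `replicate`,
#'   `ct`.
#' @param gene Target gene.
#' @param treatment Treatment to contrast against the control.
#' @param timepoint Timepoint label.
#' @param reference_gene Reference gene (present in every cell).
#' @param control Control treatment label.
#' @return One-row data.frame: `gene`, `treatment`, `timepoint`,
#'   `delta_delta_ct`, `fold_change`, `anova_p`, `stars`.
#' @export
ddct_fold_change <- function(ct, gene, treatment, timepoint,
                             reference_gene = "beta_actin",
                             control = NULL) {
  if (is.null(control)) control <- ct$treatment[1]
  cell <- function(g, tr) {
    rows <- ct[ct$gene == g & ct$treatment == tr &
                 ct$timepoint == timepoint, , drop = FALSE]
    rows[order(rows$replicate), , drop = FALSE]
  }
  ref_t <- cell(reference_gene, treatment)
  ref_c <- cell(reference_gene, control)
  tgt_t <- cell(gene, treatment)
  tgt_c <- cell(gene, control)
  if (!nrow(ref_t) || !nrow(ref_c))
    stop("reference gene '", reference_gene, "' missing for this cell")
  if (!nrow(tgt_t) || !nrow(tgt_c)) stop("target gene missing for this cell")
  if (nrow(tgt_t) != nrow(ref_t) || nrow(tgt_c) != nrow(ref_c))
    stop("replicate structure of target and reference differ")
  dct_t <- tgt_t$ct - ref_t$ct
  dct_c <- tgt_c$ct - ref_c$ct
  ddct <- mean(dct_t) - mean(dct_c)
  an <- tryCatch(one_way_anova(list(control = dct_c, treated = dct_t)),
                 error = function(e) list(F = NA_real_, p = NA_real_))
  stars <- if (!is.na(an$p) && an$p < 0.01) "**"
           else if (!is.na(an$p) && an$p < 0.05) "*" else ""
  data.frame(gene = gene, treatment = treatment, timepoint = timepoint,
             delta_delta_ct = ddct, fold_change = 2^(-ddct),
             anova_p = an$p, stars = stars, stringsAsFactors = FALSE)
}

#' Classical one-way ANOVA
#'
#' Equal-variance between/within mean-square F test (via
#' `stats::oneway.test(var.equal = TRUE)`).
#'
#' @param groups Named list of numeric vectors (>= 2 groups, >= 2 values
#'   each).
#' @return List with `F` and `p`. Zero within-group variance with equal
#'   means yields an error (F undefined).
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2))
    stop("one-way ANOVA needs >= 2 groups with >= 2 values each")
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), lengths(groups)))
  within_var <- vapply(groups, stats::var, numeric(1))
  if (all(within_var == 0) && length(unique(vapply(groups, mean,
                                                   numeric(1)))) == 1)
    stop("F undefined: zero within-group variance and equal means")
  res <- stats::oneway.test(values ~ fac, var.equal = TRUE)
  list(F = unname(res$statistic), p = unname(res$p.value))
}
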