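# ProtParam-style physicochemical statistics: molecular weight, theoretical
# pI, GRAVY, aliphatic index, instability index.

check_protein <- function(seq, allow_unknown = FALSE) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty protein sequence")
  chars <- strsplit(seq, "")[[1]]
  extra <- if (allow_unknown) c("X", "B", "Z") else character(0)
  bad <- setdiff(unique(chars), c(AA20, extra))
  if (length(bad))
    stop("unknown residue(s): ", paste(bad, collapse = ", "))
  chars
}

#' Average-isotopic molecular weight of a peptide
#'
#' Sum of ExPASy average residue masses plus one water (18.0153 Da).
#' With `allow_unknown = TRUE`, residues X/B/Z contribute the mean residue
#' mass.
#'
#' @param seq Amino-acid string.
#' @param allow_unknown Tolerate X/B/Z (default strict).
#' @return Molecular weight in Da.
#' @export
molecular_weight <- function(seq, allow_unknown = FALSE) {
  chars <- check_protein(seq, allow_unknown)
  m <- RESIDUE_MASS[chars]
  m[is.na(m)] <- mean(RESIDUE_MASS)
  sum(m) + WATER_MASS
}

# Net charge of a peptide at a given pH under the Bjellqvist pKa set.
peptide_charge <- function(counts, n_basic_term = 1, n_acidic_term = 1,
                           pH, pka = PKA_SET) {
  pos <- n_basic_term / (1 + 10^(pH - pka$nterm))
  for (r in names(pka$basic))
    pos <- pos + counts[[r]] / (1 + 10^(pH - pka$basic[[r]]))
  neg <- n_acidic_term / (1 + 10^(pka$cterm - pH))
  for (r in names(pka$acidic))
    neg <- neg + counts[[r]] / (1 + 10^(pka$acidic[[r]] - pH))
  pos - neg
}

#' Theoretical isoelectric point
#'
#' The pH at which the peptide's net charge (Henderson-Hasselbalch over the
#' termini and D, E, C, Y, H, K, R side chains; Bjellqvist pKa values) is
#' zero, found by bisection on `[0, 14]` to `|charge| < 1e-4`.
#'
#' @param seq Amino-acid string.
#' @param pka pKa set (list with `nterm`, `cterm`, `acidic`, `basic`).
#' @param allow_unknown Tolerate X/B/Z (no ionizable contribution).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, pka = PKA_SET, allow_unknown = FALSE) {
  chars <- check_protein(seq, allow_unknown)
  ion <- c(names(pka$acidic), names(pka$basic))
  counts <- as.list(vapply(ion, function(r) sum(chars == r), numeric(1)))
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- peptide_charge(counts, pH = mid, pka = pka)
    if (abs(q) < 1e-4 || (hi - lo) < 1e-8) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues. Unknown residues (X/B/Z,
#' when allowed) contribute zero to the numerator but count in the length.
#'
#' @inheritParams molecular_weight
#' @return GRAVY score (dimensionless).
#' @export
gravy <- function(seq, allow_unknown = FALSE) {
  chars <- check_protein(seq, allow_unknown)
  v <- KD_HYDROPATHY[chars]
  v[is.na(v)] <- 0
  sum(v) / length(chars)
}

#' Aliphatic index
#'
#' `AI = X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu)` with X in mole percent.
#'
#' @inheritParams molecular_weight
#' @return Aliphatic index (dimensionless).
#' @export
aliphatic_index <- function(seq, allow_unknown = FALSE) {
  chars <- check_protein(seq, allow_unknown)
  L <- length(chars)
  100 * (sum(chars == "A") + 2.9 * sum(chars == "V") +
           3.9 * (sum(chars == "I") + sum(chars == "L"))) / L
}

#' Instability index
#'
#' Guruprasad's `II = (10 / L) * sum of DIWV(x, y)` over the `L - 1`
#' dipeptides. Proteins with II below 40 are conventionally called stable;
#' II of exactly 40 counts as unstable (strict inequality). Dipeptides
#' containing an unknown residue (when allowed) contribute zero.
#'
#' @inheritParams molecular_weight
#' @return Instability index (dimensionless).
#' @export
instability_index <- function(seq, allow_unknown = FALSE) {
  chars <- check_protein(seq, allow_unknown)
  L <- length(chars)
  if (L < 2) stop("instability index needs at least 2 residues")
  a <- chars[-L]; b <- chars[-1]
  w <- DIWV[cbind(match(a, AA20), match(b, AA20))]
  w[is.na(w)] <- 0
  10 * sum(w) / L
}

#' Per-protein statistics and extremes for a catalog
#'
#' Computes all five statistics for every catalog entry and reports, per
#' statistic, the min/max value and the protein(s) attaining it.
#'
#' @param catalog A gene catalog (from [identify_family()]), or any data frame
#'   with `name` and `gene_id` columns.
#' @param proteome Sequence table resolving the catalog's `gene_id`s.
#' @param allow_unknown Tolerate X/B/Z residues.
#' @return List with `stats` (one row per protein: `name`, `gene_id`,
#'   `length`, `mw`, `pi`, `instability_index`, `aliphatic_index`, `gravy`,
#'   `is_stable`) and `extremes` (one row per statistic x min/max).
#' @export
summarize_properties <- function(catalog, proteome, allow_unknown = FALSE) {
  seqs <- proteome$sequence[match(catalog$gene_id, proteome$id)]
  if (anyNA(seqs)) stop("catalog gene(s) missing from proteome: ",
                        catalog$gene_id[which(is.na(seqs))[1]])
  stats <- data.frame(
    name = catalog$name, gene_id = catalog$gene_id,
    length = nchar(seqs),
    mw = vapply(seqs, molecular_weight, numeric(1), allow_unknown),
    pi = vapply(seqs, isoelectric_point, numeric(1),
                allow_unknown = allow_unknown),
    instability_index = vapply(seqs, instability_index, numeric(1),
                               allow_unknown),
    aliphatic_index = vapply(seqs, aliphatic_index, numeric(1), allow_unknown),
    gravy = vapply(seqs, gravy, numeric(1), allow_unknown),
    row.names = NULL, stringsAsFactors = FALSE)
  stats$is_stable <- stats$instability_index < 40
  ex <- do.call(rbind, lapply(
    c("length", "mw", "pi", "instability_index", "aliphatic_index", "gravy"),
    function(col) {
      v <- stats[[col]]
      data.frame(statistic = col,
                 which = c("min", "max"),
                 value = c(min(v), max(v)),
                 proteins = c(paste(stats$name[v == min(v)], collapse = "/"),
                              paste(stats$name[v == max(v)], collapse = "/")),
                 stringsAsFactors = FALSE)
    }))
  list(stats = stats, extremes = ex)
}
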