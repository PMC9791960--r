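# Nei-Gojobori (1986) Ka/Ks: fractional site counting per codon, equal-weight
# averaging over minimal mutational pathways (stop-passing pathways excluded
# and the rest renormalized), Jukes-Cantor correction, selection
# classification, and molecular-clock divergence dating.

#' Synonymous/nonsynonymous site counts of a sense codon
#'
#' For each codon position, the fraction of the possible single-nucleotide
#' changes that are synonymous, with changes creating a stop codon excluded
#' from the denominator. Returns `s` (synonymous sites) and `n = 3 - s`.
#'
#' @param codon A three-letter sense codon.
#' @return Named numeric vector `c(s, n)` with `s + n = 3`.
#' @export
ng86_site_counts <- function(codon) {
  tab <- codon_tables()
  codon <- toupper(codon)
  if (!codon %in% names(tab$index)) stop("not a codon: ", codon)
  i <- tab$index[[codon]]
  if (tab$is_stop[i]) stop("stop codon has no site counts: ", codon)
  s <- 0
  for (pos in 1:3) {
    slots <- (pos - 1) * 3 + 1:3
    usable <- !tab$nbr_stop[i, slots]
    if (any(usable))
      s <- s + sum(tab$nbr_syn[i, slots][usable]) / sum(usable)
  }
  c(s = s, n = 3 - s)
}

#' Pathway-averaged substitution differences between two codons
#'
#' Enumerates all orderings of the differing positions (1, 2 or 6 minimal
#' pathways), drops pathways passing through a stop codon, renormalizes over
#' the remainder, and averages the synonymous and nonsynonymous step counts.
#'
#' @param codon_a,codon_b Sense codons.
#' @return Named numeric vector `c(sd, nd)`; `sd + nd` equals the number of
#'   differing positions. Errors if every pathway is blocked by stops.
#' @export
ng86_pathway_differences <- function(codon_a, codon_b) {
  tab <- codon_tables()
  a <- strsplit(toupper(codon_a), "")[[1]]
  b <- strsplit(toupper(codon_b), "")[[1]]
  if (length(a) != 3 || length(b) != 3) stop("codons must have 3 bases")
  if (tab$is_stop[tab$index[[paste(a, collapse = "")]]] ||
      tab$is_stop[tab$index[[paste(b, collapse = "")]]])
    stop("stop codons are not comparable")
  diffs <- which(a != b)
  if (!length(diffs)) return(c(sd = 0, nd = 0))
  perms <- permutations_of(diffs)
  sd <- 0; nd <- 0; n_ok <- 0
  for (ord in perms) {
    cur <- a
    path_s <- 0; path_n <- 0
    blocked <- FALSE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- b[pos]
      j <- tab$index[[paste(nxt, collapse = "")]]
      if (tab$is_stop[j]) { blocked <- TRUE; break }
      i <- tab$index[[paste(cur, collapse = "")]]
      if (tab$aa[i] == tab$aa[j]) path_s <- path_s + 1
      else path_n <- path_n + 1
      cur <- nxt
    }
    if (!blocked) {
      sd <- sd + path_s; nd <- nd + path_n; n_ok <- n_ok + 1
    }
  }
  if (n_ok == 0)
    stop("all mutational pathways between ", codon_a, " and ", codon_b,
         " pass through stop codons")
  c(sd = sd / n_ok, nd = nd / n_ok)
}

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in permutations_of(x[-i]))
      out[[length(out) + 1]] <- c(x[i], rest)
  out
}

#' NG86 Ka/Ks for a codon-aligned pair
#'
#' Site counts `S`, `N` are averaged over the two sequences; difference
#' counts `Sd`, `Nd` are pathway-averaged per codon pair and summed;
#' proportions `pS = Sd/S`, `pN = Nd/N` are Jukes-Cantor corrected:
#' `Ks = -(3/4) ln(1 - 4 pS / 3)` (same for Ka); `omega = Ka/Ks`. Saturated
#' pairs (`pS >= 3/4` or `pN >= 3/4`) and pairs with `Ks = 0` are flagged
#' `incalculable` with `omega = NA`.
#'
#' @param seq_a,seq_b Gap-free CDS strings of equal length (no internal
#'   stops; a trailing stop codon is tolerated and trimmed from both).
#' @param lambda_rate Clock rate for [divergence_time()] (substitutions per
#'   synonymous site per year).
#' @return A one-row data.frame: `n_codons`, `S`, `N`, `Sd`, `Nd`, `pS`,
#'   `pN`, `Ka`, `Ks`, `omega`, `selection`, `t_mya`, `flag`.
#' @export
ka_ks <- function(seq_a, seq_b, lambda_rate = 6.5e-9) {
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  if (length(ca) != length(cb)) stop("sequences differ in codon length")
  tab <- codon_tables()
  bad <- setdiff(c(ca, cb), names(tab$index))
  if (length(bad)) stop("invalid codon(s): ", paste(bad, collapse = ", "))
  stop_a <- tab$is_stop[tab$index[ca]]
  stop_b <- tab$is_stop[tab$index[cb]]
  # tolerate one trailing stop codon on both
  if (length(ca) > 1 && stop_a[length(ca)] && stop_b[length(cb)]) {
    ca <- ca[-length(ca)]; cb <- cb[-length(cb)]
    stop_a <- stop_a[-length(stop_a)]; stop_b <- stop_b[-length(stop_b)]
  }
  if (any(stop_a) || any(stop_b)) stop("internal stop codon in alignment")
  n_codons <- length(ca)
  sa <- vapply(ca, function(cc) ng86_site_counts(cc)[["s"]], numeric(1))
  sb <- vapply(cb, function(cc) ng86_site_counts(cc)[["s"]], numeric(1))
  S <- (sum(sa) + sum(sb)) / 2
  N <- 3 * n_codons - S
  Sd <- 0; Nd <- 0
  for (k in seq_len(n_codons)) {
    d <- ng86_pathway_differences(ca[k], cb[k])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) -3 / 4 * log(1 - 4 * p / 3)
  flag <- "ok"
  Ks <- Ka <- NA_real_
  if (pS >= 3 / 4 || pN >= 3 / 4) {
    flag <- "incalculable"     # substitutional saturation
  } else {
    Ks <- jc(pS); Ka <- jc(pN)
    if (Ks == 0) flag <- "incalculable"   # omega undefined
  }
  omega <- if (flag == "ok") Ka / Ks else NA_real_
  data.frame(n_codons = n_codons, S = S, N = N, Sd = Sd, Nd = Nd,
             pS = pS, pN = pN, Ka = Ka, Ks = Ks, omega = omega,
             selection = if (flag == "ok") classify_selection(omega)
                         else NA_character_,
             t_mya = if (!is.na(Ks)) divergence_time(Ks, lambda_rate)
                     else NA_real_,
             flag = flag, stringsAsFactors = FALSE)
}

#' Molecular-clock divergence time from synonymous divergence
#'
#' `T = Ks / (2 lambda)` years, reported in millions of years (Mya).
#'
#' @param Ks Synonymous substitutions per synonymous site (>= 0).
#' @param lambda_rate Clock rate in substitutions per site per year
#'   (default 6.5e-9, the grass synonymous clock).
#' @return Divergence time in Mya.
#' @export
divergence_time <- function(Ks, lambda_rate = 6.5e-9) {
  if (any(Ks < 0)) stop("Ks must be >= 0")
  if (lambda_rate <= 0) stop("lambda_rate must be > 0")
  Ks / (2 * lambda_rate) / 1e6
}

#' Selection regime from an omega value
#'
#' `omega < 1` purifying, `omega = 1` (within `eps`) neutral, `omega > 1`
#' positive.
#'
#' @param omega Finite Ka/Ks value.
#' @param eps Equality guard for the neutral class (default 1e-6).
#' @return One of `"purifying"`, `"neutral"`, `"positive"`.
#' @export
classify_selection <- function(omega, eps = 1e-6) {
  if (!is.finite(omega) || omega < 0) stop("omega must be finite and >= 0")
  if (abs(omega - 1) <= eps) return("neutral")
  if (omega < 1) "purifying" else "positive"
}

#' Back-thread a protein alignment onto CDS to get a codon alignment
#'
#' Columns where either protein holds a gap are dropped; remaining aligned
#' residues are replaced by their source codons.
#'
#' @param aln_a,aln_b Aligned protein strings (with `-` gaps).
#' @param cds_a,cds_b Ungapped CDS of the two proteins (trailing stop codon
#'   allowed).
#' @return List with gap-free `seq_a`, `seq_b` codon strings.
#' @export
codon_alignment <- function(aln_a, aln_b, cds_a, cds_b) {
  pa <- strsplit(aln_a, "")[[1]]
  pb <- strsplit(aln_b, "")[[1]]
  if (length(pa) != length(pb)) stop("protein alignment rows differ in length")
  coda <- split_codons(cds_a)
  codb <- split_codons(cds_b)
  ia <- cumsum(pa != "-")
  ib <- cumsum(pb != "-")
  keep <- pa != "-" & pb != "-"
  list(seq_a = paste(coda[ia[keep]], collapse = ""),
       seq_b = paste(codb[ib[keep]], collapse = ""))
}
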