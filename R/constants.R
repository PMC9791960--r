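# Shared lookup tables: amino-acid constants and the standard genetic code.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# ExPASy average residue masses (Da); peptide MW = sum(residues) + one water.
WATER_MASS <- 18.0153
RESIDUE_MASS <- c(
  A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167, Q = 128.1307, R = 156.1875,
  S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760
)

# Kyte-Doolittle hydropathy.
KD_HYDROPATHY <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

# Bjellqvist pKa set (ExPASy default family). nterm/cterm are the termini.
PKA_SET <- list(
  nterm = 7.50, cterm = 3.55,
  acidic = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00),
  basic  = c(H = 5.98, K = 10.00, R = 12.00)
)

# Guruprasad dipeptide instability weights (DIWV), rows = first residue.
DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE, dimnames = list(AA20, AA20))

NUC <- c("T", "C", "A", "G")

# All 64 codons in TCAG order; translation via the standard nuclear code.
CODONS <- as.vector(outer(outer(NUC, NUC, function(a, b) paste0(a, b)),
                          NUC, paste0))
CODONS <- sort(CODONS)  # alphabetical; order is irrelevant, lookups are by name

codon_aa <- NULL  # populated at load time (needs Biostrings)

.codon_env <- new.env(parent = emptyenv())

# Codon machinery built lazily: amino-acid translation, stop flags, and for each
# codon the 9 single-nucleotide neighbours with their synonymous/stop status.
codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  gc_map <- Biostrings::GENETIC_CODE
  aa <- unname(gc_map[CODONS])
  is_stop <- aa == "*"
  n <- length(CODONS)
  nbr <- matrix(NA_integer_, n, 9)         # neighbour codon index
  nbr_syn <- matrix(FALSE, n, 9)           # synonymous change?
  nbr_stop <- matrix(FALSE, n, 9)          # change creates a stop?
  codon_index <- seq_len(n)
  names(codon_index) <- CODONS
  for (i in codon_index) {
    cod <- strsplit(CODONS[i], "")[[1]]
    k <- 0
    for (pos in 1:3) {
      for (alt in setdiff(NUC, cod[pos])) {
        k <- k + 1
        mut <- cod
        mut[pos] <- alt
        j <- codon_index[[paste(mut, collapse = "")]]
        nbr[i, k] <- j
        nbr_syn[i, k] <- identical(aa[j], aa[i])
        nbr_stop[i, k] <- is_stop[j]
      }
    }
  }
  .codon_env$tab <- list(aa = aa, is_stop = is_stop, index = codon_index,
                         nbr = nbr, nbr_syn = nbr_syn, nbr_stop = nbr_stop)
  .codon_env$tab
}

# Split a nucleotide string into a vector of codons; errors on ragged length.
split_codons <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0)
    stop("sequence length ", nchar(seq), " is not a multiple of 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}
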