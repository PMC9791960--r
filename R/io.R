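#' Read a FASTA file into a sequence table
#'
#' Parses a (plain or gzipped) FASTA file with Biostrings and returns one row
#' per record. The first whitespace-delimited token of each header is the
#' record id; the remainder is kept as the description. Sequences are
#' normalized to upper case. Duplicate ids and empty sequences are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with columns `id`, `description`, `sequence`,
#'   in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence for record '", ids[which(empty)[1]], "' in ", path)
  dup <- duplicated(ids)
  if (any(dup))
    stop("duplicate FASTA id '", ids[which(dup)[1]], "' in ", path)
  data.frame(id = ids, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write a sequence table to FASTA
#'
#' @param records Data frame with columns `id`, `sequence` and optionally
#'   `description` (appended to the header after a space when non-empty).
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  headers <- records$id
  if (!is.null(records$description)) {
    has_desc <- nzchar(records$description)
    headers[has_desc] <- paste(records$id[has_desc],
                               records$description[has_desc])
  }
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

parse_chromosome <- function(chrom) {
  num <- ifelse(grepl("^\\d+[A-Z]$", chrom), as.integer(sub("[A-Z]$", "", chrom)),
                NA_integer_)
  sub_g <- ifelse(grepl("^\\d+[A-Z]$", chrom), sub("^\\d+", "", chrom),
                  ifelse(chrom == "U", "U", NA_character_))
  list(number = num, subgenome = sub_g)
}

#' Read gene features from a GFF3 file
#'
#' Retains `gene` features only. Chromosome labels are expected to follow the
#' `<number><subgenome letter>` convention of an allopolyploid assembly
#' (e.g. `5B`), or `U` for unplaced scaffolds; the subgenome letter is parsed
#' out. Coordinates are 1-based inclusive throughout the package. Malformed
#' lines are rejected with their line number rather than repaired.
#'
#' @param path Path to a GFF3 file.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `chrom_number`, `subgenome`, sorted by (chromosome, start).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no feature lines in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9)
  if (length(bad))
    stop("GFF3 line ", lineno[bad[1]], ": expected 9 tab-separated columns, got ",
         length(fields[[bad[1]]]))
  mat <- do.call(rbind, fields)
  type <- mat[, 3]
  gene <- type == "gene"
  if (!any(gene)) stop("no 'gene' features in ", path)
  start <- suppressWarnings(as.integer(mat[gene, 4]))
  end <- suppressWarnings(as.integer(mat[gene, 5]))
  gl <- lineno[gene]
  if (anyNA(start) || anyNA(end))
    stop("GFF3 line ", gl[which(is.na(start) | is.na(end))[1]],
         ": non-numeric coordinate")
  rev_coord <- which(end < start)
  if (length(rev_coord))
    stop("GFF3 line ", gl[rev_coord[1]], ": end < start")
  attrs <- mat[gene, 9]
  id <- sub("^.*ID=([^;]+).*$", "\\1", attrs)
  no_id <- which(!grepl("ID=", attrs))
  if (length(no_id))
    stop("GFF3 line ", gl[no_id[1]], ": gene feature without ID attribute")
  chrom <- mat[gene, 1]
  pc <- parse_chromosome(chrom)
  out <- data.frame(gene_id = id, chrom = chrom, start = start, end = end,
                    strand = mat[gene, 7], chrom_number = pc$number,
                    subgenome = pc$subgenome, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write gene features as GFF3
#'
#' Emits a `gene` and a matching `mRNA` feature (with `ID=`/`Parent=`) per row,
#' 1-based inclusive coordinates, GFF version 3 header.
#'
#' @param features Data frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(features)))
  gene_lines <- sprintf("%s\tpolyfam\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                        features$chrom, features$start, features$end,
                        features$strand, features$gene_id)
  mrna_lines <- sprintf("%s\tpolyfam\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
                        features$chrom, features$start, features$end,
                        features$strand, features$gene_id, features$gene_id)
  writeLines(c("##gff-version 3",
               as.vector(rbind(gene_lines, mrna_lines))), path)
  invisible(path)
}

#' Parse the packaged domain-architecture table
#'
#' Reads the TSV transcription of the published domain-architecture census
#' (domain type, slash-separated member ids per homoeologous group, gene
#' number, chromosome field, subgenome composition field). Blank domain-type
#' cells inherit the value from the row above, as in the printed table.
#'
#' @param path Path to the TSV (default: the fixture shipped with the package).
#' @return A `data.frame` with columns `domain_type`, `triad_gene_ids`
#'   (list column), `gene_number`, `chromosome_field`, `genomes_field`.
#' @export
parse_domain_table <- function(path = system.file("extdata",
                                                  "wheat_phd_domain_table.tsv",
                                                  package = "polyfam")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("domain_type", "triad", "gene_number", "chr", "genomes")
  if (!all(need %in% names(tab)))
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  # carry the domain type down through the blank cells of a merged table block
  dt <- tab$domain_type
  for (i in seq_along(dt)) if (!nzchar(dt[i])) dt[i] <- dt[i - 1]
  ids <- strsplit(tab$triad, "/", fixed = TRUE)
  n <- as.integer(tab$gene_number)
  mismatch <- which(lengths(ids) != n)
  if (length(mismatch))
    stop("row ", mismatch[1], ": gene_number (", n[mismatch[1]],
         ") does not match the number of listed ids (",
         lengths(ids)[mismatch[1]], ")")
  flat <- unlist(ids)
  dup <- flat[duplicated(flat)]
  if (length(dup)) stop("duplicate gene id in domain table: ", dup[1])
  data.frame(domain_type = dt,
             triad_gene_ids = I(ids),
             gene_number = n,
             chromosome_field = tab$chr,
             genomes_field = tab$genomes,
             stringsAsFactors = FALSE)
}

#' Write a phylogenetic tree to Newick
#'
#' Branch lengths are serialized with six decimals; internal node labels hold
#' integer bootstrap supports when present.
#'
#' @param tree An `ape::phylo` object (optionally with `node.label` supports).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$node.label)) {
    lab <- suppressWarnings(as.numeric(tree$node.label))
    tree$node.label <- ifelse(is.na(lab), tree$node.label,
                              as.character(as.integer(round(lab))))
  }
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Read a TPM expression matrix from TSV
#'
#' Expects genes in rows (first column = gene id) and samples in columns.
#'
#' @param path Path to the TSV.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_tpm_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- tab[[1]]
  if (any(m < 0, na.rm = TRUE)) stop("negative TPM values in ", path)
  m
}

#' Write a TPM expression matrix as TSV
#' @param tpm Numeric matrix, genes x samples.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tpm_matrix <- function(tpm, path) {
  df <- data.frame(gene = rownames(tpm), tpm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
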