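#' Read a protein FASTA file into a tibble
#'
#' Sequences are upper-cased and wrapped lines concatenated. Each record
#' becomes one row; the `source` column records that sequences were provided
#' rather than translated in-package.
#'
#' @param path path to a FASTA file of amino-acid sequences.
#' @return a tibble with columns `id`, `sequence`, `source`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKLV", "ACDE"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    warn("FASTA file contains no records; returning an empty collection.")
    return(tibble(id = character(), sequence = character(), source = character()))
  }
  # FASTA headers keep only the first whitespace-delimited token as the id
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate FASTA id(s): %s", paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) check_aa_sequence(seqs[i], arg = ids[i])
  tibble(id = ids, sequence = unname(seqs), source = "provided")
}

#' Write protein records to a FASTA file
#'
#' @param proteins a data frame with columns `id` and `sequence`.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  set <- Biostrings::BStringSet(setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Translate a coding sequence to protein
#'
#' Standard genetic code; a single terminal stop codon is permitted and
#' excluded from the protein, so a CDS of 336 bp ending in a stop yields a
#' 111-aa protein. Internal stop codons and ambiguity codes are rejected
#' rather than translated through, which keeps CDS/3 - 1 length arithmetic
#' exact.
#'
#' @param dna a character vector of CDS strings (ACGT only, length divisible
#'   by 3).
#' @return a character vector of protein strings.
#' @examples
#' translate_cds("ATGGGTTAA")  # "MG"
#' @export
translate_cds <- function(dna) {
  vapply(dna, translate_one_cds, character(1), USE.NAMES = FALSE)
}

translate_one_cds <- function(dna) {
  if (!is.character(dna) || length(dna) != 1 || is.na(dna) || nchar(dna) == 0) {
    abort("`dna` must be a single non-empty string.")
  }
  dna <- toupper(dna)
  bad <- setdiff(unique(seq_chars(dna)), c("A", "C", "G", "T"))
  if (length(bad) > 0) {
    abort(sprintf(
      "CDS contains non-ACGT symbol(s): %s (ambiguity codes are rejected)",
      paste(bad, collapse = ", ")
    ))
  }
  n <- nchar(dna)
  if (n %% 3 != 0) abort(sprintf("CDS length %d is not divisible by 3.", n))
  codons <- substring(dna, seq(1, n, by = 3), seq(3, n, by = 3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stops <- which(aa == "*")
  n_codon <- length(aa)
  if (length(stops) > 0 && any(stops < n_codon)) {
    abort(sprintf(
      "Internal stop codon at codon index %d.", stops[stops < n_codon][1]
    ))
  }
  if (length(stops) > 0) aa <- aa[-n_codon]
  paste(aa, collapse = "")
}

# One representative codon per amino acid; fixed choice makes
# translate_cds(reverse_translate(p)) an exact round trip.
REVERSE_CODON <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT"
)

#' Reverse-translate a protein with a fixed codon table
#'
#' Used by the synthetic-data generator and round-trip tests; appends a TAA
#' stop so `translate_cds()` inverts it exactly.
#'
#' @param protein a character vector of protein strings (canonical letters).
#' @param stop append a terminal stop codon?
#' @return a character vector of CDS strings.
#' @export
reverse_translate <- function(protein, stop = TRUE) {
  vapply(protein, function(p) {
    check_aa_sequence(p, allow_x = FALSE, arg = "protein")
    body <- paste(REVERSE_CODON[seq_chars(p)], collapse = "")
    if (stop) paste0(body, "TAA") else body
  }, character(1), USE.NAMES = FALSE)
}

#' Gene-structure statistics from a GFF3 file
#'
#' Counts exon features for a gene and derives the intron count as
#' exons - 1. When the annotation also carries explicit `intron` features,
#' their count is reported alongside and a discrepancy flag is raised if the
#' two disagree (some annotations list UTR introns that exon arithmetic
#' cannot see), rather than trusting either source.
#'
#' @param gff path to a GFF3 file (1-based inclusive coordinates).
#' @param gene_id gene identifier to look up (matched against `ID=` and
#'   `Parent=` attributes).
#' @return a one-row tibble: `gene_id`, `cds_length`, `gene_length`,
#'   `exon_count`, `intron_count`, `intron_count_annotated`,
#'   `intron_discrepancy`, `strand`.
#' @export
gene_structure_stats <- function(gff, gene_id) {
  if (!file.exists(gff)) abort(sprintf("GFF3 file not found: %s", gff))
  g <- ape::read.gff(gff, na.strings = c(".", "?"))
  has_id <- grepl(paste0("(^|;)(ID|Parent)=", gene_id, "($|[;.])"), g$attributes)
  gene_rows <- g[has_id | grepl(paste0("(^|;)ID=", gene_id, "($|;)"), g$attributes), , drop = FALSE]
  if (nrow(gene_rows) == 0) abort(sprintf("Gene not found in GFF: %s", gene_id))

  feature_rows <- function(type) {
    r <- gene_rows[gene_rows$type == type, , drop = FALSE]
    r[order(r$start), , drop = FALSE]
  }
  exons <- feature_rows("exon")
  if (nrow(exons) == 0) abort(sprintf("Gene %s has no exon features.", gene_id))
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    abort(sprintf("Gene %s has overlapping exon features.", gene_id))
  }
  cds <- feature_rows("CDS")
  gene_feat <- feature_rows("gene")
  gene_span <- if (nrow(gene_feat) > 0) {
    gene_feat$end[1] - gene_feat$start[1] + 1L
  } else {
    max(exons$end) - min(exons$start) + 1L
  }
  cds_length <- if (nrow(cds) > 0) sum(cds$end - cds$start + 1L) else NA_integer_
  if (!is.na(cds_length) && cds_length %% 3 != 0) {
    warn(sprintf("Gene %s: CDS length %d not divisible by 3.", gene_id, cds_length))
  }
  exon_count <- nrow(exons)
  intron_count <- exon_count - 1L
  n_intron_feat <- sum(gene_rows$type == "intron")
  annotated <- if (n_intron_feat > 0) as.integer(n_intron_feat) else NA_integer_
  strand <- as.character(exons$strand[1])

  tibble(
    gene_id = gene_id,
    cds_length = as.integer(cds_length),
    gene_length = as.integer(gene_span),
    exon_count = as.integer(exon_count),
    intron_count = as.integer(intron_count),
    intron_count_annotated = annotated,
    intron_discrepancy = !is.na(annotated) && annotated != intron_count,
    strand = strand
  )
}
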