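#' Build a transcript set from sequences and CDS intervals
#'
#' A transcript set holds uppercase DNA sequences together with one CDS
#' interval per transcript in 0-based, half-open transcript coordinates:
#' `cds_start` is the first nucleotide of the start codon, `cds_end` is one
#' past the last nucleotide of the stop codon. Codon 0 is the start codon and
#' the final codon is the stop codon. Per-transcript codon vectors are
#' precomputed so codon lookups during site assignment are O(1).
#'
#' @param sequences named character vector of transcript sequences
#'   (A/C/G/T; lowercase and RNA `U` are normalized).
#' @param cds data.frame with columns `transcript_id`, `cds_start`, `cds_end`.
#' @return object of class `transcript_set`.
#' @export
transcript_set <- function(sequences, cds) {
  cds <- as.data.table(cds)[, .(transcript_id, cds_start, cds_end)]
  if (anyDuplicated(cds$transcript_id))
    stop("duplicated transcript ids in CDS table")
  if (nrow(cds) == 0L) stop("transcript set must be non-empty")
  missing <- setdiff(cds$transcript_id, names(sequences))
  if (length(missing))
    stop("transcript(s) in CDS table absent from FASTA: ",
         paste(missing, collapse = ", "))
  sequences <- toupper(sequences[cds$transcript_id])
  sequences <- gsub("U", "T", sequences, fixed = TRUE)
  bad <- grepl("[^ACGT]", sequences)
  if (any(bad))
    stop("non-ACGT characters in sequence(s): ",
         paste(names(sequences)[bad], collapse = ", "))
  cds[, cds_start := as.integer(cds_start)]
  cds[, cds_end := as.integer(cds_end)]
  cds[, tx_len := nchar(sequences[transcript_id])]
  if (any(cds$cds_start < 0L | cds$cds_start >= cds$cds_end |
          cds$cds_end > cds$tx_len))
    stop("CDS coordinates out of bounds (require 0 <= cds_start < cds_end <= length)")
  if (any((cds$cds_end - cds$cds_start) %% 3L != 0L))
    stop("CDS length not multiple of 3 for: ", paste(
      cds$transcript_id[(cds$cds_end - cds$cds_start) %% 3L != 0L],
      collapse = ", "))
  cds[, n_codons := (cds_end - cds_start) %/% 3L]
  codons <- Map(function(seq, s, n) {
    substring(seq, s + 1L + 3L * (seq_len(n) - 1L), s + 3L * seq_len(n))
  }, sequences, cds$cds_start, cds$n_codons)
  structure(list(sequences = sequences, cds = cds, codons = codons),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x$cds), "transcript(s),",
      sum(x$cds$n_codons), "CDS codons total\n")
  invisible(x)
}

#' @export
length.transcript_set <- function(x) nrow(x$cds)

#' @rdname transcript_set
#' @param transcripts a `transcript_set`.
#' @export
transcript_ids <- function(transcripts) transcripts$cds$transcript_id

#' Read transcripts from FASTA plus a CDS coordinate table
#'
#' @param fasta_path FASTA of transcript sequences.
#' @param cds_table_path TSV with header `transcript_id`, `cds_start`,
#'   `cds_end` (0-based half-open).
#' @return a [transcript_set()].
#' @export
read_transcripts <- function(fasta_path, cds_table_path) {
  # BStringSet so RNA-alphabet and lowercase records load; normalization
  # to uppercase DNA happens in transcript_set()
  seqs <- Biostrings::readBStringSet(fasta_path)
  sequences <- setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  cds <- fread(cds_table_path, sep = "\t")
  req <- c("transcript_id", "cds_start", "cds_end")
  if (!all(req %in% names(cds)))
    stop("CDS table must have columns: ", paste(req, collapse = ", "))
  transcript_set(sequences, cds)
}

#' Write a transcript set as FASTA + CDS table
#'
#' @param transcripts a [transcript_set()].
#' @param fasta_path,cds_table_path output paths.
#' @export
write_transcripts <- function(transcripts, fasta_path, cds_table_path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(transcripts$sequences), fasta_path)
  fwrite(transcripts$cds[, .(transcript_id, cds_start, cds_end)],
         cds_table_path, sep = "\t")
  invisible(NULL)
}

#' Extract a codon from a transcript's CDS
#'
#' Codon indices are 0-based within the CDS: index 0 is the start codon, the
#' last index is the stop codon.
#'
#' @param transcripts a [transcript_set()].
#' @param transcript_id transcript identifier.
#' @param codon_index 0-based codon index (vectorized).
#' @return character vector of 3-nt codons.
#' @export
codon_at <- function(transcripts, transcript_id, codon_index) {
  cv <- transcripts$codons[[transcript_id]]
  if (is.null(cv)) stop("unknown transcript: ", transcript_id)
  if (any(codon_index < 0L | codon_index >= length(cv)))
    stop("codon index out of range for ", transcript_id,
         " (", length(cv), " codons)")
  cv[codon_index + 1L]
}

# ---- footprint alignments -------------------------------------------------

ALIGNMENT_COLS <- c("sample_id", "condition", "replicate",
                    "transcript_id", "start", "length")

#' Construct a sample library of footprint alignments
#'
#' A sample library is a data.table with one row per aligned footprint:
#' `transcript_id`, `start` (0-based transcript coordinate of the 5' end),
#' `length` (nt), plus `sample_id`, `condition` and `replicate` labels.
#' Several samples may be row-bound into one table for joint processing.
#'
#' @param alignments data.frame with `transcript_id`, `start`, `length`.
#' @param sample_id,condition,replicate sample annotation.
#' @param transcripts optional [transcript_set()]; when given, alignments are
#'   checked against transcript bounds.
#' @return data.table with the six library columns.
#' @export
sample_library <- function(alignments, sample_id, condition, replicate,
                           transcripts = NULL) {
  al <- as.data.table(alignments)
  if (!all(c("transcript_id", "start", "length") %in% names(al)))
    stop("alignments need columns transcript_id, start, length")
  lib <- data.table(sample_id = sample_id, condition = condition,
                    replicate = as.integer(replicate),
                    transcript_id = al$transcript_id,
                    start = as.integer(al$start),
                    length = as.integer(al$length))
  validate_alignments(lib, transcripts)
  lib[]
}

validate_alignments <- function(lib, transcripts = NULL) {
  bad <- which(is.na(lib$start) | is.na(lib$length) |
               lib$start < 0L | lib$length < 1L)
  if (length(bad))
    stop("invalid alignment at row(s) ", paste(head(bad, 5L), collapse = ", "),
         ": start must be >= 0 and length >= 1")
  if (!is.null(transcripts)) {
    unknown <- setdiff(unique(lib$transcript_id), transcript_ids(transcripts))
    if (length(unknown))
      stop("alignment transcript(s) not in transcript set: ",
           paste(unknown, collapse = ", "))
    len <- nchar(transcripts$sequences)[lib$transcript_id]
    over <- which(lib$start + lib$length > len)
    if (length(over))
      stop("alignment exceeds transcript bounds at row(s) ",
           paste(head(over, 5L), collapse = ", "))
  }
  invisible(lib)
}

#' Read footprint alignments in transcript coordinates
#'
#' TSV dialect: header `transcript_id`, `start`, `length`; one row per read,
#' duplicates allowed. BAM: transcript-space, forward strand; secondary,
#' supplementary, reverse-strand and clipped records are dropped with a
#' message reporting the count (real transcriptome BAMs contain them; they
#' are not errors). Read length is the query length.
#'
#' @param path alignment file.
#' @param format `"tsv"` or `"bam"`.
#' @param sample_id,condition,replicate sample annotation.
#' @param transcripts optional [transcript_set()] for bounds checking.
#' @return a [sample_library()] data.table.
#' @export
read_alignments <- function(path, format = c("tsv", "bam"),
                            sample_id = basename(path), condition = NA_character_,
                            replicate = 1L, transcripts = NULL) {
  format <- match.arg(format)
  al <- if (format == "tsv") read_alignments_tsv(path) else
    read_alignments_bam(path)
  sample_library(al, sample_id, condition, replicate, transcripts)
}

read_alignments_tsv <- function(path) {
  al <- fread(path, sep = "\t", colClasses = list(
    character = "transcript_id"))
  if (!all(c("transcript_id", "start", "length") %in% names(al)))
    stop("alignment TSV must have header transcript_id, start, length")
  for (col in c("start", "length")) {
    v <- al[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != as.integer(v))) {
      row <- which(!is.finite(suppressWarnings(as.numeric(v))) |
                   suppressWarnings(as.numeric(v)) != floor(suppressWarnings(as.numeric(v))))[1]
      stop("malformed ", col, " at line ", (row %||% 1L) + 1L, " of ", path)
    }
  }
  bad <- which(al$start < 0L | al$length < 1L)
  if (length(bad))
    stop("malformed alignment at line ", bad[1] + 1L, " of ", path,
         " (negative start or non-positive length)")
  al
}

read_alignments_bam <- function(path) {
  b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("flag", "rname", "strand", "pos", "qwidth", "cigar")))[[1]]
  n <- length(b$flag)
  keep <- rep(TRUE, n)
  keep <- keep & bitwAnd(b$flag, 4L) == 0L                    # mapped
  keep <- keep & bitwAnd(b$flag, 256L) == 0L                  # primary
  keep <- keep & bitwAnd(b$flag, 2048L) == 0L                 # not supplementary
  keep <- keep & (as.character(b$strand) == "+")
  keep <- keep & grepl("^[0-9]+M$", b$cigar)                  # unclipped
  dropped <- sum(!keep)
  if (dropped > 0)
    message("read_alignments: dropped ", dropped,
            " secondary/supplementary/reverse/clipped record(s)")
  data.table(transcript_id = as.character(b$rname)[keep],
             start = b$pos[keep] - 1L,   # BAM POS is 1-based
             length = b$qwidth[keep])
}

#' Write a sample library as alignment TSV
#'
#' Rows are sorted by (`transcript_id`, `start`, `length`) so output is
#' stable; write-then-read round-trips the alignment multiset.
#'
#' @param library a [sample_library()].
#' @param path output TSV.
#' @export
write_alignments <- function(library, path) {
  out <- as.data.table(library)[, .(transcript_id, start, length)]
  setorder(out, transcript_id, start, length)
  fwrite(out, path, sep = "\t")
  invisible(NULL)
}
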