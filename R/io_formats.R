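# Readers/writers for the external formats the pipeline touches.
# Parsers reject malformed input rather than coercing it; round-trips are
# lossless for canonical files.

#' Read a FASTA file
#'
#' @param path file path.
#' @param alphabet `"DNA"` validates sequences over A/C/G/T/N
#'   (case-insensitive, upper-cased on read); `"AA"` accepts the 20
#'   amino acids plus `X`, `*` and the alignment gap `-`.
#' @return named character vector of sequences (possibly empty).
#'   Duplicate identifiers, empty sequences and illegal characters are
#'   errors naming the offending record.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "AA")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (length(ids) == 0L) return(stats::setNames(character(0), character(0)))
  if (anyDuplicated(ids))
    stop("duplicate FASTA identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  empty <- ids[nchar(seqs) == 0L]
  if (length(empty))
    stop("empty sequence for record(s): ", paste(empty, collapse = ", "))
  legal <- if (alphabet == "DNA") c("A", "C", "G", "T", "N")
           else c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*", "-")
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[[i]], "", fixed = TRUE)[[1]]), legal)
    if (length(bad))
      stop("illegal character(s) ", paste(bad, collapse = ""),
           " in record ", ids[i])
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)) || length(seqs) == 0L)
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read synchronized paired-end FASTQ files
#'
#' Phred+33 quality encoding is assumed throughout. Files must contain the
#' same number of records in the same order; mate identifiers must agree
#' after stripping a trailing `/1` or `/2`.
#'
#' @param path1,path2 mate FASTQ paths.
#' @return data.frame with columns `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- Biostrings::readBStringSet(path1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readBStringSet(path2, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2))
    stop("mate files are not synchronized: ", length(r1), " vs ", length(r2),
         " records")
  id1 <- sub("/[12]$", "", sub("\\s.*$", "", names(r1)))
  id2 <- sub("/[12]$", "", sub("\\s.*$", "", names(r2)))
  if (!identical(id1, id2))
    stop("mate identifiers disagree at record ",
         which(id1 != id2)[1])
  q1 <- as.character(S4Vectors::mcols(r1)$qualities)
  q2 <- as.character(S4Vectors::mcols(r2)$qualities)
  s1 <- toupper(as.character(r1)); s2 <- toupper(as.character(r2))
  bad <- which(nchar(s1) != nchar(q1) | nchar(s2) != nchar(q2))
  if (length(bad))
    stop("sequence/quality length mismatch at record ", id1[bad[1]])
  data.frame(read_id = id1, seq1 = unname(s1), qual1 = unname(q1),
             seq2 = unname(s2), qual2 = unname(q2),
             stringsAsFactors = FALSE)
}

#' Write paired reads as two synchronized FASTQ files
#'
#' @param pairs data.frame as returned by [read_fastq_pairs()].
#' @param path1,path2 output paths for mate 1 and mate 2.
#' @return invisibly, `c(path1, path2)`.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  .write_fastq_one <- function(ids, seqs, quals, mate, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    if (length(ids)) {
      txt <- paste0("@", ids, "/", mate, "\n", seqs, "\n+\n", quals)
      writeLines(txt, con, sep = "\n")
    }
    path
  }
  .write_fastq_one(pairs$read_id, pairs$seq1, pairs$qual1, 1L, path1)
  .write_fastq_one(pairs$read_id, pairs$seq2, pairs$qual2, 2L, path2)
  invisible(c(path1, path2))
}

#' Decode / encode Phred+33 quality strings
#'
#' @param qual character vector of quality strings.
#' @return for `phred_scores`, a list of integer vectors; for
#'   `phred_string`, a character vector.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' @rdname phred_scores
#' @param scores list (or vector) of integer Phred scores.
#' @export
phred_string <- function(scores) {
  if (!is.list(scores)) scores <- list(scores)
  vapply(scores, function(s) intToUtf8(s + 33L), character(1))
}

#' Read a gene-to-transcript map
#'
#' Headerless two-column text (gene id, then transcript id, tab- or
#' whitespace-separated), the format used to roll isoform-level abundance
#' up to gene level. Duplicated identical rows are deduplicated silently;
#' a transcript listed under two different genes is an error.
#'
#' @param path file path.
#' @return named character vector: `names()` are transcript ids, values
#'   are gene ids.
#' @export
read_genes_trans_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  parts <- strsplit(trimws(lines), "[\t ]+")
  if (any(lengths(parts) != 2L))
    stop("genes_trans_map line is not two columns: line ",
         which(lengths(parts) != 2L)[1])
  gene <- vapply(parts, `[[`, "", 1L)
  tx <- vapply(parts, `[[`, "", 2L)
  keep <- !duplicated(paste0(gene, "\r", tx))
  gene <- gene[keep]; tx <- tx[keep]
  dup <- tx[duplicated(tx)]
  if (length(dup))
    stop("transcript(s) listed under more than one gene: ",
         paste(unique(dup), collapse = ", "))
  stats::setNames(gene, tx)
}

#' Write a gene-to-transcript map
#'
#' @param map named character vector (transcript -> gene).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes_trans_map <- function(map, path) {
  writeLines(paste(unname(map), names(map), sep = "\t"), path)
  invisible(path)
}
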