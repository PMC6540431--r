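# Six-frame translation, ORF enumeration and completeness
# classification. Coordinates are 0-based half-open on the forward
# strand everywhere; the frame (+1..+3, -1..-3) carries the strand. ATG
# is the sole start codon; codons containing N translate to X and never
# count as start or stop.

.FRAME_LABELS <- c("+1", "+2", "+3", "-1", "-2", "-3")

#' Translate a nucleotide sequence in all six frames
#'
#' @param seq nucleotide string (length >= 3 for non-empty frames).
#' @return named character vector of peptides for frames `+1`, `+2`,
#'   `+3`, `-1`, `-2`, `-3` (stops as `*`). Frames `-1..-3` translate
#'   the reverse complement; trailing 1-2 nt of each frame are ignored.
#' @export
six_frame_translate <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  rc <- if (nchar(seq)) revcomp(seq) else seq
  out <- c(vapply(0:2, function(o) translate_nt(substr(seq, o + 1L, nchar(seq))),
                  character(1)),
           vapply(0:2, function(o) translate_nt(substr(rc, o + 1L, nchar(rc))),
                  character(1)))
  stats::setNames(out, .FRAME_LABELS)
}

# signed integer frame for a label and vice versa
.frame_int <- function(label) c(`+1` = 1L, `+2` = 2L, `+3` = 3L,
                                `-1` = -1L, `-2` = -2L, `-3` = -3L)[label]

#' Enumerate open reading frames with completeness classes
#'
#' Per frame, maximal stop-to-stop codon runs are scanned. A run with an
#' ATG that is stop-terminated yields a `complete` call (first
#' ATG..stop); with an ATG but running off the transcript end, a
#' `partial3` call; without any ATG, a run anchored at the transcript
#' start yields `partial5` if stop-terminated and `internal` if it spans
#' the whole frame. Interior runs with no start codon are not reported.
#' Intervals of stop-terminated calls include the stop codon; `peptide`
#' never includes the stop.
#'
#' @param seq nucleotide string.
#' @param transcript_id id recorded in the output.
#' @param min_len_aa minimum peptide length (>= 1) to report.
#' @return data.frame of ORF calls sorted by decreasing `length_aa`:
#'   columns `transcript_id`, `frame` (signed integer), `start`, `end`
#'   (0-based half-open, forward strand), `peptide`, `completeness`,
#'   `length_aa`, `aa_start`, `aa_end` (0-based half-open codon
#'   coordinates within the frame's translation, excluding the stop),
#'   and `aa_seg_start` (the enclosing stop-to-stop segment's first
#'   codon, used for homology-guided 5' extension).
#' @export
find_orfs <- function(seq, transcript_id = "tx", min_len_aa = 30L) {
  stopifnot(min_len_aa >= 1L)
  L <- nchar(seq)
  rc <- if (L) revcomp(seq) else seq
  calls <- list()
  for (fi in seq_along(.FRAME_LABELS)) {
    reverse <- fi > 3L
    offset <- (fi - 1L) %% 3L
    w <- if (reverse) rc else seq
    if (nchar(w) - offset < 3L) next
    starts <- seq.int(offset + 1L, nchar(w) - 2L, by = 3L)
    codons <- substring(w, starts, starts + 2L)
    aa <- .codon_table()[codons]
    aa[is.na(aa)] <- "X"
    ncod <- length(aa)
    is_stop <- aa == "*"
    # maximal runs of non-stop codons
    r <- rle(is_stop)
    seg_end <- cumsum(r$lengths)
    seg_start <- seg_end - r$lengths + 1L
    for (si in which(!r$values)) {
      cs <- seg_start[si]; ce <- seg_end[si]
      terminated <- ce < ncod # a stop codon follows
      atg_rel <- which(codons[cs:ce] == "ATG")
      emit <- NULL
      if (length(atg_rel)) {
        a0 <- cs + atg_rel[1] - 1L
        if (terminated) {
          emit <- list(c1 = a0, c2 = ce, stop = TRUE, class = "complete")
        } else {
          emit <- list(c1 = a0, c2 = ce, stop = FALSE, class = "partial3")
        }
      } else if (cs == 1L) {
        if (terminated) {
          emit <- list(c1 = 1L, c2 = ce, stop = TRUE, class = "partial5")
        } else {
          emit <- list(c1 = 1L, c2 = ce, stop = FALSE, class = "internal")
        }
      }
      if (is.null(emit)) next
      pep <- paste(aa[emit$c1:emit$c2], collapse = "")
      if (nchar(pep) < min_len_aa) next
      c2i <- emit$c2 + as.integer(emit$stop) # include stop codon in interval
      wa <- offset + 3L * (emit$c1 - 1L)
      wb <- offset + 3L * c2i
      if (reverse) { tmp <- wa; wa <- L - wb; wb <- L - tmp }
      calls[[length(calls) + 1L]] <- data.frame(
        transcript_id = transcript_id,
        frame = .frame_int(.FRAME_LABELS[fi]),
        start = wa, end = wb, peptide = pep, completeness = emit$class,
        length_aa = nchar(pep), aa_start = emit$c1 - 1L, aa_end = emit$c2,
        aa_seg_start = cs - 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(data.frame(transcript_id = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      peptide = character(0), completeness = character(0),
                      length_aa = integer(0), aa_start = integer(0),
                      aa_end = integer(0), aa_seg_start = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  out <- out[order(-out$length_aa, out$frame, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Refine an ORF completeness call against a homology hit
#'
#' Alignment coverage arbitrates partial calls: projecting the query's
#' N-terminus onto the subject (`s_start - q_start`), a projected start
#' lying more than `tol` residues upstream of the ORF's start codon
#' means the homologous protein begins before the ATG — the ORF has
#' lost its true start and is downgraded to `partial5`/`internal` even
#' though an internal ATG exists.
#'
#' @param orf one row of [find_orfs()] output (data.frame or list).
#' @param hit one homology hit (see [search_homology()]); must be on the
#'   same transcript and frame, with an overlapping subject interval.
#' @param query_len query length in aa.
#' @param tol how close to the query terminus (aa) an alignment must
#'   reach to count as covering it. Default 5.
#' @return refined completeness string.
#' @export
classify_against_hit <- function(orf, hit, query_len, tol = 5L) {
  if (!identical(as.character(orf$transcript_id),
                 as.character(hit$transcript_id)) ||
      orf$frame != hit$frame)
    stop("ORF and hit are not on the same transcript and frame")
  if (hit$s_end <= orf$aa_start || hit$s_start >= orf$aa_end)
    stop("ORF and hit subject intervals do not overlap")
  has_start <- orf$completeness %in% c("complete", "partial3")
  has_stop <- orf$completeness %in% c("complete", "partial5")
  projected_query_start <- hit$s_start - hit$q_start
  if (has_start && projected_query_start < orf$aa_start - tol)
    has_start <- FALSE
  if (has_start && has_stop) "complete"
  else if (has_stop) "partial5"
  else if (has_start) "partial3"
  else "internal"
}

#' Extend an ORF call to its enclosing segment's 5' end
#'
#' Used when homology evidence shows an ORF's ATG is internal: the call
#' is stretched back to the start of its stop-to-stop segment (which,
#' for a transcript-start-anchored segment, is the transcript 5' end),
#' and its peptide, coordinates and length are recomputed. The caller
#' is responsible for setting the refined completeness.
#'
#' @param orf one row of [find_orfs()] output (as a list).
#' @param seq the transcript sequence.
#' @return the adjusted ORF call (list).
#' @export
extend_orf_to_segment <- function(orf, seq) {
  if (orf$aa_seg_start >= orf$aa_start) return(orf)
  L <- nchar(seq)
  offset <- abs(orf$frame) - 1L
  w <- if (orf$frame < 0) revcomp(seq) else seq
  has_stop <- orf$completeness %in% c("complete", "partial5")
  c2i <- orf$aa_end + as.integer(has_stop)
  wa <- offset + 3L * orf$aa_seg_start
  wb <- offset + 3L * c2i
  if (orf$frame < 0) { tmp <- wa; wa <- L - wb; wb <- L - tmp }
  orf$peptide <- translate_nt(substr(w, offset + 3L * orf$aa_seg_start + 1L,
                                     offset + 3L * orf$aa_end))
  orf$aa_start <- orf$aa_seg_start
  orf$start <- wa
  orf$end <- wb
  orf$length_aa <- nchar(orf$peptide)
  orf
}

#' Re-translate an ORF call from its coordinates
#'
#' Utility asserting the coordinate bookkeeping: extracts the ORF's
#' nucleotide interval (minus the stop codon when present) and
#' translates it in its own frame.
#'
#' @param orf one row of [find_orfs()] output.
#' @param seq the transcript sequence.
#' @return the peptide encoded at the ORF's coordinates.
#' @export
orf_peptide_from_coords <- function(orf, seq) {
  has_stop <- orf$completeness %in% c("complete", "partial5")
  a <- orf$start; b <- orf$end
  sub <- substr(seq, a + 1L, b)
  if (orf$frame < 0) sub <- revcomp(sub)
  if (has_stop) sub <- substr(sub, 1L, nchar(sub) - 3L)
  translate_nt(sub)
}
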