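# Greedy identity clustering of transcripts (cd-hit-est style): sort by
# descending length, each sequence joins the first existing
# representative it matches at >= threshold identity, otherwise founds a
# new cluster. Because clustering is longest-first, the representative
# of every cluster is automatically its largest member.

#' Pairwise sequence identity
#'
#' Identity is the number of matched positions in an optimal
#' end-gap-free pairwise alignment under unit scoring (match +1,
#' mismatch -1, internal gap -1, terminal gaps free; among
#' equal-scoring alignments the match-richest one counts) divided by
#' the length of the shorter sequence. Free terminal gaps make the
#' measure a containment identity when lengths differ, which is how
#' cd-hit treats sequences of different sizes. Symmetric, in `[0, 1]`,
#' and 1 for identical sequences. Works for nucleotide and amino-acid
#' strings alike.
#'
#' @param a,b non-empty sequence strings.
#' @return identity fraction.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  matches <- .nw_matches_cpp(utf8ToInt(a), utf8ToInt(b))
  matches / min(nchar(a), nchar(b))
}

# k-mer prefilter: can a pair sharing no word of length w still reach
# identity >= t? If matches >= t*Ls then non-match alignment columns are
# at most Ls + Ll - 2*t*Ls, so some run of >= t*Ls/(e+1) consecutive
# matches exists. Skipping is only allowed when that guaranteed run is
# at least w.
.prefilter_safe <- function(ls, ll, t, w) {
  e <- ls + ll - 2 * t * ls
  (t * ls) / (e + 1) >= w
}

.kmer_set <- function(seq, w) {
  n <- nchar(seq)
  if (n < w) return(character(0))
  unique(substring(seq, 1:(n - w + 1L), w:n))
}

#' Collapse redundant transcripts by greedy identity clustering
#'
#' Emulates a cd-hit-est pass with `-c threshold -n word_size`:
#' sequences are visited longest first (ties broken lexicographically by
#' id) and join the earliest-founded representative with
#' [pairwise_identity()] >= `threshold`; otherwise they found a new
#' cluster. Comparison is forward strand only. The word-size k-mer
#' prefilter only skips pairs that provably cannot reach the threshold.
#'
#' @param transcripts named character vector of nucleotide sequences.
#' @param threshold identity threshold in (0, 1]; default 0.98.
#' @param word_size prefilter k-mer length; default 8.
#' @return list of class `cluster_result` with `representatives` (named
#'   character vector, in founding order), `membership` (named character
#'   vector transcript_id -> representative_id), `threshold`,
#'   `word_size`.
#' @export
collapse <- function(transcripts, threshold = 0.98, word_size = 8L) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  stopifnot(length(transcripts) == 0L || !is.null(names(transcripts)))
  ord <- order(-nchar(transcripts), names(transcripts))
  ids <- names(transcripts)[ord]
  seqs <- unname(transcripts[ord])
  rep_ids <- character(0)
  rep_kmers <- list()
  membership <- character(0)
  for (i in seq_along(ids)) {
    s <- seqs[[i]]
    km <- .kmer_set(s, word_size)
    assigned <- NA_character_
    for (r in seq_along(rep_ids)) {
      rs <- transcripts[[rep_ids[r]]]
      ls <- min(nchar(s), nchar(rs)); ll <- max(nchar(s), nchar(rs))
      if (.prefilter_safe(ls, ll, threshold, word_size) &&
          !any(km %in% rep_kmers[[r]])) next
      if (pairwise_identity(s, rs) >= threshold) {
        assigned <- rep_ids[r]
        break
      }
    }
    if (is.na(assigned)) {
      rep_ids <- c(rep_ids, ids[i])
      rep_kmers[[length(rep_ids)]] <- km
      assigned <- ids[i]
    }
    membership[[ids[i]]] <- assigned
  }
  structure(list(representatives = transcripts[rep_ids],
                 membership = membership[names(transcripts)],
                 threshold = threshold, word_size = as.integer(word_size)),
            class = "cluster_result")
}
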