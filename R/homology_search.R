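# Translated homology search: protein queries against the six-frame
# translations of a transcript set, scored by affine-gap Smith-Waterman
# under BLOSUM62 with Karlin-Altschul E-values. A desk-scale stand-in
# for tblastn: full dynamic programming, no heuristic seeding, with an
# optional k-mer prefilter that can only skip subjects sharing no word
# with the query. E-values use the raw database length (no effective-
# length correction) and are therefore conservative and comparable only
# within this implementation.

.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

#' Search configuration
#'
#' @param gap_open,gap_extend affine gap penalties (positive; a gap of
#'   length L costs `gap_open + L * gap_extend`). Defaults 11 and 1.
#' @param lambda,K Karlin-Altschul constants; defaults 0.267 and 0.041,
#'   the published gapped values for BLOSUM62/11/1.
#' @param e_max maximum E-value for a reported hit. Default 1e-05.
#' @param max_hits_per_query hit-list truncation. Default 50.
#' @param prefilter_word if > 0, subjects sharing no amino-acid word of
#'   this length with the query are skipped. Default 4; set 0 to
#'   disable.
#' @return object of class `search_config`.
#' @export
search_config <- function(gap_open = 11, gap_extend = 1,
                          lambda = 0.267, K = 0.041,
                          e_max = 1e-05, max_hits_per_query = 50L,
                          prefilter_word = 4L) {
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0, e_max >= 0)
  structure(list(matrix = .blosum62(), gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 e_max = e_max,
                 max_hits_per_query = as.integer(max_hits_per_query),
                 prefilter_word = as.integer(prefilter_word)),
            class = "search_config")
}

# peptide -> 0-based indices into the substitution matrix rows; unknown
# characters become X
.aa_encode <- function(pep, alphabet) {
  idx <- match(strsplit(pep, "", fixed = TRUE)[[1]], alphabet)
  idx[is.na(idx)] <- match("X", alphabet)
  idx - 1L
}

#' Optimal local alignment of two peptides
#'
#' Affine-gap Smith-Waterman under the configuration's substitution
#' matrix. Ties between equal-scoring alignments are broken by lowest
#' subject start, then lowest query start. An all-negative scoring
#' landscape yields the empty alignment with score 0.
#'
#' @param query_aa,subject_aa non-empty peptide strings.
#' @param config a [search_config()].
#' @return list: `score`, `q_start`, `q_end`, `s_start`, `s_end`
#'   (0-based half-open aa intervals), `n_ident`, `aln_len`,
#'   `identity` (matched columns / alignment columns; `NA` for the
#'   empty alignment).
#' @export
smith_waterman <- function(query_aa, subject_aa, config = search_config()) {
  if (!nzchar(query_aa) || !nzchar(subject_aa)) stop("empty peptide")
  alpha <- rownames(config$matrix)
  q <- .aa_encode(query_aa, alpha)
  s <- .aa_encode(subject_aa, alpha)
  r <- .sw_align_cpp(q, s, config$matrix, config$gap_open, config$gap_extend)
  qc <- r$q_col; sc <- r$s_col
  aln_len <- length(qc)
  n_ident <- if (aln_len == 0L) 0L else {
    both <- qc > 0L & sc > 0L
    sum(both &
          substring(query_aa, qc, qc) == substring(subject_aa, sc, sc))
  }
  list(score = r$score, q_start = r$q_start, q_end = r$q_end,
       s_start = r$s_start, s_end = r$s_end, n_ident = n_ident,
       aln_len = aln_len,
       identity = if (aln_len) n_ident / aln_len else NA_real_)
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)`; non-positive scores are capped at
#' `K * m * n`. Strictly decreasing in the score, linear in the
#' database length.
#'
#' @param raw_score alignment raw score.
#' @param query_len query length (aa).
#' @param database_len_aa total database residues (all six frames).
#' @param config a [search_config()].
#' @return the E-value.
#' @export
evalue_of <- function(raw_score, query_len, database_len_aa,
                      config = search_config()) {
  stopifnot(query_len > 0, database_len_aa > 0)
  mn <- config$K * query_len * database_len_aa
  if (raw_score <= 0) return(mn)
  mn * exp(-config$lambda * raw_score)
}

#' Bit score from a raw score
#' @inheritParams evalue_of
#' @return bit score `(lambda * S - ln K) / ln 2`.
#' @export
bit_score <- function(raw_score, config = search_config()) {
  (config$lambda * raw_score - log(config$K)) / log(2)
}

.kmer_set_aa <- function(pep, w) {
  n <- nchar(pep)
  if (n < w) return(character(0))
  unique(substring(pep, 1:(n - w + 1L), w:n))
}

#' Translated homology search of protein queries against transcripts
#'
#' Every query is aligned against all six frames of every transcript;
#' hits with E-value at most `config$e_max` are kept, sorted per query
#' by ascending E-value then descending score, and truncated to
#' `max_hits_per_query`. `contains_internal_stop` flags hits whose
#' aligned subject region contains an in-frame stop codon (the
#' pseudogenized-hit signature).
#'
#' @param queries named character vector of protein sequences.
#' @param transcripts named character vector of nucleotide sequences.
#' @param config a [search_config()].
#' @param genes_map optional named character vector (transcript ->
#'   gene); absent transcripts fall back to their own id as gene_id.
#' @return data.frame of hits: `query_id`, `transcript_id`, `gene_id`,
#'   `frame`, `q_start`, `q_end`, `s_start`, `s_end` (aa, 0-based
#'   half-open; subject coordinates are within the frame translation),
#'   `raw_score`, `bit_score`, `evalue`, `pct_identity`,
#'   `contains_internal_stop`.
#' @export
search_homology <- function(queries, transcripts, config = search_config(),
                            genes_map = NULL) {
  stopifnot(length(queries) > 0, length(transcripts) > 0,
            !is.null(names(queries)), !is.null(names(transcripts)))
  frames <- lapply(transcripts, six_frame_translate)
  db_len <- sum(vapply(frames, function(f) sum(nchar(f)), numeric(1)))
  w <- config$prefilter_word
  frame_kmers <- if (w > 0)
    lapply(frames, function(f) lapply(f, .kmer_set_aa, w = w)) else NULL
  rows <- vector("list", 0L)
  for (qi in seq_along(queries)) {
    qid <- names(queries)[qi]
    qpep <- queries[[qi]]
    qk <- if (w > 0) .kmer_set_aa(qpep, w) else NULL
    for (ti in seq_along(transcripts)) {
      tid <- names(transcripts)[ti]
      for (fi in seq_along(.FRAME_LABELS)) {
        fpep <- frames[[ti]][[fi]]
        if (nchar(fpep) == 0L) next
        if (w > 0 && !any(qk %in% frame_kmers[[ti]][[fi]])) next
        al <- smith_waterman(qpep, fpep, config)
        if (al$score <= 0) next
        ev <- evalue_of(al$score, nchar(qpep), db_len, config)
        if (ev > config$e_max) next
        sub_region <- substr(fpep, al$s_start + 1L, al$s_end)
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = qid, transcript_id = tid,
          gene_id = if (!is.null(genes_map) && tid %in% names(genes_map))
            unname(genes_map[[tid]]) else tid,
          frame = .frame_int(.FRAME_LABELS[fi]),
          q_start = al$q_start, q_end = al$q_end,
          s_start = al$s_start, s_end = al$s_end,
          raw_score = al$score, bit_score = bit_score(al$score, config),
          evalue = ev, pct_identity = al$identity,
          contains_internal_stop = grepl("*", sub_region, fixed = TRUE),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(query_id = character(0), transcript_id = character(0),
                      gene_id = character(0), frame = integer(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      raw_score = numeric(0), bit_score = numeric(0),
                      evalue = numeric(0), pct_identity = numeric(0),
                      contains_internal_stop = logical(0),
                      stringsAsFactors = FALSE))
  hits <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(hits, hits$query_id), function(h) {
    h <- h[order(h$evalue, -h$raw_score, -h$pct_identity, h$transcript_id), ,
           drop = FALSE]
    utils::head(h, n = config$max_hits_per_query)
  }))
  rownames(out) <- NULL
  out
}

#' Gene-level cluster of a query's top hit
#'
#' @param query_id the query.
#' @param hits output of [search_homology()].
#' @return the best hit's `gene_id` (ties: lower E-value, higher score,
#'   higher identity, lexicographic transcript id), or `NA_character_`
#'   as an explicit no-hit signal.
#' @export
top_hit_transcript <- function(query_id, hits) {
  h <- hits[hits$query_id == query_id, , drop = FALSE]
  if (nrow(h) == 0L) return(NA_character_)
  h <- h[order(h$evalue, -h$raw_score, -h$pct_identity, h$transcript_id), ,
         drop = FALSE]
  h$gene_id[1]
}
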