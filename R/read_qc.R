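# Paired-end read quality filtering: the three read-removal criteria
# applied before any downstream use. A pair is removed when EITHER mate
# fails ANY criterion; report counts are mutually exclusive in criterion
# order adaptor -> N -> quality. Boundaries are strict ("greater than"):
# exactly 5% N and exactly 50% low-quality bases are kept.

#' Construct a read-filtering policy
#'
#' @param adaptors character vector of adaptor sequences (possibly
#'   empty, in which case the adaptor criterion is vacuous). A read
#'   fails the adaptor criterion when it contains an exact match to any
#'   10-nt (or longer) stretch of an adaptor.
#' @param max_n_fraction maximum tolerated fraction of unknown (N)
#'   bases; reads strictly above it are removed. Default 0.05.
#' @param max_lowq_fraction maximum tolerated fraction of bases below
#'   `q_threshold`; strictly above it removes the read. Default 0.50.
#' @param q_threshold Phred score below which a base counts as low
#'   quality. Default 10.
#' @param adaptor_word minimum exact adaptor match length. Default 10.
#' @return object of class `qc_policy`.
#' @export
qc_policy <- function(adaptors = character(0), max_n_fraction = 0.05,
                      max_lowq_fraction = 0.50, q_threshold = 10L,
                      adaptor_word = 10L) {
  stopifnot(max_n_fraction >= 0, max_n_fraction <= 1,
            max_lowq_fraction >= 0, max_lowq_fraction <= 1,
            q_threshold >= 0, adaptor_word >= 1)
  structure(list(adaptors = toupper(adaptors),
                 max_n_fraction = max_n_fraction,
                 max_lowq_fraction = max_lowq_fraction,
                 q_threshold = as.integer(q_threshold),
                 adaptor_word = as.integer(adaptor_word)),
            class = "qc_policy")
}

# all distinct words of length w from the adaptor set
.adaptor_words <- function(adaptors, w) {
  words <- unlist(lapply(adaptors, function(a) {
    n <- nchar(a)
    if (n < w) return(character(0))
    substring(a, 1:(n - w + 1L), w:n)
  }))
  unique(words)
}

# vectorized per-read criterion checks ----------------------------------

.fails_adaptor <- function(seqs, policy) {
  words <- .adaptor_words(policy$adaptors, policy$adaptor_word)
  hit <- rep(FALSE, length(seqs))
  for (wd in words) hit <- hit | grepl(wd, seqs, fixed = TRUE)
  hit
}

.fails_n <- function(seqs, policy) {
  n_count <- nchar(seqs) - nchar(gsub("N", "", seqs, fixed = TRUE))
  n_count / nchar(seqs) > policy$max_n_fraction
}

.fails_lowq <- function(quals, policy) {
  if (policy$q_threshold <= 0) return(rep(FALSE, length(quals)))
  # low-quality = Phred < q, i.e. ASCII 33 .. 33 + q - 1
  hi <- intToUtf8(33L + policy$q_threshold - 1L)
  re <- paste0("[\\x21-\\x", sprintf("%x", utf8ToInt(hi)), "]")
  low <- nchar(quals) - nchar(gsub(re, "", quals, perl = TRUE))
  low / nchar(quals) > policy$max_lowq_fraction
}

#' Filter read pairs by the three removal criteria
#'
#' @param pairs data.frame with columns `read_id`, `seq1`, `qual1`,
#'   `seq2`, `qual2` (see [read_fastq_pairs()]).
#' @param policy a [qc_policy()].
#' @return list with `kept` (the surviving pairs, same columns) and
#'   `report`: named list of counts `n_input`, `removed_adaptor`,
#'   `removed_n`, `removed_lowq`, `n_kept`. A pair is attributed to the
#'   first criterion (adaptor, then N, then quality) failed by either
#'   mate, so the removal counts are mutually exclusive and exhaustive.
#' @export
filter_pairs <- function(pairs, policy) {
  stopifnot(inherits(policy, "qc_policy"),
            all(c("seq1", "qual1", "seq2", "qual2") %in% names(pairs)))
  n <- nrow(pairs)
  fa <- .fails_adaptor(pairs$seq1, policy) | .fails_adaptor(pairs$seq2, policy)
  fn <- .fails_n(pairs$seq1, policy) | .fails_n(pairs$seq2, policy)
  fq <- .fails_lowq(pairs$qual1, policy) | .fails_lowq(pairs$qual2, policy)
  cls <- rep("kept", n)
  cls[fq] <- "lowq"
  cls[fn] <- "nfrac"
  cls[fa] <- "adaptor"
  keep <- cls == "kept"
  list(kept = pairs[keep, , drop = FALSE],
       report = list(n_input = n,
                     removed_adaptor = sum(cls == "adaptor"),
                     removed_n = sum(cls == "nfrac"),
                     removed_lowq = sum(cls == "lowq"),
                     n_kept = sum(keep)))
}
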